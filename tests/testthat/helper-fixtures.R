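# In-code fixtures shared across test files.

# Hand-built cross design (replicate counts all 1 unless given).
make_design <- function(crosses, tissues = "ear", replicates = NULL) {
  maize <- unique(crosses$maize_line)
  teo <- unique(crosses$teosinte_line)
  crosses$cross <- paste0(crosses$maize_line, "x", crosses$teosinte_line)
  genos <- c(maize, teo, crosses$cross)
  reps <- if (is.null(replicates)) stats::setNames(rep(1L, length(genos)),
                                                   genos) else replicates
  structure(list(maize_lines = maize, teosinte_lines = teo,
                 crosses = crosses, replicates = reps, tissues = tissues),
            class = "cross_design")
}

# One count row.
count_row <- function(gene, genotype, m, t, tissue = "ear", rep = 1L) {
  data.frame(gene_id = gene, tissue = tissue, genotype = genotype,
             replicate = rep, maize_count = m, teosinte_count = t,
             stringsAsFactors = FALSE)
}

# Single-cross fixture: one gene, hybrid (hm, ht), parents (pm, pt),
# equal library sizes by adding a filler gene balancing totals.
one_cross_counts <- function(hm, ht, pm, pt, filler = 10000L) {
  rbind(
    count_row("g1", "M1xT1", hm, ht),
    count_row("g1", "M1", pm, 0L),
    count_row("g1", "T1", 0L, pt),
    # filler gene equalizes parent library sizes
    count_row("g0", "M1xT1", filler, filler),
    count_row("g0", "M1", 2L * filler - pm, 0L),
    count_row("g0", "T1", 0L, 2L * filler - pt))
}

one_cross_design <- function() {
  make_design(data.frame(maize_line = "M1", teosinte_line = "T1",
                         stringsAsFactors = FALSE))
}

# Independent minlike two-sided binomial oracle (exact for n <= 20:
# choose() and 2^n are integer-exact in doubles).
binom_oracle <- function(m, n) {
  pmf <- choose(n, 0:n) / 2^n
  sum(pmf[pmf <= pmf[m + 1] * (1 + 1e-7)])
}

# Independent minlike two-sided FET oracle by hypergeometric enumeration
# over all tables with the observed margins.
fet_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  logp <- vapply(lo:hi, function(x)
    lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k), numeric(1))
  pmf <- exp(logp)
  sum(pmf[pmf <= pmf[a - lo + 1] * (1 + 1e-7)])
}

# One-sided (enrichment) hypergeometric tail oracle for set overlaps:
# P(overlap >= obs) with list size nl, set size ns, universe nu.
hyper_tail_oracle <- function(obs, nl, ns, nu) {
  x <- obs:min(nl, ns)
  sum(exp(lchoose(ns, x) + lchoose(nu - ns, nl - x) - lchoose(nu, nl)))
}
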