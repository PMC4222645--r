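#' Exact two-sided binomial test of a 1:1 allelic ratio
#'
#' Tests whether maize:teosinte read counts deviate from the 1:1 expectation,
#' using the exact binomial distribution with success probability 0.5 and the
#' "minimum-likelihood" two-sided p-value (sum of outcome probabilities no
#' greater than that of the observed outcome). Because the null distribution
#' is symmetric at p = 0.5, that outcome set is exactly the two equal tails,
#' so the p-value has the closed form `min(1, 2 * P(X <= min(m, t)))` —
#' computed vectorized, which keeps the test fast at read depths in the
#' hundreds of thousands.
#'
#' @param m,t Maize- and teosinte-allele read counts (vectors allowed;
#'   recycled to common length). `m + t` must be at least 1; pairs with zero
#'   total get `NA`.
#' @return Vector of two-sided p-values.
#' @export
binom_test_1to1 <- function(m, t) {
  n <- max(length(m), length(t))
  m <- as.numeric(rep_len(m, n)); t <- as.numeric(rep_len(t, n))
  tot <- m + t
  p <- pmin(1, 2 * stats::pbinom(pmin(m, t), tot, 0.5))
  p[is.na(tot) | tot < 1] <- NA_real_
  p
}

#' Fisher's exact test of parent versus hybrid allelic ratios
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' `[[parent_m, parent_t], [hybrid_m, hybrid_t]]`, asking whether the parent
#' (cis + trans) and hybrid (cis) maize:teosinte ratios differ. Two-sidedness
#' sums tables whose conditional probability does not exceed the observed
#' one. A degenerate table (a zero row and a zero column) returns 1.
#'
#' @param parent_m,parent_t,hybrid_m,hybrid_t Non-negative counts (vectors
#'   allowed).
#' @return Vector of two-sided p-values.
#' @export
fet_parent_vs_hybrid <- function(parent_m, parent_t, hybrid_m, hybrid_t) {
  n <- max(length(parent_m), length(parent_t), length(hybrid_m),
           length(hybrid_t))
  pm <- rep_len(parent_m, n); pt <- rep_len(parent_t, n)
  hm <- rep_len(hybrid_m, n); ht <- rep_len(hybrid_t, n)
  vapply(seq_len(n), function(i)
    .fet2x2(pm[i], pt[i], hm[i], ht[i]), numeric(1))
}

# two-sided Fisher p for [[a, b], [c, d]] by direct hypergeometric
# enumeration over the support, summing tables with conditional probability
# <= observed (with the standard 1 + 1e-7 relative tie tolerance). Avoids
# the odds-ratio machinery of stats::fisher.test, which dominates run time
# at RNA-seq depths.
.fet2x2 <- function(a, b, c, d) {
  if (any(is.na(c(a, b, c, d)))) return(NA_real_)
  m1 <- a + b; m2 <- c + d        # row margins
  k <- a + c                      # first-column margin
  if (m1 == 0 || m2 == 0 || k == 0 || b + d == 0) return(1)
  lo <- max(0, k - m2); hi <- min(k, m1)
  x <- lo:hi
  pmf <- stats::dhyper(x, m1, m2, k)
  min(1, sum(pmf[pmf <= pmf[a - lo + 1] * (1 + 1e-7)]))
}

#' Storey q-values with fixed-lambda pi0 estimation
#'
#' Converts p-values to q-values controlling the positive false discovery
#' rate. The proportion of true nulls is estimated as
#' `pi0 = mean(p > lambda) / (1 - lambda)` at a single fixed `lambda`
#' (default 0.5, no smoother, for determinism), clamped to (0, 1]: values
#' above 1 are set to 1 and a zero estimate falls back to `1/m` so q-values
#' stay positive. Then `q_i = min over {j : p_j >= p_i} of
#' pi0 * m * p_j / rank(p_j)`, capped at 1 — monotone non-decreasing in p.
#'
#' @param p Vector of p-values in `[0, 1]` (NAs propagate).
#' @param lambda Tuning parameter in `[0, 1)` for the pi0 estimate.
#' @return Vector of q-values in the original order.
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(lambda >= 0, lambda < 1)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(q)
  pi0 <- mean(pv > lambda) / (1 - lambda)
  pi0 <- min(pi0, 1)
  if (pi0 <= 0) pi0 <- 1 / m
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  qv <- pmin(1, cummin(pi0 * m * pv[o] / rank(pv, ties.method = "max")[o]))[ro]
  q[ok] <- qv
  q
}

#' Assign the seven-way regulatory category
#'
#' Maps the significance pattern of the parent binomial test, hybrid binomial
#' test and Fisher's exact test, plus the directions of the cis and trans
#' effects, to one of seven regulatory categories:
#' \itemize{
#'   \item cis: parent sig, hybrid sig, FET not sig
#'   \item trans: parent sig, hybrid not sig, FET sig
#'   \item cis_plus_trans: all three sig, cis and trans effects same direction
#'   \item cis_x_trans: all three sig, opposite directions
#'   \item compensatory: parent not sig, hybrid sig, FET sig
#'   \item conserved: both binomial tests not sig (FET is not run)
#'   \item ambiguous: every other pattern
#' }
#' A zero trans direction (exact equality) is grouped with "same direction".
#'
#' @param sig_parent,sig_hybrid,sig_fet Logical significance flags (vectors
#'   allowed). `sig_fet` is ignored when both binomial tests are
#'   non-significant, and may be `NA` when the FET was not run.
#' @param cis_sign,trans_sign Directions in `{-1, 0, 1}` of the hybrid log
#'   ratio and the trans effect.
#' @return Character vector of categories.
#' @export
classify_gene <- function(sig_parent, sig_hybrid, sig_fet, cis_sign,
                          trans_sign) {
  n <- max(length(sig_parent), length(sig_hybrid), length(sig_fet),
           length(cis_sign), length(trans_sign))
  sp <- rep_len(as.logical(sig_parent), n)
  sh <- rep_len(as.logical(sig_hybrid), n)
  sf <- rep_len(as.logical(sig_fet), n)
  cs <- rep_len(cis_sign, n); ts <- rep_len(trans_sign, n)
  out <- rep("ambiguous", n)
  out[!sp & !sh] <- "conserved"
  both <- sp & sh
  out[both & !sf %in% TRUE] <- "cis"
  same_dir <- cs == ts | ts == 0 | cs == 0
  out[both & sf %in% TRUE & same_dir] <- "cis_plus_trans"
  out[both & sf %in% TRUE & !same_dir] <- "cis_x_trans"
  out[sp & !sh & sf %in% TRUE] <- "trans"
  out[!sp & sh & sf %in% TRUE] <- "compensatory"
  out
}

#' Classify all genes from overall ratio records
#'
#' Runs the full testing flow of the regulatory classifier per tissue:
#' binomial tests of the overall parent and hybrid counts against 1:1,
#' Storey q-values per test family within tissue, then a Fisher's exact test
#' only for genes where at least one binomial test is significant (its
#' q-values computed within that subset), and finally the seven-way category
#' assignment. Directions are taken from the counts themselves
#' (`sign(hybrid_m - hybrid_t)` for cis; the sign of the parent-vs-hybrid
#' ratio difference for trans) so genes with zero counts on one side are
#' still classified.
#'
#' @param overall Overall records from [overall_ratios()].
#' @param fdr q-value significance threshold (default 0.005, i.e. FDR 0.5%).
#' @param lambda Passed to [storey_qvalues()].
#' @return A list with `calls` (per-gene data.frame: p/q-values, significance
#'   flags, signs, `category`) and `summary` (per-tissue category counts and
#'   proportions).
#' @export
classify_all <- function(overall, fdr = 0.005, lambda = 0.5) {
  stopifnot(fdr > 0, fdr < 1)
  dt <- data.table::as.data.table(overall)
  res <- vector("list", length(unique(dt$tissue)))
  k <- 0L
  for (tis in sort(unique(dt$tissue))) {
    d <- dt[tissue == tis]
    p_parent <- binom_test_1to1(d$wsum_parent_m, d$wsum_parent_t)
    p_hybrid <- binom_test_1to1(d$sum_hybrid_m, d$sum_hybrid_t)
    q_parent <- storey_qvalues(p_parent, lambda)
    q_hybrid <- storey_qvalues(p_hybrid, lambda)
    sig_parent <- q_parent < fdr & !is.na(q_parent)
    sig_hybrid <- q_hybrid < fdr & !is.na(q_hybrid)
    run_fet <- sig_parent | sig_hybrid
    p_fet <- rep(NA_real_, nrow(d))
    q_fet <- rep(NA_real_, nrow(d))
    if (any(run_fet)) {
      p_fet[run_fet] <- fet_parent_vs_hybrid(
        d$wsum_parent_m[run_fet], d$wsum_parent_t[run_fet],
        d$sum_hybrid_m[run_fet], d$sum_hybrid_t[run_fet])
      q_fet[run_fet] <- storey_qvalues(p_fet[run_fet], lambda)
    }
    sig_fet <- ifelse(is.na(q_fet), NA, q_fet < fdr)
    cis_sign <- sign(d$sum_hybrid_m - d$sum_hybrid_t)
    trans_sign <- sign(as.numeric(d$wsum_parent_m) * d$sum_hybrid_t -
                         as.numeric(d$wsum_parent_t) * d$sum_hybrid_m)
    category <- classify_gene(sig_parent, sig_hybrid, sig_fet,
                              cis_sign, trans_sign)
    k <- k + 1L
    res[[k]] <- data.table::data.table(
      gene_id = d$gene_id, tissue = tis,
      p_parent_bt = p_parent, p_hybrid_bt = p_hybrid, p_fet = p_fet,
      q_parent_bt = q_parent, q_hybrid_bt = q_hybrid, q_fet = q_fet,
      sig_parent = sig_parent, sig_hybrid = sig_hybrid, sig_fet = sig_fet,
      cis_sign = cis_sign, trans_sign = trans_sign, category = category)
  }
  calls <- data.table::rbindlist(res[seq_len(k)])
  data.table::setorder(calls, gene_id, tissue)
  summ <- calls[, .(n = .N), by = .(tissue, category)]
  summ[, proportion := n / sum(n), by = tissue]
  data.table::setorder(summ, tissue, category)
  data.table::setDF(calls); data.table::setDF(summ)
  list(calls = calls, summary = summ)
}

#' Plot parent versus hybrid log2 ratios colored by regulatory category
#'
#' The standard diagnostic scatter for cis/trans dissection: each gene's
#' parent (cis + trans) log2 ratio on the x-axis against its hybrid (cis)
#' log2 ratio on the y-axis, colored by assigned category. Pure-cis genes
#' fall on the diagonal, pure-trans genes on the x-axis, compensatory genes
#' on the y-axis.
#'
#' @param overall Overall records from [overall_ratios()].
#' @param calls `calls` data.frame from [classify_all()].
#' @param tissue Single tissue to plot.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the merged plotting data.
#' @export
plot_parent_hybrid <- function(overall, calls, tissue, ...) {
  tis <- tissue
  m <- merge(overall[overall$tissue == tis, ],
             calls[calls$tissue == tis,
                   c("gene_id", "tissue", "category")],
             by = c("gene_id", "tissue"))
  pal <- c(cis = "black", trans = "red3", cis_plus_trans = "dodgerblue3",
           cis_x_trans = "orange2", compensatory = "purple3",
           conserved = "grey60", ambiguous = "grey85")
  ok <- !is.na(m$log2_parent_overall) & !is.na(m$log2_hybrid_overall)
  m <- m[ok, ]
  graphics::plot(m$log2_parent_overall, m$log2_hybrid_overall,
                 col = pal[m$category], pch = 16, cex = 0.5,
                 xlab = "log2 parent ratio (cis + trans)",
                 ylab = "log2 hybrid ratio (cis)",
                 main = paste0("Regulatory divergence (", tis, ")"), ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  graphics::abline(0, 1, col = "grey70", lty = 2)
  graphics::legend("topleft", legend = names(pal), col = pal, pch = 16,
                   cex = 0.7, bty = "n")
  invisible(m)
}
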