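#' Cis share of regulatory divergence
#'
#' The fraction of a gene's regulatory divergence attributable to cis:
#' `|cis| / (|cis| + |trans|)`, where cis is the log2 hybrid ratio and trans
#' the parent-minus-hybrid log2 ratio difference. Scale-free: doubling both
#' effects leaves it unchanged. Undefined (NA) when both effects are zero or
#' either is NA (zero counts).
#'
#' @param log2_hybrid,trans_effect Effect vectors (log2 units).
#' @return Numeric vector in `[0, 1]` with NAs where undefined.
#' @export
cis_share <- function(log2_hybrid, trans_effect) {
  denom <- abs(log2_hybrid) + abs(trans_effect)
  ifelse(is.na(denom) | denom == 0, NA_real_, abs(log2_hybrid) / denom)
}

#' Cis share binned by total expression divergence
#'
#' Bins genes by the magnitude of total divergence (`|log2 parent ratio|`)
#' into 0-1, 1-2, 2-3, 3-4, 4-5 and 5+ log2 units and reports the mean cis
#' share per bin with a seeded nonparametric bootstrap (resampling genes
#' within bins) 95% percentile confidence interval. Genes with undefined cis
#' share are excluded.
#'
#' @param overall Overall records from [overall_ratios()] (uses
#'   `log2_hybrid_overall` and `log2_parent_overall`).
#' @param n_boot Bootstrap replicates (default 1000); 0 suppresses CIs.
#' @param seed Integer seed for the bootstrap.
#' @param breaks Left edges of the bins; the last bin is open-ended.
#' @return Data.frame with `bin`, `n_genes`, `mean_cis_share`, `ci_low`,
#'   `ci_high` (CIs NA when `n_boot = 0`).
#' @export
cis_share_by_bin <- function(overall, n_boot = 1000, seed = 1,
                             breaks = 0:5) {
  cis <- overall$log2_hybrid_overall
  trans <- overall$log2_parent_overall - overall$log2_hybrid_overall
  share <- cis_share(cis, trans)
  total <- abs(overall$log2_parent_overall)
  ok <- !is.na(share) & !is.na(total)
  share <- share[ok]; total <- total[ok]
  if (length(share) == 0L)
    return(data.frame(bin = character(), n_genes = integer(),
                      mean_cis_share = numeric(), ci_low = numeric(),
                      ci_high = numeric()))
  edges <- c(breaks, Inf)
  labs <- c(paste(utils::head(breaks, -1), utils::tail(breaks, -1),
                  sep = "-"),
            paste0(breaks[length(breaks)], "+"))
  binidx <- findInterval(total, edges, rightmost.closed = FALSE)
  binidx[binidx < 1] <- 1L
  set.seed(seed)
  rows <- lapply(seq_along(labs), function(b) {
    s <- share[binidx == b]
    if (length(s) == 0L) return(NULL)
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0) {
      bm <- vapply(seq_len(n_boot), function(i)
        mean(sample(s, length(s), replace = TRUE)), numeric(1))
      ci <- unname(stats::quantile(bm, c(0.025, 0.975)))
    }
    data.frame(bin = labs[b], n_genes = length(s), mean_cis_share = mean(s),
               ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Leave-one-out influence of single F1s on the overall cis effect
#'
#' For every gene x tissue with at least two passing crosses, recomputes the
#' overall log2 hybrid ratio with each cross's counts removed and reports the
#' per-cross change `delta = full - dropped` plus the gene's mean delta and
#' mean absolute delta. A gene whose overall ratio is robust has deltas
#' tightly peaked at zero.
#'
#' @param ratios Per-cross records from [cross_ratios()].
#' @return A list with `per_cross` (gene_id, tissue, cross, delta) and
#'   `per_gene` (gene_id, tissue, n_crosses, mean_delta, mean_abs_delta).
#'   Genes with fewer than two passing crosses are omitted.
#' @export
loo_influence <- function(ratios) {
  dt <- data.table::as.data.table(ratios)
  dt <- dt[passes_depth == TRUE]
  dt <- dt[, if (.N >= 2) .SD, by = .(gene_id, tissue)]
  if (nrow(dt) == 0L)
    return(list(per_cross = data.frame(), per_gene = data.frame()))
  pc <- dt[, {
    Sm <- sum(hybrid_m); St <- sum(hybrid_t)
    full <- .log2_ratio(Sm, St)
    dropped <- .log2_ratio(Sm - hybrid_m, St - hybrid_t)
    .(cross = cross, delta = full - dropped)
  }, by = .(gene_id, tissue)]
  pg <- pc[, .(n_crosses = .N, mean_delta = mean(delta),
               mean_abs_delta = mean(abs(delta))),
           by = .(gene_id, tissue)]
  data.table::setorder(pc, gene_id, tissue, cross)
  data.table::setorder(pg, gene_id, tissue)
  data.table::setDF(pc); data.table::setDF(pg)
  list(per_cross = pc, per_gene = pg)
}
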