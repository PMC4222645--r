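#' Remove crosses with singleton teosinte parents
#'
#' Teosinte inbreds that participate in only a single cross contribute a
#' factor level confounded with that cross's residual, unbalancing the
#' per-gene variance-partition model. This filter drops all records from
#' crosses whose teosinte parent appears in exactly one cross of the design.
#'
#' @param ratios Per-cross records from [cross_ratios()] (any table with
#'   `cross` and `teosinte_line` columns).
#' @return The filtered records; warns if everything was removed.
#' @export
balance_design <- function(ratios) {
  cr <- unique(ratios[, c("cross", "teosinte_line")])
  n_per_t <- table(cr$teosinte_line)
  singletons <- names(n_per_t)[n_per_t == 1]
  out <- ratios[!ratios$teosinte_line %in% singletons, , drop = FALSE]
  if (nrow(out) == 0L) warning("all crosses removed by balance_design")
  out
}

#' Per-gene weighted variance partition between parents
#'
#' Fits, gene by gene, a weighted least-squares model of the per-cross log2
#' hybrid expression ratio on the maize-parent and teosinte-parent factors,
#' with per-cross total hybrid depth as weights. Each parent's contribution
#' is quantified as a drop-one (Type II) R-squared: the increase in weighted
#' residual sum of squares when that factor is dropped, divided by the total
#' weighted sum of squares about the weighted mean; significance comes from
#' the corresponding drop-one F-test. In an unbalanced design the two R²
#' values need not sum to the model R².
#'
#' @param ratios Per-cross records from [cross_ratios()]; typically pass
#'   through [balance_design()] first. Only passing records with defined
#'   `log2_hybrid` are used.
#' @param min_levels Minimum factor levels required on each side (default 2).
#' @return Data.frame with `gene_id`, `tissue`, `n_crosses`, `r2_maize`,
#'   `r2_teosinte`, `p_maize`, `p_teosinte`, `sig_class` (one of
#'   `maize_only`, `teosinte_only`, `both`, `neither` at p < 0.05) and
#'   `skipped_reason` (NA unless the gene could not be fitted).
#' @export
variance_partition <- function(ratios, min_levels = 2) {
  empty <- data.frame(gene_id = character(), tissue = character(),
                      n_crosses = integer(), r2_maize = numeric(),
                      r2_teosinte = numeric(), p_maize = numeric(),
                      p_teosinte = numeric(), sig_class = character(),
                      skipped_reason = character(), stringsAsFactors = FALSE)
  if (nrow(ratios) == 0L) return(empty)
  dt <- data.table::as.data.table(ratios)
  dt <- dt[passes_depth == TRUE & !is.na(log2_hybrid)]
  if (nrow(dt) == 0L) return(empty)
  fit1 <- function(y, mz, tz, w) {
    if (length(unique(mz)) < min_levels || length(unique(tz)) < min_levels)
      return(list(skip = "too_few_levels"))
    df_res <- length(y) - (1 + (length(unique(mz)) - 1) +
                             (length(unique(tz)) - 1))
    if (df_res < 1) return(list(skip = "no_residual_df"))
    dat <- data.frame(y = y, mz = factor(mz), tz = factor(tz), w = w)
    fit <- stats::lm(y ~ mz + tz, data = dat, weights = w)
    if (fit$rank < 1 + (nlevels(dat$mz) - 1) + (nlevels(dat$tz) - 1))
      return(list(skip = "rank_deficient"))
    # suppressed warning: "essentially perfect fit" on noiseless genes
    dr <- suppressWarnings(stats::drop1(fit, test = "F"))
    tss <- sum(w * (y - stats::weighted.mean(y, w))^2)
    if (tss <= 0)
      return(list(r2m = 0, r2t = 0, pm = 1, pt = 1))
    list(r2m = dr["mz", "Sum of Sq"] / tss,
         r2t = dr["tz", "Sum of Sq"] / tss,
         pm = dr["mz", "Pr(>F)"], pt = dr["tz", "Pr(>F)"])
  }
  res <- dt[, {
    f <- fit1(log2_hybrid, maize_line, teosinte_line, depth_hybrid)
    if (!is.null(f$skip))
      .(n_crosses = .N, r2_maize = NA_real_, r2_teosinte = NA_real_,
        p_maize = NA_real_, p_teosinte = NA_real_,
        sig_class = NA_character_, skipped_reason = f$skip)
    else {
      sc <- if (f$pm < 0.05 && f$pt < 0.05) "both"
            else if (f$pm < 0.05) "maize_only"
            else if (f$pt < 0.05) "teosinte_only"
            else "neither"
      .(n_crosses = .N, r2_maize = f$r2m, r2_teosinte = f$r2t,
        p_maize = f$pm, p_teosinte = f$pt, sig_class = sc,
        skipped_reason = NA_character_)
    }
  }, by = .(gene_id, tissue)]
  data.table::setorder(res, gene_id, tissue)
  data.table::setDF(res)
  res
}

#' Ratio of mean maize to mean teosinte R-squared
#'
#' Summarizes a set of variance partitions as the ratio of the mean maize R²
#' to the mean teosinte R² (ratio of means, not mean of ratios), with a
#' standard error by the delta method or a seeded gene bootstrap.
#'
#' @param partitions Output of [variance_partition()] (fitted rows only are
#'   used).
#' @param genes Optional gene-id subset (e.g. a candidate list).
#' @param se_method `"delta"` or `"bootstrap"`.
#' @param n_boot,seed Bootstrap settings.
#' @return List with `ratio`, `se`, `n_genes`, `mean_r2_maize`,
#'   `mean_r2_teosinte`.
#' @export
r2_ratio_summary <- function(partitions, genes = NULL, se_method = "delta",
                             n_boot = 1000, seed = 1) {
  x <- partitions[is.na(partitions$skipped_reason), , drop = FALSE]
  if (!is.null(genes)) x <- x[x$gene_id %in% genes, , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 fitted genes")
  rm_ <- x$r2_maize; rt <- x$r2_teosinte
  mt <- mean(rt)
  if (mt == 0) stop("mean teosinte R-squared is zero")
  mm <- mean(rm_)
  ratio <- mm / mt
  n <- nrow(x)
  if (se_method == "delta") {
    vm <- stats::var(rm_) / n; vt <- stats::var(rt) / n
    cv <- stats::cov(rm_, rt) / n
    se <- sqrt(vm / mt^2 + mm^2 * vt / mt^4 - 2 * mm * cv / mt^3)
  } else if (se_method == "bootstrap") {
    set.seed(seed)
    bs <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      mean(rm_[idx]) / mean(rt[idx])
    }, numeric(1))
    se <- stats::sd(bs)
  } else stop("unknown se_method: ", se_method)
  list(ratio = ratio, se = se, n_genes = n,
       mean_r2_maize = mm, mean_r2_teosinte = mt)
}

#' Count genes by which parent contributes significant variance
#'
#' Tabulates the per-gene drop-one F-test outcomes (p < 0.05) into
#' maize-only / teosinte-only / both / neither counts, optionally restricted
#' to a gene list and split by tissue.
#'
#' @param partitions Output of [variance_partition()].
#' @param genes Optional gene-id subset.
#' @return Data.frame with `tissue`, `maize_only`, `teosinte_only`, `both`,
#'   `neither`.
#' @export
count_significant_parents <- function(partitions, genes = NULL) {
  x <- partitions[is.na(partitions$skipped_reason), , drop = FALSE]
  if (!is.null(genes)) x <- x[x$gene_id %in% genes, , drop = FALSE]
  lv <- c("maize_only", "teosinte_only", "both", "neither")
  tissues <- sort(unique(x$tissue))
  rows <- lapply(tissues, function(tis) {
    tab <- table(factor(x$sig_class[x$tissue == tis], levels = lv))
    cbind(data.frame(tissue = tis, stringsAsFactors = FALSE),
          as.data.frame(as.list(tab)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tissue = character(), maize_only = integer(),
                      teosinte_only = integer(), both = integer(),
                      neither = integer())
  out
}
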