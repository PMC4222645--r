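#' Additive and dominance effects for one cross
#'
#' Given library-normalized diploid expression totals of the maize parent,
#' the teosinte parent, and their F1 hybrid (sum of both allele counts),
#' computes the additive effect `a = (P_M - P_T) / 2`, the dominance effect
#' `d = F1 - (P_M + P_T) / 2` (deviation from the midparent), and the
#' dominance/additivity ratio `da = d / |a|`. With this sign convention
#' `da = +1` means the F1 matches the higher-expressing parent (complete
#' dominance of the high allele) regardless of which species is higher, and
#' `da = -1` the lower parent. `da` is invariant to multiplying all three
#' totals by a constant; it is undefined (NA) when `a = 0`.
#'
#' @param P_M,P_T,F1 Normalized expression totals (vectors allowed).
#' @return Data.frame with columns `a`, `d`, `da`.
#' @export
cross_da <- function(P_M, P_T, F1) {
  a <- (P_M - P_T) / 2
  d <- F1 - (P_M + P_T) / 2
  da <- ifelse(a == 0, NA_real_, d / abs(a))
  data.frame(a = a, d = d, da = da)
}

# Dixon Q critical values, two-sided alpha = 0.05 (95% confidence),
# staged statistic: r10 for n<=7, r11 for 8<=n<=10, r21 for 11<=n<=13,
# r22 for n>=14 (Rorabacher 1991 tables), n = 3..30.
.dixon_crit <- c(
  `3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.625, `7` = 0.568,
  `8` = 0.608, `9` = 0.564, `10` = 0.530,
  `11` = 0.619, `12` = 0.583, `13` = 0.557,
  `14` = 0.586, `15` = 0.565, `16` = 0.546, `17` = 0.529, `18` = 0.514,
  `19` = 0.501, `20` = 0.489, `21` = 0.478, `22` = 0.468, `23` = 0.459,
  `24` = 0.451, `25` = 0.443, `26` = 0.436, `27` = 0.429, `28` = 0.423,
  `29` = 0.417, `30` = 0.412)

.dixon_q <- function(x) {
  # returns Q statistics for the smallest and largest value of sorted x
  n <- length(x)
  s <- sort(x)
  if (n <= 7) {            # r10
    den <- s[n] - s[1]
    if (den == 0) return(c(low = 0, high = 0))
    c(low = (s[2] - s[1]) / den, high = (s[n] - s[n - 1]) / den)
  } else if (n <= 10) {    # r11
    dl <- s[n - 1] - s[1]; dh <- s[n] - s[2]
    c(low = if (dl == 0) 0 else (s[2] - s[1]) / dl,
      high = if (dh == 0) 0 else (s[n] - s[n - 1]) / dh)
  } else if (n <= 13) {    # r21
    dl <- s[n - 1] - s[1]; dh <- s[n] - s[2]
    c(low = if (dl == 0) 0 else (s[3] - s[1]) / dl,
      high = if (dh == 0) 0 else (s[n] - s[n - 2]) / dh)
  } else {                 # r22
    dl <- s[n - 2] - s[1]; dh <- s[n] - s[3]
    c(low = if (dl == 0) 0 else (s[3] - s[1]) / dl,
      high = if (dh == 0) 0 else (s[n] - s[n - 2]) / dh)
  }
}

#' Iterative Dixon outlier filter
#'
#' Repeatedly tests the most extreme value with the Dixon Q statistic
#' against the embedded two-sided critical-value table (alpha = 0.05,
#' n = 3..30; the staged r10/r11/r21/r22 statistic appropriate for the
#' current sample size) and removes it if rejected. Iteration stops when no
#' value is rejected or when only three values remain, so the output always
#' keeps at least three values; inputs with fewer than three values are
#' returned unfiltered. Samples larger than 30 use the n = 30 critical
#' value (conservative).
#'
#' @param x Numeric vector (NAs dropped).
#' @param alpha Significance level; only 0.05 is tabulated.
#' @return List with `retained` (numeric vector) and `n_removed`.
#' @export
dixon_filter <- function(x, alpha = 0.05) {
  if (alpha != 0.05) stop("only alpha = 0.05 critical values are embedded")
  x <- x[!is.na(x)]
  removed <- 0L
  while (length(x) > 3) {
    n <- length(x)
    q <- .dixon_q(x)
    crit <- .dixon_crit[[as.character(min(n, 30L))]]
    if (max(q) <= crit) break
    s <- sort(x)
    drop_val <- if (q["high"] >= q["low"]) s[n] else s[1]
    x <- x[-match(drop_val, x)]
    removed <- removed + 1L
  }
  list(retained = x, n_removed = removed)
}

#' Classify expression inheritance from an overall D/A ratio
#'
#' Applies the standard thresholds: additive when `|D/A| < 0.25`, dominant
#' when `0.75 < |D/A| < 1.25`, otherwise `"other"`. For dominant genes the
#' dominant allele is mapped back to a species using the consensus sign of
#' the additive effect: `da` near +1 means the F1 matches the
#' higher-expressing parent (maize if `a > 0`, else teosinte); `da` near -1
#' the lower parent.
#'
#' @param overall_da Overall (post-filter mean) D/A ratio (vector allowed).
#' @param a_sign Consensus sign of the additive effect in `{-1, 0, 1}`.
#' @return Data.frame with `inheritance_class` and `dominant_allele`
#'   (`"maize"`, `"teosinte"`, or `"none"`).
#' @export
classify_inheritance <- function(overall_da, a_sign) {
  n <- max(length(overall_da), length(a_sign))
  da <- rep_len(overall_da, n); s <- rep_len(a_sign, n)
  cls <- rep("other", n)
  cls[!is.na(da) & abs(da) < 0.25] <- "additive"
  cls[!is.na(da) & abs(da) > 0.75 & abs(da) < 1.25] <- "dominant"
  cls[is.na(da)] <- NA_character_
  allele <- rep("none", n)
  dom <- !is.na(da) & cls %in% "dominant" & s != 0
  high <- ifelse(s > 0, "maize", "teosinte")
  low <- ifelse(s > 0, "teosinte", "maize")
  allele[dom & da > 0] <- high[dom & da > 0]
  allele[dom & da < 0] <- low[dom & da < 0]
  data.frame(inheritance_class = cls, dominant_allele = allele,
             stringsAsFactors = FALSE)
}

#' Per-gene dominance analysis
#'
#' Computes per-cross additive and dominance effects from library-normalized
#' expression totals (counts scaled to a common library size of 1e6 within
#' genotype x tissue), filters outlier D/A ratios per gene with
#' [dixon_filter()], averages the retained ratios, and classifies
#' inheritance. Crosses with `a = 0` or missing normalization are skipped.
#'
#' @param ratios Per-cross records from [cross_ratios()]; only passing
#'   records are used.
#' @param alpha Dixon filter significance level.
#' @return Data.frame with one row per gene x tissue: `n_crosses`,
#'   `n_outliers_removed`, `overall_da`, `a_sign`, `inheritance_class`,
#'   `dominant_allele`.
#' @export
dominance_table <- function(ratios, alpha = 0.05) {
  dt <- data.table::as.data.table(ratios)
  dt <- dt[passes_depth == TRUE & L_m > 0 & L_t > 0 & L_h > 0]
  if (nrow(dt) == 0L) stop("no passing records")
  dt[, `:=`(PM = parent_m_raw / L_m * 1e6,
            PT = parent_t_raw / L_t * 1e6,
            F1 = (hybrid_m + hybrid_t) / L_h * 1e6)]
  res <- dt[, {
    eff <- cross_da(PM, PT, F1)
    keep <- !is.na(eff$da)
    if (!any(keep)) {
      .(n_crosses = .N, n_outliers_removed = 0L, overall_da = NA_real_,
        a_sign = 0)
    } else {
      fl <- dixon_filter(eff$da[keep], alpha)
      # consensus additive sign over crosses whose da was retained
      asign <- sign(mean(eff$a[keep][eff$da[keep] %in% fl$retained]))
      .(n_crosses = .N, n_outliers_removed = fl$n_removed,
        overall_da = mean(fl$retained), a_sign = asign)
    }
  }, by = .(gene_id, tissue)]
  cls <- classify_inheritance(res$overall_da, res$a_sign)
  res <- cbind(data.table::setDF(res), cls)
  res[order(res$gene_id, res$tissue), , drop = FALSE]
}

#' Compare dominance between cis-only and trans-only candidates
#'
#' Tests (i) whether the rate of dominant versus additive inheritance
#' differs between cis-only and trans-only gene lists (two-sided Fisher's
#' exact test on the 2x2 class x inheritance table) and (ii) whether, among
#' trans-only dominant genes, the maize and teosinte alleles are dominant
#' equally often (exact two-sided binomial test against 0.5).
#'
#' @param dom Output of [dominance_table()].
#' @param cis_genes,trans_genes Character vectors of gene ids (e.g. from
#'   [list_members()]).
#' @param tissue Optional tissue restriction.
#' @return List with `table` (2x2 counts), `fet_p`, `n_maize_dominant`,
#'   `n_teosinte_dominant`, `binom_p`, and per-class dominance proportions.
#' @export
dominance_summary <- function(dom, cis_genes, trans_genes, tissue = NULL) {
  if (length(cis_genes) == 0L || length(trans_genes) == 0L)
    stop("both gene lists must be non-empty")
  x <- dom
  if (!is.null(tissue)) x <- x[x$tissue %in% tissue, , drop = FALSE]
  pick <- function(genes) x[x$gene_id %in% genes &
                              x$inheritance_class %in%
                              c("dominant", "additive"), , drop = FALSE]
  ci <- pick(cis_genes); tr <- pick(trans_genes)
  tab <- matrix(c(sum(ci$inheritance_class == "dominant"),
                  sum(ci$inheritance_class == "additive"),
                  sum(tr$inheritance_class == "dominant"),
                  sum(tr$inheritance_class == "additive")),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("cis_only", "trans_only"),
                                c("dominant", "additive")))
  fet_p <- if (any(rowSums(tab) == 0)) NA_real_ else
    stats::fisher.test(tab)$p.value
  trd <- tr[tr$inheritance_class == "dominant", , drop = FALSE]
  nm <- sum(trd$dominant_allele == "maize")
  nt <- sum(trd$dominant_allele == "teosinte")
  binom_p <- if (nm + nt == 0) NA_real_ else binom_test_1to1(nm, nt)
  list(table = tab, fet_p = fet_p,
       prop_dominant_cis = if (nrow(ci)) tab[1, 1] / sum(tab[1, ]) else NA,
       prop_dominant_trans = if (nrow(tr)) tab[2, 1] / sum(tab[2, ]) else NA,
       n_maize_dominant = nm, n_teosinte_dominant = nt, binom_p = binom_p)
}
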