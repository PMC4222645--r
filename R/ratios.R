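#' Pool biological replicates
#'
#' Element-wise sums allele counts over replicates within each
#' (gene, tissue, genotype). A gene absent from one replicate simply
#' contributes nothing (the additive zero).
#'
#' @param counts Replicate-level allele-count data.frame
#'   (see [read_counts()] for the schema).
#' @return A data.frame with one row per (gene, tissue, genotype) and summed
#'   `maize_count`, `teosinte_count`.
#' @export
pool_replicates <- function(counts) {
  validate_counts(counts)
  dt <- data.table::as.data.table(counts)
  pooled <- dt[, .(maize_count = sum(maize_count),
                   teosinte_count = sum(teosinte_count)),
               by = .(gene_id, tissue, genotype)]
  data.table::setorder(pooled, gene_id, tissue, genotype)
  data.table::setDF(pooled)
  pooled
}

#' Correct parent counts for library-size differences
#'
#' Scales the parent with the larger library down to the smaller library:
#' its counts are multiplied by `min(L) / L` and rounded half-to-even back to
#' integers; the smaller-library parent is left unchanged. Scaling down
#' (never up) keeps the subsequent count-based tests conservative. The
#' correction is invariant to multiplying both library sizes by a constant.
#'
#' @param parent_m_raw,parent_t_raw Raw pooled own-allele counts of the maize
#'   and teosinte parent (vectors allowed).
#' @param L_m,L_t Library sizes (total allele-informative reads of the inbred
#'   in the tissue); must be positive.
#' @return A list with integer vectors `parent_m`, `parent_t`.
#' @export
correct_parent_libsize <- function(parent_m_raw, parent_t_raw, L_m, L_t) {
  if (any(L_m <= 0) || any(L_t <= 0)) stop("library sizes must be > 0")
  n <- max(length(parent_m_raw), length(parent_t_raw))
  parent_m_raw <- as.numeric(rep_len(parent_m_raw, n))
  parent_t_raw <- as.numeric(rep_len(parent_t_raw, n))
  L_m <- as.numeric(rep_len(L_m, n)); L_t <- as.numeric(rep_len(L_t, n))
  m <- ifelse(L_m > L_t, round(parent_m_raw * L_t / L_m), parent_m_raw)
  t <- ifelse(L_t > L_m, round(parent_t_raw * L_m / L_t), parent_t_raw)
  list(parent_m = as.integer(m), parent_t = as.integer(t))
}

.log2_ratio <- function(a, b) ifelse(a > 0 & b > 0, log2(a / b), NA_real_)

#' Per-cross maize:teosinte expression ratios
#'
#' Builds one record per gene x tissue x cross from pooled counts: pooled
#' hybrid allele counts, library-corrected pooled parent counts, the log2
#' hybrid ratio (the cis effect), the log2 parent ratio (cis + trans), and
#' the trans effect (parent minus hybrid log ratio). Log ratios are `NA`
#' whenever either count is zero; such records keep their counts (they still
#' enter pooled sums and count-based tests) but are excluded from effect-size
#' summaries downstream. `passes_depth` requires both the hybrid and the
#' parent comparison to reach `min_depth`.
#'
#' Crosses whose parent genotypes are absent from the counts in a tissue are
#' flagged `missing_parent` and fail the depth filter.
#'
#' @param pooled Pooled counts from [pool_replicates()].
#' @param design A [simulate_design()] object (or compatible list).
#' @param min_depth Minimum total depth required in both the hybrid and the
#'   parent comparison (default 100).
#' @return A data.frame with columns `gene_id`, `tissue`, `cross`,
#'   `maize_line`, `teosinte_line`, `hybrid_m`, `hybrid_t`, `parent_m`,
#'   `parent_t`, `parent_m_raw`, `parent_t_raw`, `L_m`, `L_t`, `L_h`,
#'   `log2_hybrid`, `log2_parent`, `trans_effect`, `depth_hybrid`,
#'   `depth_parent`, `passes_depth`, `missing_parent`.
#' @export
cross_ratios <- function(pooled, design, min_depth = 100) {
  stopifnot(min_depth >= 0)
  dt <- data.table::as.data.table(pooled)
  # library sizes per genotype x tissue (total allele-informative reads)
  libs <- dt[, .(L = sum(maize_count) + sum(teosinte_count)),
             by = .(genotype, tissue)]
  cr <- design$crosses
  out <- vector("list", nrow(cr))
  for (i in seq_len(nrow(cr))) {
    M <- cr$maize_line[i]; T_ <- cr$teosinte_line[i]; g <- cr$cross[i]
    hy <- dt[genotype == g,
             .(gene_id, tissue, hybrid_m = maize_count,
               hybrid_t = teosinte_count)]
    if (nrow(hy) == 0L) next
    pm <- dt[genotype == M, .(gene_id, tissue, parent_m_raw = maize_count)]
    pt <- dt[genotype == T_, .(gene_id, tissue, parent_t_raw = teosinte_count)]
    rec <- merge(merge(hy, pm, by = c("gene_id", "tissue"), all.x = TRUE),
                 pt, by = c("gene_id", "tissue"), all.x = TRUE)
    Lm <- libs[genotype == M][rec, on = "tissue"]$L
    Lt <- libs[genotype == T_][rec, on = "tissue"]$L
    Lh <- libs[genotype == g][rec, on = "tissue"]$L
    rec[, `:=`(cross = g, maize_line = M, teosinte_line = T_,
               L_m = Lm, L_t = Lt, L_h = Lh)]
    miss <- is.na(rec$parent_m_raw) | is.na(rec$parent_t_raw) |
      is.na(Lm) | is.na(Lt)
    rec$missing_parent <- miss
    rec$parent_m_raw[is.na(rec$parent_m_raw)] <- 0L
    rec$parent_t_raw[is.na(rec$parent_t_raw)] <- 0L
    ok <- !miss
    pm_c <- rec$parent_m_raw; pt_c <- rec$parent_t_raw
    if (any(ok)) {
      corr <- correct_parent_libsize(rec$parent_m_raw[ok],
                                     rec$parent_t_raw[ok],
                                     rec$L_m[ok], rec$L_t[ok])
      pm_c[ok] <- corr$parent_m; pt_c[ok] <- corr$parent_t
    }
    rec[, `:=`(parent_m = pm_c, parent_t = pt_c)]
    out[[i]] <- rec
  }
  res <- data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(res) == 0L) stop("no hybrid genotypes found in counts")
  res[, `:=`(depth_hybrid = hybrid_m + hybrid_t,
             depth_parent = parent_m + parent_t)]
  res[, `:=`(log2_hybrid = .log2_ratio(hybrid_m, hybrid_t),
             log2_parent = .log2_ratio(parent_m, parent_t))]
  res[, trans_effect := log2_parent - log2_hybrid]
  res[, passes_depth := !missing_parent & depth_hybrid >= min_depth &
        depth_parent >= min_depth]
  data.table::setcolorder(res, c("gene_id", "tissue", "cross", "maize_line",
                                 "teosinte_line", "hybrid_m", "hybrid_t",
                                 "parent_m", "parent_t"))
  data.table::setorder(res, gene_id, tissue, cross)
  data.table::setDF(res)
  res
}

#' Overall maize:teosinte expression ratios
#'
#' Aggregates the per-cross records of [cross_ratios()] into one record per
#' gene x tissue, using only crosses that pass the depth filter. The hybrid
#' side is a plain sum of hybrid allele counts over passing crosses. On the
#' parent side each inbred's raw pooled count enters exactly once (never once
#' per cross): counts are scaled to the smallest library size among the
#' inbreds involved in the gene's passing crosses and combined with weights
#' equal to the number of passing crosses the inbred participates in.
#' Because every cross contributes weight 1 to exactly one maize and one
#' teosinte line, both sides carry equal total weight by construction and the
#' weighted ratio is directly comparable. Finally both weighted sums are
#' rescaled by a common factor so that their total equals the once-counted
#' (unweighted) scaled read total, then rounded to integers: the ratio is the
#' weighted ratio, while the total depth reflects the number of distinct
#' parent reads actually observed, so downstream count-based tests are not
#' fed artificially multiplied evidence.
#'
#' @param ratios Per-cross records from [cross_ratios()].
#' @return A data.frame with columns `gene_id`, `tissue`, `sum_hybrid_m`,
#'   `sum_hybrid_t`, `wsum_parent_m`, `wsum_parent_t`, `n_crosses_used`,
#'   `n_unique_maize`, `n_unique_teosinte`, `log2_hybrid_overall`,
#'   `log2_parent_overall`. Genes with no passing cross are absent.
#' @export
overall_ratios <- function(ratios) {
  dt <- data.table::as.data.table(ratios)
  dt <- dt[passes_depth == TRUE]
  if (nrow(dt) == 0L)
    return(data.frame(gene_id = character(), tissue = character(),
                      sum_hybrid_m = integer(), sum_hybrid_t = integer(),
                      wsum_parent_m = integer(), wsum_parent_t = integer(),
                      n_crosses_used = integer(), n_unique_maize = integer(),
                      n_unique_teosinte = integer(),
                      log2_hybrid_overall = numeric(),
                      log2_parent_overall = numeric()))
  agg <- dt[, {
    Lmin <- min(c(L_m, L_t))
    mline <- data.table::data.table(line = maize_line,
                                    cnt = as.numeric(parent_m_raw),
                                    L = as.numeric(L_m))
    msum <- mline[, .(w = .N, cnt = cnt[1], L = L[1]), by = line]
    tline <- data.table::data.table(line = teosinte_line,
                                    cnt = as.numeric(parent_t_raw),
                                    L = as.numeric(L_t))
    tsum <- tline[, .(w = .N, cnt = cnt[1], L = L[1]), by = line]
    wm <- sum(msum$w * msum$cnt * Lmin / msum$L)
    wt <- sum(tsum$w * tsum$cnt * Lmin / tsum$L)
    once <- sum(msum$cnt * Lmin / msum$L) + sum(tsum$cnt * Lmin / tsum$L)
    if (wm + wt > 0) {
      s <- once / (wm + wt)
      wm <- wm * s; wt <- wt * s
    }
    .(sum_hybrid_m = sum(hybrid_m), sum_hybrid_t = sum(hybrid_t),
      wsum_parent_m = as.integer(round(wm)),
      wsum_parent_t = as.integer(round(wt)),
      n_crosses_used = .N,
      n_unique_maize = data.table::uniqueN(maize_line),
      n_unique_teosinte = data.table::uniqueN(teosinte_line))
  }, by = .(gene_id, tissue)]
  agg[, `:=`(log2_hybrid_overall = .log2_ratio(sum_hybrid_m, sum_hybrid_t),
             log2_parent_overall = .log2_ratio(wsum_parent_m, wsum_parent_t))]
  data.table::setorder(agg, gene_id, tissue)
  data.table::setDF(agg)
  agg
}
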