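#' Coverage filter for candidate genes
#'
#' A gene (x tissue) passes when it was assayed in at least `min_crosses`
#' passing F1 crosses involving at least `min_maize` distinct maize and
#' `min_teosinte` distinct teosinte inbreds. Defaults mirror the standard
#' candidate filter (15 crosses, 3 maize, 5 teosinte).
#'
#' @param n_crosses,n_unique_maize,n_unique_teosinte Per-gene coverage counts
#'   (vectors allowed), e.g. columns of [overall_ratios()].
#' @param min_crosses,min_maize,min_teosinte Thresholds.
#' @return Logical vector.
#' @export
coverage_filter <- function(n_crosses, n_unique_maize, n_unique_teosinte,
                            min_crosses = 15, min_maize = 3,
                            min_teosinte = 5) {
  n_crosses >= min_crosses & n_unique_maize >= min_maize &
    n_unique_teosinte >= min_teosinte
}

.tier_of <- function(consistency, thresholds = c(A = 1.0, B = 0.9, C = 0.8)) {
  out <- rep("none", length(consistency))
  out[consistency >= thresholds["C"]] <- "C"
  out[consistency >= thresholds["B"]] <- "B"
  out[consistency >= thresholds["A"] - 1e-12] <- "A"
  out
}

#' Depth-weighted directional consistency per gene
#'
#' For each gene x tissue, computes the fraction of total hybrid read depth
#' carried by maize-biased crosses among all passing crosses:
#' `weighted_maize_fraction = sum(depth of crosses with hybrid_m > hybrid_t) /
#' sum(depth of all passing crosses)`. Crosses with exactly 1:1 hybrid counts
#' contribute depth to the denominator only. Consistency is
#' `max(f, 1 - f)` and is mapped to tier A / B / C at thresholds 1.0 / 0.9 /
#' 0.8 (tier A genes also satisfy B and C); the favored allele is the
#' direction with the larger weighted fraction.
#'
#' @param ratios Per-cross records from [cross_ratios()]; only rows with
#'   `passes_depth` are used.
#' @return A data.frame with `gene_id`, `tissue`, `n_crosses`,
#'   `n_unique_maize`, `n_unique_teosinte`, `weighted_maize_fraction`,
#'   `consistency`, `tier`, `favored_allele`.
#' @export
consistency_tier <- function(ratios) {
  dt <- data.table::as.data.table(ratios)
  dt <- dt[passes_depth == TRUE]
  if (nrow(dt) == 0L) stop("no passing cross records")
  cons <- dt[, {
    tot <- sum(depth_hybrid)
    if (tot == 0) stop("zero total hybrid depth for gene ", gene_id[1])
    f <- sum(depth_hybrid[hybrid_m > hybrid_t]) / tot
    .(n_crosses = .N,
      n_unique_maize = data.table::uniqueN(maize_line),
      n_unique_teosinte = data.table::uniqueN(teosinte_line),
      weighted_maize_fraction = f)
  }, by = .(gene_id, tissue)]
  cons[, consistency := pmax(weighted_maize_fraction,
                             1 - weighted_maize_fraction)]
  cons[, tier := .tier_of(consistency)]
  cons[, favored_allele := ifelse(weighted_maize_fraction >= 0.5,
                                  "maize", "teosinte")]
  data.table::setorder(cons, gene_id, tissue)
  data.table::setDF(cons)
  cons
}

#' Build CCT, cis-only and trans-only candidate lists
#'
#' Combines regulatory calls with consistency records into tiered candidate
#' membership. List classes: `CCT` (categories cis or cis+trans — candidates
#' for direct selection on expression), `cis_only` (category cis) and
#' `trans_only` (category trans). Genes must pass the coverage filter; tier
#' is the consistency tier. The returned membership table has one row per
#' gene x tissue x list class the gene belongs to, with tier `"none"` rows
#' retained so callers can apply their own tier cuts; use
#' [list_members()] for tier-filtered per-tissue or union gene sets.
#'
#' @param calls `calls` data.frame from [classify_all()].
#' @param consistency Data.frame from [consistency_tier()].
#' @param min_crosses,min_maize,min_teosinte Coverage thresholds (see
#'   [coverage_filter()]).
#' @return Membership data.frame: `gene_id`, `tissue`, `list_class`, `tier`,
#'   `favored_allele`, `weighted_maize_fraction`, `consistency`.
#' @export
build_lists <- function(calls, consistency, min_crosses = 15, min_maize = 3,
                        min_teosinte = 5) {
  ca <- data.table::as.data.table(calls)
  co <- data.table::as.data.table(consistency)
  co <- co[coverage_filter(n_crosses, n_unique_maize, n_unique_teosinte,
                           min_crosses, min_maize, min_teosinte)]
  mem <- merge(ca[, .(gene_id, tissue, category)], co,
               by = c("gene_id", "tissue"))
  if (nrow(mem) == 0L)
    return(data.frame(gene_id = character(), tissue = character(),
                      list_class = character(), tier = character(),
                      favored_allele = character(),
                      weighted_maize_fraction = numeric(),
                      consistency = numeric()))
  pieces <- list(
    CCT = mem[category %in% c("cis", "cis_plus_trans")],
    cis_only = mem[category == "cis"],
    trans_only = mem[category == "trans"])
  out <- data.table::rbindlist(lapply(names(pieces), function(nm) {
    x <- pieces[[nm]]
    if (nrow(x) == 0L) return(NULL)
    x[, .(gene_id, tissue, list_class = nm, tier, favored_allele,
          weighted_maize_fraction, consistency)]
  }))
  data.table::setorder(out, list_class, gene_id, tissue)
  data.table::setDF(out)
  out
}

#' Extract tier-filtered gene sets from a membership table
#'
#' @param membership Output of [build_lists()].
#' @param list_class One of `"CCT"`, `"cis_only"`, `"trans_only"`.
#' @param tiers Tiers to keep, e.g. `c("A", "B")` for the AB list.
#' @param tissue Optional tissue; `NULL` returns the union across tissues
#'   (a gene qualifies if it is on the list in at least one tissue).
#' @return Character vector of gene ids.
#' @export
list_members <- function(membership, list_class = "CCT",
                         tiers = c("A", "B", "C"), tissue = NULL) {
  x <- membership[membership$list_class == list_class &
                    membership$tier %in% tiers, , drop = FALSE]
  if (!is.null(tissue)) x <- x[x$tissue %in% tissue, , drop = FALSE]
  sort(unique(x$gene_id))
}

#' Per-tissue overlap counts of a candidate list
#'
#' Counts, for each combination of tissues, the genes on the (tier-filtered)
#' list in exactly that combination — the Venn-diagram compartments.
#'
#' @inheritParams list_members
#' @return Data.frame with `tissues` (label like `"ear+leaf"`) and `n_genes`.
#' @export
list_overlap <- function(membership, list_class = "CCT",
                         tiers = c("A", "B", "C")) {
  x <- membership[membership$list_class == list_class &
                    membership$tier %in% tiers, , drop = FALSE]
  if (nrow(x) == 0L) return(data.frame(tissues = character(),
                                       n_genes = integer()))
  sp <- split(x$tissue, x$gene_id)
  lab <- vapply(sp, function(ts) paste(sort(unique(ts)), collapse = "+"),
                character(1))
  tab <- table(lab)
  data.frame(tissues = names(tab), n_genes = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Directional bias of a candidate list
#'
#' Counts genes favoring the maize versus the teosinte allele and tests the
#' split against a 50:50 expectation with an exact two-sided binomial test.
#'
#' @param membership Output of [build_lists()], already subset as desired
#'   (e.g. one tissue, one list class, chosen tiers).
#' @return List with `n_maize_biased`, `n_teosinte_biased`, `p_value`.
#' @export
directional_bias_test <- function(membership) {
  if (nrow(membership) == 0L) stop("empty candidate list")
  u <- membership[!duplicated(membership$gene_id), , drop = FALSE]
  nm <- sum(u$favored_allele == "maize")
  nt <- sum(u$favored_allele == "teosinte")
  list(n_maize_biased = nm, n_teosinte_biased = nt,
       p_value = binom_test_1to1(nm, nt))
}

#' Reference-line alignment-bias check
#'
#' Tests whether the maize-allele bias of candidate genes is stronger in F1s
#' involving the reference maize line (whose reads align perfectly to the
#' reference) than in non-reference F1s — the expected signature of
#' systematic alignment bias. For each gene, hybrid counts are pooled
#' separately over passing crosses that involve the reference line and those
#' that do not; each subset with a non-tied pooled ratio contributes one
#' maize- or teosinte-biased call to a 2x2 table
#' (rows reference / non-reference F1s, columns teosinte- / maize-biased),
#' which is tested with a two-sided Fisher's exact test.
#'
#' @param ratios Per-cross records from [cross_ratios()].
#' @param genes Character vector of candidate gene ids.
#' @param reference_line Maize line name (default `"B73"`).
#' @param tissue Single tissue to analyze.
#' @return List with `table` (2x2 matrix) and `p_value`.
#' @export
reference_bias_check <- function(ratios, genes, reference_line = "B73",
                                 tissue) {
  tis <- tissue
  dt <- data.table::as.data.table(ratios)
  dt <- dt[passes_depth == TRUE & gene_id %in% genes & tissue == tis]
  if (nrow(dt) == 0L) stop("no passing records for the given genes/tissue")
  if (!any(dt$maize_line == reference_line))
    stop("no crosses involving reference line '", reference_line, "'")
  bias <- dt[, .(ref = .SD[maize_line == reference_line,
                           sign(sum(hybrid_m) - sum(hybrid_t))],
                 nonref = .SD[maize_line != reference_line,
                              sign(sum(hybrid_m) - sum(hybrid_t))]),
             by = gene_id]
  tab <- matrix(c(sum(bias$ref %in% -1), sum(bias$ref %in% 1),
                  sum(bias$nonref %in% -1), sum(bias$nonref %in% 1)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("reference_F1s", "nonreference_F1s"),
                                c("teosinte_biased", "maize_biased")))
  p <- if (any(rowSums(tab) == 0)) NA_real_ else
    stats::fisher.test(tab)$p.value
  list(table = tab, p_value = p)
}
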