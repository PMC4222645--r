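#' Gene-set overlap enrichment by Fisher's exact test
#'
#' Hypergeometric (Fisher's exact) test of the overlap between a candidate
#' gene list and an annotation gene set within a stated universe, on the 2x2
#' table `[[in both, list only], [set only, neither]]`. The expected overlap
#' is the margin product `|list| * |set| / |universe|`. One-tailed
#' (`sided = "greater"`, enrichment) by default; `"two.sided"` also tests
#' depletion.
#'
#' @param list_genes,set_genes Character vectors of gene ids; elements
#'   outside `universe` are dropped.
#' @param universe Character vector of all assayed genes; must be non-empty.
#' @param sided `"greater"` or `"two.sided"`.
#' @param name Optional label for the result row.
#' @return One-row data.frame: `set_name`, `universe_size`, `list_size`,
#'   `set_size`, `observed`, `expected`, `odds_ratio`, `p_value`.
#' @export
set_overlap_fet <- function(list_genes, set_genes, universe,
                            sided = c("greater", "two.sided"),
                            name = NA_character_) {
  sided <- match.arg(sided)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  l <- unique(intersect(list_genes, universe))
  s <- unique(intersect(set_genes, universe))
  both <- length(intersect(l, s))
  tab <- matrix(c(both, length(l) - both,
                  length(s) - both,
                  length(universe) - length(l) - length(s) + both),
                nrow = 2)
  ft <- stats::fisher.test(tab, alternative = sided)
  data.frame(set_name = name, universe_size = length(universe),
             list_size = length(l), set_size = length(s), observed = both,
             expected = length(l) * length(s) / length(universe),
             odds_ratio = unname(ft$estimate), p_value = ft$p.value,
             stringsAsFactors = FALSE)
}

#' Compare selection-scan score distributions between gene groups
#'
#' Compares XPCLR (or any positive selection-scan) scores of candidate genes
#' against a background group (typically conserved genes) on the natural-log
#' scale, with a two-sample Kolmogorov-Smirnov test (distribution shape) and
#' a Welch t-test (mean shift). Non-positive scores are excluded with a
#' warning.
#'
#' @param scores_list,scores_bg Numeric score vectors for the candidate and
#'   background groups; each needs at least 2 positive values.
#' @return List with `ks_p`, `t_p`, `mean_ln_list`, `mean_ln_bg`, `n_list`,
#'   `n_bg`.
#' @export
xpclr_compare <- function(scores_list, scores_bg) {
  clean <- function(x, lab) {
    bad <- is.na(x) | x <= 0
    if (any(bad)) warning(sum(bad), " non-positive/missing ", lab,
                          " score(s) excluded")
    x[!bad]
  }
  a <- log(clean(scores_list, "candidate"))
  b <- log(clean(scores_bg, "background"))
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 positive scores")
  ks <- suppressWarnings(stats::ks.test(a, b))
  tt <- stats::t.test(a, b)
  list(ks_p = ks$p.value, t_p = tt$p.value,
       mean_ln_list = mean(a), mean_ln_bg = mean(b),
       n_list = length(a), n_bg = length(b))
}

#' QTL-interval enrichment of a candidate list
#'
#' Tests, trait by trait, whether a candidate list is enriched among the
#' genes inside QTL support intervals. Intervals containing more than
#' `max_genes` genes are dropped (large intervals carry little positional
#' information); the surviving intervals' gene memberships are unioned per
#' trait and tested with [set_overlap_fet()]. P-values are Bonferroni
#' corrected over traits.
#'
#' @param list_genes Character vector of candidate gene ids.
#' @param qtl Data.frame with columns `trait`, `qtl_id`, `gene_id` (one row
#'   per gene per interval).
#' @param universe Character vector of assayed genes.
#' @param max_genes Maximum interval size in genes (default 20).
#' @param sided Tail, as in [set_overlap_fet()].
#' @return Data.frame with one row per surviving trait: the
#'   [set_overlap_fet()] columns plus `n_intervals` and `p_bonferroni`.
#'   Traits with no surviving interval are skipped.
#' @export
qtl_enrichment <- function(list_genes, qtl, universe, max_genes = 20,
                           sided = "greater") {
  stopifnot(all(c("trait", "qtl_id", "gene_id") %in% names(qtl)))
  sz <- stats::aggregate(gene_id ~ trait + qtl_id, qtl,
                         function(g) length(unique(g)))
  keep <- sz[sz$gene_id <= max_genes, c("trait", "qtl_id")]
  q <- merge(qtl, keep, by = c("trait", "qtl_id"))
  traits <- sort(unique(q$trait))
  rows <- lapply(traits, function(tr) {
    sub <- q[q$trait == tr, , drop = FALSE]
    r <- set_overlap_fet(list_genes, unique(sub$gene_id), universe,
                         sided = sided, name = tr)
    r$n_intervals <- length(unique(sub$qtl_id))
    r
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$p_bonferroni <- p_adjust(out$p_value, "bonferroni")
  out
}

#' Agreement between allelic expression bias and methylation direction
#'
#' For genes near differentially methylated regions (DMRs), asks how often
#' the higher-expressed allele is the hypomethylated one, and whether the
#' candidate list is over-represented among DMR-neighbor genes at all.
#'
#' @param membership Candidate membership rows (with `gene_id` and
#'   `favored_allele`), e.g. a subset of [build_lists()] output.
#' @param dmr Data.frame with `gene_id` and `hypomethylated_allele`
#'   (`"maize"` / `"teosinte"`).
#' @param universe Character vector of assayed genes for the overlap FET.
#' @return List with `n_compared`, `agreement` (fraction, NA when the
#'   intersection is empty) and `overlap` (the [set_overlap_fet()] row).
#' @export
dmr_agreement <- function(membership, dmr, universe) {
  stopifnot(all(c("gene_id", "hypomethylated_allele") %in% names(dmr)))
  u <- membership[!duplicated(membership$gene_id), , drop = FALSE]
  mrg <- merge(u[, c("gene_id", "favored_allele")],
               dmr[, c("gene_id", "hypomethylated_allele")], by = "gene_id")
  agree <- if (nrow(mrg) == 0L) NA_real_ else
    mean(mrg$favored_allele == mrg$hypomethylated_allele)
  ov <- set_overlap_fet(unique(u$gene_id), unique(dmr$gene_id), universe,
                        sided = "greater", name = "DMR_neighbors")
  list(n_compared = nrow(mrg), agreement = agree, overlap = ov)
}

#' Multiple-testing correction
#'
#' Thin wrapper over [stats::p.adjust()] restricted to the two corrections
#' used in this pipeline: Benjamini-Hochberg step-up FDR (`"BH"`) and
#' Bonferroni.
#'
#' @param p Vector of p-values.
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values.
#' @export
p_adjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = method)
}

#' Read gene sets from a two-column TSV
#'
#' Expects columns `set_name` and `gene_id` (header required); returns a
#' named list of gene-id vectors.
#'
#' @param path TSV file path.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("set_name", "gene_id") %in% names(x)))
  lapply(split(x$gene_id, x$set_name), unique)
}
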