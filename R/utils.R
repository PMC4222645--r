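#' Write a table as tab-separated values
#'
#' Deterministic TSV writer used for every pipeline output: header row, no
#' quoting, no row names, 15 significant digits for numerics.
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(v) formatC(v, digits = 15, format = "g"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read an allele-specific count table
#'
#' Reads a TSV with columns `gene_id`, `tissue`, `genotype`, `replicate`,
#' `maize_count`, `teosinte_count` and validates the schema: counts must be
#' non-negative integers and (gene, tissue, genotype, replicate) unique.
#'
#' @param path TSV file path.
#' @return A validated data.frame.
#' @export
read_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_counts(x)
  x
}

#' @rdname read_counts
#' @param x A count data.frame (as from [simulate_counts()]).
#' @export
validate_counts <- function(x) {
  need <- c("gene_id", "tissue", "genotype", "replicate",
            "maize_count", "teosinte_count")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("count table missing column(s): ", paste(miss, collapse = ", "))
  for (cc in c("maize_count", "teosinte_count")) {
    v <- x[[cc]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop(cc, " must be non-negative integers; first bad row: ", bad[1])
  }
  key <- paste(x$gene_id, x$tissue, x$genotype, x$replicate)
  if (anyDuplicated(key))
    stop("duplicate (gene, tissue, genotype, replicate) rows, e.g. row ",
         which(duplicated(key))[1])
  invisible(x)
}
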