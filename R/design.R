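#' Simulate a maize x teosinte crossing design
#'
#' Draws a set of distinct maize x teosinte F1 crosses from the full factorial
#' grid, together with per-genotype biological replicate counts and a set of
#' tissue labels. The default arguments reproduce the structure of a typical
#' domestication ASE panel: 6 maize inbreds, 9 teosinte inbreds, 29 of the 54
#' possible F1 hybrids, three tissues, and an average of 1.96 biological
#' replicates per genotype.
#'
#' When `n_crosses` is at least `max(n_maize, n_teosinte)` the sampler
#' guarantees that every parental line participates in at least one cross
#' (as in the real panel, where all lines were used); remaining crosses are
#' drawn uniformly without replacement.
#'
#' @param n_maize Number of maize inbred lines. The first line is named
#'   `"B73"` (the reference line), remaining lines `"MZ02"`, `"MZ03"`, ...
#' @param n_teosinte Number of teosinte inbred lines, named `"TIL01"`, ...
#' @param n_crosses Number of distinct F1 crosses; must not exceed
#'   `n_maize * n_teosinte`.
#' @param tissues Character vector of tissue labels.
#' @param replicate_mean Target mean number of biological replicates per
#'   genotype; replicate counts are drawn as `1 + Poisson(replicate_mean - 1)`
#'   so every genotype has at least one replicate and the mean matches.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#'
#' @return An object of class `cross_design`: a list with elements
#'   `maize_lines`, `teosinte_lines`, `crosses` (data.frame with columns
#'   `maize_line`, `teosinte_line`, `cross`), `replicates` (named integer
#'   vector over all genotypes), and `tissues`.
#' @export
#' @examples
#' d <- simulate_design(seed = 1)
#' nrow(d$crosses)
simulate_design <- function(n_maize = 6, n_teosinte = 9, n_crosses = 29,
                            tissues = c("ear", "leaf", "stem"),
                            replicate_mean = 1.96, seed = NULL) {
  stopifnot(n_maize >= 1, n_teosinte >= 1, n_crosses >= 1,
            length(tissues) >= 1, replicate_mean >= 1)
  if (n_crosses > n_maize * n_teosinte)
    stop("n_crosses (", n_crosses, ") exceeds the ", n_maize, " x ",
         n_teosinte, " cross grid")
  if (!is.null(seed)) set.seed(seed)

  maize_lines <- c("B73", if (n_maize > 1) sprintf("MZ%02d", 2:n_maize))
  teosinte_lines <- sprintf("TIL%02d", seq_len(n_teosinte))

  grid <- expand.grid(maize_line = maize_lines, teosinte_line = teosinte_lines,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (n_crosses == nrow(grid)) {
    picked <- seq_len(nrow(grid))
  } else if (n_crosses >= max(n_maize, n_teosinte)) {
    # cover every line first, then fill at random
    m_perm <- sample(maize_lines)
    t_perm <- sample(teosinte_lines)
    k <- max(n_maize, n_teosinte)
    seedpairs <- data.frame(
      maize_line = m_perm[(seq_len(k) - 1L) %% n_maize + 1L],
      teosinte_line = t_perm[(seq_len(k) - 1L) %% n_teosinte + 1L],
      stringsAsFactors = FALSE)
    idx <- match(paste(seedpairs$maize_line, seedpairs$teosinte_line),
                 paste(grid$maize_line, grid$teosinte_line))
    idx <- unique(idx)
    rest <- setdiff(seq_len(nrow(grid)), idx)
    need <- n_crosses - length(idx)
    picked <- c(idx, sample(rest, need))
  } else {
    picked <- sample(nrow(grid), n_crosses)
  }
  crosses <- grid[sort(picked), , drop = FALSE]
  rownames(crosses) <- NULL
  crosses$cross <- paste0(crosses$maize_line, "x", crosses$teosinte_line)

  genotypes <- c(maize_lines, teosinte_lines, crosses$cross)
  reps <- 1L + stats::rpois(length(genotypes), replicate_mean - 1)
  names(reps) <- genotypes

  structure(list(maize_lines = maize_lines, teosinte_lines = teosinte_lines,
                 crosses = crosses, replicates = reps, tissues = tissues),
            class = "cross_design")
}

#' @export
print.cross_design <- function(x, ...) {
  cat("cross_design:", length(x$maize_lines), "maize x",
      length(x$teosinte_lines), "teosinte lines,",
      nrow(x$crosses), "F1 crosses,", length(x$tissues), "tissue(s)\n")
  cat("mean replicates:", round(mean(x$replicates), 2), "\n")
  invisible(x)
}

#' Validate a cross design
#'
#' Checks the structural invariants of a [simulate_design()] object: crosses
#' are unique pairs referencing declared lines, and replicate counts are
#' positive integers covering every genotype.
#'
#' @param design A `cross_design` object.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  cr <- design$crosses
  if (anyDuplicated(cr$cross)) stop("duplicate crosses in design")
  if (!all(cr$maize_line %in% design$maize_lines))
    stop("cross references undeclared maize line")
  if (!all(cr$teosinte_line %in% design$teosinte_lines))
    stop("cross references undeclared teosinte line")
  genos <- c(design$maize_lines, design$teosinte_lines, cr$cross)
  if (!all(genos %in% names(design$replicates)))
    stop("replicate counts missing for some genotypes")
  if (any(design$replicates < 1)) stop("replicate counts must be >= 1")
  invisible(TRUE)
}

#' Write / read a cross design as YAML
#'
#' @param design A `cross_design` object.
#' @param path Output file path.
#' @return `write_design` returns `path` invisibly; `read_design` returns the
#'   `cross_design`.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  obj <- list(maize_lines = design$maize_lines,
              teosinte_lines = design$teosinte_lines,
              crosses = lapply(seq_len(nrow(design$crosses)), function(i)
                list(maize_line = design$crosses$maize_line[i],
                     teosinte_line = design$crosses$teosinte_line[i])),
              replicates = as.list(design$replicates),
              tissues = design$tissues)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  obj <- yaml::read_yaml(path)
  crosses <- do.call(rbind, lapply(obj$crosses, function(p)
    data.frame(maize_line = p$maize_line, teosinte_line = p$teosinte_line,
               stringsAsFactors = FALSE)))
  crosses$cross <- paste0(crosses$maize_line, "x", crosses$teosinte_line)
  reps <- vapply(obj$replicates, as.integer, integer(1))
  d <- structure(list(maize_lines = obj$maize_lines,
                      teosinte_lines = obj$teosinte_lines,
                      crosses = crosses, replicates = reps,
                      tissues = obj$tissues),
                 class = "cross_design")
  validate_design(d)
  d
}
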