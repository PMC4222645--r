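#' Simulation parameters for synthetic allele-specific counts
#'
#' Bundles and validates the knobs of the synthetic-data generator. The seven
#' regulatory truth categories are `cis`, `trans`, `cis_plus_trans`,
#' `cis_x_trans`, `compensatory` and `conserved` (`ambiguous` is never planted;
#' it can only arise from test outcomes downstream).
#'
#' Effect magnitudes are drawn as `scale * (1 + |N(0, 0.5)|)` with a random
#' sign, so `cis_effect_scale` / `trans_effect_scale` are guaranteed lower
#' bounds on the magnitude of planted non-zero effects (in log2 units).
#' Line-level cis deviations model the allelic series within each species:
#' maize deviations have standard deviation `sigma_cis_maize`, teosinte
#' deviations `sigma_cis_teosinte`; the maize side defaults to less variance,
#' reflecting the domestication bottleneck.
#'
#' @param n_genes Number of genes.
#' @param category_mix Named numeric vector of category proportions; must sum
#'   to 1 and use only planted category names.
#' @param cis_effect_scale,trans_effect_scale Minimum magnitude (log2 units)
#'   of planted cis / trans effects.
#' @param sigma_cis_maize,sigma_cis_teosinte SD (log2) of per-line cis
#'   deviations on the maize / teosinte side.
#' @param mean_depth Expected allele-informative read depth per gene per
#'   hybrid library.
#' @param dispersion Negative-binomial dispersion alpha (variance
#'   `mu + alpha * mu^2`); 0 degenerates to Poisson.
#' @param libsize_cv Coefficient of variation of per-library size factors
#'   (log-normal, mean 1).
#' @param seed Integer seed used by [simulate_truth()] and
#'   [simulate_counts()].
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 2000,
                       category_mix = c(conserved = 0.30, cis = 0.15,
                                        trans = 0.20, cis_plus_trans = 0.10,
                                        cis_x_trans = 0.10,
                                        compensatory = 0.15),
                       cis_effect_scale = 0.75, trans_effect_scale = 0.75,
                       sigma_cis_maize = 0.23, sigma_cis_teosinte = 0.25,
                       mean_depth = 300, dispersion = 0.05,
                       libsize_cv = 0.25, seed = 1L) {
  cats <- c("cis", "trans", "cis_plus_trans", "cis_x_trans",
            "compensatory", "conserved")
  stopifnot(n_genes >= 1, mean_depth > 0, dispersion >= 0, libsize_cv >= 0,
            cis_effect_scale >= 0, trans_effect_scale >= 0,
            sigma_cis_maize >= 0, sigma_cis_teosinte >= 0)
  if (is.null(names(category_mix)) || !all(names(category_mix) %in% cats))
    stop("category_mix names must be among: ", paste(cats, collapse = ", "))
  if (abs(sum(category_mix) - 1) > 1e-9)
    stop("category_mix must sum to 1")
  structure(list(n_genes = as.integer(n_genes), category_mix = category_mix,
                 cis_effect_scale = cis_effect_scale,
                 trans_effect_scale = trans_effect_scale,
                 sigma_cis_maize = sigma_cis_maize,
                 sigma_cis_teosinte = sigma_cis_teosinte,
                 mean_depth = mean_depth, dispersion = dispersion,
                 libsize_cv = libsize_cv, seed = as.integer(seed)),
            class = "sim_params")
}

# signed effect magnitudes: scale is a guaranteed lower bound
.draw_effect <- function(n, scale) {
  if (scale == 0) return(rep(0, n))
  mag <- scale * (1 + abs(stats::rnorm(n, 0, 0.5)))
  mag * sample(c(-1, 1), n, replace = TRUE)
}

#' Plant regulatory truth for a synthetic panel
#'
#' Assigns each gene x tissue a regulatory category drawn from
#' `params$category_mix` and plants base cis (`c`) and trans (`t`) effects
#' (log2 allelic-ratio units) obeying the category constraints: conserved has
#' `c = t = 0`; cis-only `t = 0`; trans-only `c = 0`; compensatory `t = -c`;
#' cis+trans same signs; cis x trans opposite signs. Per-line cis deviations
#' are drawn independently per gene x tissue with species-specific SDs.
#'
#' @param design A [simulate_design()] object.
#' @param params A [sim_params()] object.
#' @return A list of class `sim_truth` with data.frames `truth`
#'   (`gene_id`, `tissue`, `category`, `cis_effect`, `trans_effect`) and
#'   `line_dev` (`gene_id`, `tissue`, `line`, `dev`).
#' @export
simulate_truth <- function(design, params) {
  validate_design(design)
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  genes <- sprintf("gene%05d", seq_len(params$n_genes))
  base <- expand.grid(gene_id = genes, tissue = design$tissues,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(base)
  mix <- params$category_mix
  base$category <- sample(names(mix), n, replace = TRUE, prob = mix)

  cis <- .draw_effect(n, params$cis_effect_scale)
  trans <- .draw_effect(n, params$trans_effect_scale)
  cat <- base$category
  cis[cat %in% c("trans", "conserved")] <- 0
  trans[cat %in% c("cis", "conserved")] <- 0
  trans[cat == "compensatory"] <- -cis[cat == "compensatory"]
  same <- cat == "cis_plus_trans"
  trans[same] <- sign(cis[same]) * abs(trans[same])
  opp <- cat == "cis_x_trans"
  trans[opp] <- -sign(cis[opp]) * abs(trans[opp])
  base$cis_effect <- cis
  base$trans_effect <- trans

  lines <- c(design$maize_lines, design$teosinte_lines)
  sds <- c(rep(params$sigma_cis_maize, length(design$maize_lines)),
           rep(params$sigma_cis_teosinte, length(design$teosinte_lines)))
  ld <- expand.grid(gene_id = genes, tissue = design$tissues, line = lines,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sd_of <- sds[match(ld$line, lines)]
  ld$dev <- stats::rnorm(nrow(ld), 0, 1) * sd_of

  structure(list(truth = base, line_dev = ld), class = "sim_truth")
}

.rnb <- function(n, mu, alpha) {
  if (alpha <= 0) stats::rpois(n, mu) else
    stats::rnbinom(n, size = 1 / alpha, mu = mu)
}

#' Simulate replicate-level allele-specific read counts
#'
#' Generates the count table the downstream pipeline consumes. For a cross
#' (M, T) the effective cis effect is `c* = c + dev_M - dev_T`. Hybrid counts
#' are drawn by first drawing the total allele-informative depth
#' `N ~ NegBin(mean_depth * libsize, alpha)` and then the maize-allele count
#' `Binomial(N, 2^c* / (1 + 2^c*))`, so the hybrid allelic ratio is a pure cis
#' readout conditioned on depth. Parent inbreds express only their own allele;
#' the maize line mean is proportional to `libsize * 2^{(c+t)/2 + dev_M}` and
#' the teosinte line mean to `libsize * 2^{-(c+t)/2 + dev_T}`, so the
#' library-corrected parent log2 ratio equals `c* + t` by construction.
#' Library size factors are drawn log-normal (mean 1, CV `libsize_cv`) per
#' genotype x tissue x replicate; replicates are independent draws.
#'
#' @param design A [simulate_design()] object.
#' @param truth A [simulate_truth()] object covering all genes/tissues.
#' @param params The same [sim_params()] used for the truth.
#' @return A data.frame of allele counts with columns `gene_id`, `tissue`,
#'   `genotype` (cross `"MxT"` or inbred name), `replicate`, `maize_count`,
#'   `teosinte_count`. Inbred rows carry their own-allele count in the
#'   corresponding column and 0 in the other.
#' @export
simulate_counts <- function(design, truth, params) {
  validate_design(design)
  stopifnot(inherits(truth, "sim_truth"), inherits(params, "sim_params"))
  set.seed(params$seed + 1L)
  cv <- params$libsize_cv
  sdlog <- sqrt(log(1 + cv^2))
  draw_lib <- function(n) if (cv == 0) rep(1, n) else
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)

  tr <- data.table::as.data.table(truth$truth)
  ld <- data.table::as.data.table(truth$line_dev)
  data.table::setkey(tr, gene_id, tissue)

  out <- vector("list", 2L)

  # ---- hybrids ----
  cr <- design$crosses
  hy <- vector("list", nrow(cr))
  for (i in seq_len(nrow(cr))) {
    M <- cr$maize_line[i]; T_ <- cr$teosinte_line[i]; g <- cr$cross[i]
    nrep <- design$replicates[[g]]
    devM <- ld[ld$line == M, .(gene_id, tissue, devM = dev)]
    devT <- ld[ld$line == T_, .(gene_id, tissue, devT = dev)]
    tt <- merge(merge(tr, devM, by = c("gene_id", "tissue")),
                devT, by = c("gene_id", "tissue"))
    cstar <- tt$cis_effect + tt$devM - tt$devT
    p <- 2^cstar / (1 + 2^cstar)
    reps <- lapply(seq_len(nrep), function(r) {
      lib <- draw_lib(1L)
      N <- .rnb(nrow(tt), params$mean_depth * lib, params$dispersion)
      m <- stats::rbinom(nrow(tt), N, p)
      data.table::data.table(gene_id = tt$gene_id, tissue = tt$tissue,
                             genotype = g, replicate = r,
                             maize_count = m, teosinte_count = N - m)
    })
    hy[[i]] <- data.table::rbindlist(reps)
  }
  out[[1L]] <- data.table::rbindlist(hy)

  # ---- parent inbreds ----
  lines <- c(design$maize_lines, design$teosinte_lines)
  is_maize <- lines %in% design$maize_lines
  pa <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    L <- lines[i]
    nrep <- design$replicates[[L]]
    dv <- ld[ld$line == L, .(gene_id, tissue, dev = dev)]
    tt <- merge(tr, dv, by = c("gene_id", "tissue"))
    half <- (tt$cis_effect + tt$trans_effect) / 2
    lmean <- if (is_maize[i]) 2^(half + tt$dev) else 2^(-half + tt$dev)
    reps <- lapply(seq_len(nrep), function(r) {
      lib <- draw_lib(1L)
      cnt <- .rnb(nrow(tt), (params$mean_depth / 2) * lib * lmean,
                  params$dispersion)
      data.table::data.table(
        gene_id = tt$gene_id, tissue = tt$tissue, genotype = L,
        replicate = r,
        maize_count = if (is_maize[i]) cnt else 0L,
        teosinte_count = if (is_maize[i]) 0L else cnt)
    })
    pa[[i]] <- data.table::rbindlist(reps)
  }
  out[[2L]] <- data.table::rbindlist(pa)

  res <- data.table::rbindlist(out)
  data.table::setorder(res, gene_id, tissue, genotype, replicate)
  data.table::setDF(res)
  res
}

#' Write simulated tables as TSV
#'
#' @param counts Allele-count data.frame from [simulate_counts()].
#' @param truth Optional [simulate_truth()] object.
#' @param design Optional [simulate_design()] object.
#' @param dir Output directory (created if needed). Writes `counts.tsv`, and
#'   when given, `truth.tsv`, `line_dev.tsv`, `design.yaml`.
#' @return The directory path, invisibly.
#' @export
write_sim <- function(counts, truth = NULL, design = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(counts, file.path(dir, "counts.tsv"))
  if (!is.null(truth)) {
    write_tsv(truth$truth, file.path(dir, "truth.tsv"))
    write_tsv(truth$line_dev, file.path(dir, "line_dev.tsv"))
  }
  if (!is.null(design)) write_design(design, file.path(dir, "design.yaml"))
  invisible(dir)
}
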