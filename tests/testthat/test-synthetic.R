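test_that("simulate_design samples valid cross sets", {
  # exhaustive grid when n_crosses equals the full factorial
  d_full <- simulate_design(6, 9, 54, tissues = "ear", replicate_mean = 2,
                            seed = 5)
  expect_equal(nrow(d_full$crosses), 54)
  expect_equal(anyDuplicated(d_full$crosses$cross), 0)

  # default-sized panel: 29 unique pairs covering every line
  d <- simulate_design(seed = 1)
  expect_s3_class(d, "cross_design")
  expect_equal(nrow(d$crosses), 29)
  expect_equal(anyDuplicated(paste(d$crosses$maize_line,
                                   d$crosses$teosinte_line)), 0)
  expect_true(all(d$maize_lines %in% d$crosses$maize_line))
  expect_true(all(d$teosinte_lines %in% d$crosses$teosinte_line))
  expect_true(all(d$replicates >= 1))
  expect_no_error(validate_design(d))

  # overfull request errors
  expect_error(simulate_design(2, 2, 5), "exceeds")
})

test_that("replicate counts average near the requested mean", {
  d <- simulate_design(10, 10, 100, replicate_mean = 1.96, seed = 42)
  expect_gt(mean(d$replicates), 1.6)
  expect_lt(mean(d$replicates), 2.4)
})

test_that("planted truth respects category constraints", {
  d <- simulate_design(3, 3, 9, tissues = "ear", seed = 2)
  p_cons <- sim_params(n_genes = 200, category_mix = c(conserved = 1),
                       sigma_cis_maize = 0, sigma_cis_teosinte = 0, seed = 3)
  tr <- simulate_truth(d, p_cons)
  expect_true(all(tr$truth$cis_effect == 0))
  expect_true(all(tr$truth$trans_effect == 0))
  expect_true(all(tr$line_dev$dev == 0))

  p_comp <- sim_params(n_genes = 200, category_mix = c(compensatory = 1),
                       seed = 3)
  trc <- simulate_truth(d, p_comp)
  expect_equal(trc$truth$cis_effect + trc$truth$trans_effect,
               rep(0, nrow(trc$truth)))
  expect_true(all(abs(trc$truth$cis_effect) > 0))

  # sign constraints for the mixed-direction categories
  p_mix <- sim_params(n_genes = 500,
                      category_mix = c(cis_plus_trans = 0.5,
                                       cis_x_trans = 0.5), seed = 4)
  trm <- simulate_truth(d, p_mix)$truth
  cpt <- trm[trm$category == "cis_plus_trans", ]
  cxt <- trm[trm$category == "cis_x_trans", ]
  expect_true(all(sign(cpt$cis_effect) == sign(cpt$trans_effect)))
  expect_true(all(sign(cxt$cis_effect) == -sign(cxt$trans_effect)))
})

test_that("line deviation SDs scale with the species sigmas", {
  d <- simulate_design(6, 9, 29, tissues = "ear", seed = 6)
  p <- sim_params(n_genes = 10000, category_mix = c(conserved = 1),
                  sigma_cis_maize = 0.2, sigma_cis_teosinte = 0.4, seed = 7)
  tr <- simulate_truth(d, p)
  ld <- tr$line_dev
  sd_m <- sd(ld$dev[ld$line %in% d$maize_lines])
  sd_t <- sd(ld$dev[ld$line %in% d$teosinte_lines])
  expect_equal(sd_t / sd_m, 2, tolerance = 0.05)
})

test_that("category proportions match the mix at large n", {
  d <- simulate_design(2, 2, 4, tissues = "ear", seed = 8)
  mix <- c(conserved = 0.4, cis = 0.3, trans = 0.2, compensatory = 0.1)
  p <- sim_params(n_genes = 10000, category_mix = mix, seed = 9)
  tr <- simulate_truth(d, p)
  emp <- table(tr$truth$category) / nrow(tr$truth)
  for (nm in names(mix)) {
    # 4 SD binomial band
    tol <- 4 * sqrt(mix[[nm]] * (1 - mix[[nm]]) / 10000)
    expect_lt(abs(emp[[nm]] - mix[[nm]]), tol)
  }
})

test_that("counts are seed-deterministic and structurally valid", {
  d <- simulate_design(3, 3, 6, tissues = c("ear", "leaf"), seed = 10)
  p <- sim_params(n_genes = 40, seed = 11)
  tr <- simulate_truth(d, p)
  c1 <- simulate_counts(d, tr, p)
  c2 <- simulate_counts(d, tr, p)
  expect_identical(c1, c2)
  expect_no_error(validate_counts(c1))
  # parent inbreds express only their own allele
  expect_true(all(c1$teosinte_count[c1$genotype %in% d$maize_lines] == 0))
  expect_true(all(c1$maize_count[c1$genotype %in% d$teosinte_lines] == 0))
})

test_that("planted effects are recovered in expectation by the count model", {
  # Effects are planted with random signs (as in real data, where the
  # library-size correction is identifiable because genes are not all
  # shifted the same way), so recovery is checked on sign-aligned means.
  d <- make_design(data.frame(maize_line = "M1", teosinte_line = "T1",
                              stringsAsFactors = FALSE))
  # cis-only, |c| = 2: hybrid and parent log2 ratios both ~ c
  p <- sim_params(n_genes = 800, category_mix = c(cis = 1),
                  cis_effect_scale = 2, sigma_cis_maize = 0,
                  sigma_cis_teosinte = 0, mean_depth = 1e5, dispersion = 0,
                  libsize_cv = 0, seed = 12)
  tr <- simulate_truth(d, p)
  tr$truth$cis_effect <- 2 * sign(tr$truth$cis_effect)  # pin the magnitude
  tr$truth$trans_effect <- 0
  cts <- simulate_counts(d, tr, p)
  rt <- cross_ratios(pool_replicates(cts), d, min_depth = 100)
  rt <- merge(rt, tr$truth, by = c("gene_id", "tissue"))
  sgn <- sign(rt$cis_effect)
  expect_equal(mean(sgn * rt$log2_hybrid), 2, tolerance = 0.05)
  expect_equal(mean(sgn * rt$log2_parent), 2, tolerance = 0.05)

  # trans-only, |t| = 1: hybrid ~ 0, parent ~ t
  p2 <- sim_params(n_genes = 800, category_mix = c(trans = 1),
                   trans_effect_scale = 1, sigma_cis_maize = 0,
                   sigma_cis_teosinte = 0, mean_depth = 1e5, dispersion = 0,
                   libsize_cv = 0, seed = 13)
  tr2 <- simulate_truth(d, p2)
  tr2$truth$trans_effect <- sign(tr2$truth$trans_effect)
  cts2 <- simulate_counts(d, tr2, p2)
  rt2 <- cross_ratios(pool_replicates(cts2), d, min_depth = 100)
  rt2 <- merge(rt2, tr2$truth, by = c("gene_id", "tissue"))
  sgn2 <- sign(rt2$trans_effect.y)
  expect_equal(mean(rt2$log2_hybrid), 0, tolerance = 0.05)
  expect_equal(mean(sgn2 * rt2$log2_parent), 1, tolerance = 0.05)
})

test_that("sim tables round-trip through TSV/YAML", {
  d <- simulate_design(2, 3, 5, tissues = "ear", seed = 14)
  p <- sim_params(n_genes = 10, seed = 15)
  tr <- simulate_truth(d, p)
  cts <- simulate_counts(d, tr, p)
  dir <- withr::local_tempdir()
  write_sim(cts, tr, d, dir)
  back <- read_counts(file.path(dir, "counts.tsv"))
  expect_equal(nrow(back), nrow(cts))
  expect_equal(sum(back$maize_count), sum(cts$maize_count))
  d2 <- read_design(file.path(dir, "design.yaml"))
  expect_equal(d2$crosses$cross, d$crosses$cross)
  expect_equal(sort(names(d2$replicates)), sort(names(d$replicates)))
})
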