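test_that("pool_replicates sums element-wise over replicates", {
  cts <- rbind(count_row("g1", "M1xT1", 10L, 5L, rep = 1L),
               count_row("g1", "M1xT1", 20L, 15L, rep = 2L),
               count_row("g2", "M1xT1", 7L, 3L, rep = 1L),
               # gene present in only one replicate: additive zero
               count_row("g3", "M1xT1", 4L, 4L, rep = 2L))
  pooled <- pool_replicates(cts)
  expect_equal(pooled$maize_count[pooled$gene_id == "g1"], 30)
  expect_equal(pooled$teosinte_count[pooled$gene_id == "g1"], 20)
  # single replicate passes through unchanged
  expect_equal(pooled$maize_count[pooled$gene_id == "g2"], 7)
  expect_equal(pooled$maize_count[pooled$gene_id == "g3"], 4)
})

test_that("pool_replicates rejects malformed tables", {
  bad <- rbind(count_row("g1", "M1xT1", 1L, 1L),
               count_row("g1", "M1xT1", 2L, 2L))  # duplicate key
  expect_error(pool_replicates(bad), "duplicate")
  neg <- count_row("g1", "M1xT1", -1L, 1L)
  expect_error(pool_replicates(neg), "non-negative")
})

test_that("parent library correction scales the larger library down", {
  expect_equal(correct_parent_libsize(300, 100, 2e6, 1e6),
               list(parent_m = 150L, parent_t = 100L))
  # equal libraries: identity
  expect_equal(correct_parent_libsize(300, 100, 1e6, 1e6),
               list(parent_m = 300L, parent_t = 100L))
  # round-half-to-even: 7/3 = 2.33 -> 2
  expect_equal(correct_parent_libsize(7, 10, 3e6, 1e6),
               list(parent_m = 2L, parent_t = 10L))
  # scale invariance in the library sizes
  expect_equal(correct_parent_libsize(123, 456, 5e6, 3e6),
               correct_parent_libsize(123, 456, 10e6, 6e6))
  expect_error(correct_parent_libsize(1, 1, 0, 1), "library sizes")
})

test_that("cross_ratios computes cis and trans effects from counts", {
  d <- one_cross_design()
  # hybrid 150:150 -> log2 0
  rt <- cross_ratios(pool_replicates(one_cross_counts(150L, 150L, 100L, 100L)),
                     d, min_depth = 100)
  g1 <- rt[rt$gene_id == "g1", ]
  expect_equal(g1$log2_hybrid, 0)
  # hybrid 200:100, parent 100:100 -> cis = 1, trans = -1
  rt2 <- cross_ratios(pool_replicates(one_cross_counts(200L, 100L, 100L, 100L)),
                      d, min_depth = 100)
  g1 <- rt2[rt2$gene_id == "g1", ]
  expect_equal(g1$log2_hybrid, 1)
  expect_equal(g1$log2_parent, 0)
  expect_equal(g1$trans_effect, -1)
  expect_true(g1$passes_depth)
})

test_that("depth filter needs 100 in both hybrid and parent comparison", {
  d <- one_cross_design()
  # hybrid depth 99 fails even with deep parents
  rt <- cross_ratios(pool_replicates(one_cross_counts(50L, 49L, 500L, 500L)),
                     d, min_depth = 100)
  expect_false(rt$passes_depth[rt$gene_id == "g1"])
  # boundary: exactly 100 passes
  rt2 <- cross_ratios(pool_replicates(one_cross_counts(50L, 50L, 50L, 50L)),
                      d, min_depth = 100)
  expect_true(rt2$passes_depth[rt2$gene_id == "g1"])
})

test_that("zero counts give undefined log ratios but keep the counts", {
  d <- one_cross_design()
  rt <- cross_ratios(pool_replicates(one_cross_counts(200L, 0L, 100L, 100L)),
                     d, min_depth = 100)
  g1 <- rt[rt$gene_id == "g1", ]
  expect_true(is.na(g1$log2_hybrid))
  expect_equal(g1$hybrid_m, 200)
  expect_true(g1$passes_depth)
})

test_that("missing parent genotypes are flagged and fail the filter", {
  d <- make_design(data.frame(maize_line = c("M1", "M2"),
                              teosinte_line = c("T1", "T1"),
                              stringsAsFactors = FALSE))
  cts <- rbind(one_cross_counts(150L, 150L, 100L, 100L),
               count_row("g1", "M2xT1", 300L, 300L))  # M2 inbred absent
  rt <- cross_ratios(pool_replicates(cts), d, min_depth = 100)
  m2 <- rt[rt$cross == "M2xT1" & rt$gene_id == "g1", ]
  expect_true(m2$missing_parent)
  expect_false(m2$passes_depth)
})

test_that("overall ratios reduce to the single cross when there is one", {
  d <- one_cross_design()
  rt <- cross_ratios(pool_replicates(one_cross_counts(200L, 100L, 120L, 60L)),
                     d, min_depth = 100)
  ov <- overall_ratios(rt)
  g1 <- ov[ov$gene_id == "g1", ]
  r1 <- rt[rt$gene_id == "g1", ]
  expect_equal(g1$sum_hybrid_m, r1$hybrid_m)
  expect_equal(g1$log2_hybrid_overall, r1$log2_hybrid)
  expect_equal(g1$log2_parent_overall, r1$log2_parent)
  expect_equal(g1$n_crosses_used, 1L)
})

test_that("shared parents are not double counted in the overall parent ratio", {
  # two crosses share maize parent M1; teosinte parents carry equal counts,
  # so the overall parent ratio must equal the single-parent ratio 240:120
  d <- make_design(data.frame(maize_line = c("M1", "M1"),
                              teosinte_line = c("T1", "T2"),
                              stringsAsFactors = FALSE))
  f <- 10000L
  cts <- rbind(
    count_row("g1", "M1xT1", 500L, 500L), count_row("g1", "M1xT2", 500L, 500L),
    count_row("g1", "M1", 240L, 0L),
    count_row("g1", "T1", 0L, 120L), count_row("g1", "T2", 0L, 120L),
    count_row("g0", "M1xT1", f, f), count_row("g0", "M1xT2", f, f),
    count_row("g0", "M1", 2L * f - 240L, 0L),
    count_row("g0", "T1", 0L, 2L * f - 120L),
    count_row("g0", "T2", 0L, 2L * f - 120L))
  ov <- overall_ratios(cross_ratios(pool_replicates(cts), d, min_depth = 100))
  g1 <- ov[ov$gene_id == "g1", ]
  # hand-computed weighted sums: maize 2*240, teosinte 120+120, then the
  # common once-count rescale preserves the ratio
  expect_equal(g1$wsum_parent_m / g1$wsum_parent_t, 2, tolerance = 1e-2)
  expect_equal(g1$log2_parent_overall, 1, tolerance = 0.01)
  expect_equal(g1$n_unique_maize, 1L)
  expect_equal(g1$n_unique_teosinte, 2L)
})

test_that("overall hybrid sums equal column sums of passing records", {
  d <- simulate_design(3, 4, 8, tissues = "ear", seed = 20)
  p <- sim_params(n_genes = 60, mean_depth = 250, seed = 21)
  tr <- simulate_truth(d, p)
  rt <- cross_ratios(pool_replicates(simulate_counts(d, tr, p)), d)
  ov <- overall_ratios(rt)
  pass <- rt[rt$passes_depth, ]
  chk <- aggregate(cbind(hybrid_m, hybrid_t) ~ gene_id, pass, sum)
  mrg <- merge(ov, chk, by = "gene_id")
  expect_equal(mrg$sum_hybrid_m, mrg$hybrid_m)
  expect_equal(mrg$sum_hybrid_t, mrg$hybrid_t)
})

test_that("genes whose crosses all fail depth are absent from the overall table", {
  d <- one_cross_design()
  cts <- one_cross_counts(10L, 10L, 2000L, 2000L)  # hybrid depth 20 < 100
  ov <- overall_ratios(cross_ratios(pool_replicates(cts), d, min_depth = 100))
  expect_false("g1" %in% ov$gene_id)
})
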