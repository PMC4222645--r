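test_that("coverage filter applies all three thresholds", {
  expect_true(coverage_filter(15, 3, 5))
  expect_false(coverage_filter(16, 2, 9))
  expect_false(coverage_filter(14, 3, 5))
  expect_equal(coverage_filter(c(15, 14), c(3, 3), c(5, 5)), c(TRUE, FALSE))
})

# minimal passing per-cross records for consistency tests
cons_records <- function(depths, maize_biased, n_m = 5, n_t = 6) {
  n <- length(depths)
  data.frame(
    gene_id = "g1", tissue = "ear",
    cross = sprintf("M%dxT%d", rep_len(seq_len(n_m), n),
                    rep_len(seq_len(n_t), n)),
    maize_line = sprintf("M%d", rep_len(seq_len(n_m), n)),
    teosinte_line = sprintf("T%d", rep_len(seq_len(n_t), n)),
    hybrid_m = ifelse(maize_biased, depths - 1, 1),
    hybrid_t = ifelse(maize_biased, 1, depths - 1),
    depth_hybrid = depths, passes_depth = TRUE,
    stringsAsFactors = FALSE)
}

test_that("consistency tiers follow the depth-weighted fraction", {
  # all crosses maize-biased: tier A, favored maize
  r <- cons_records(rep(1000, 15), rep(TRUE, 15))
  co <- consistency_tier(r)
  expect_equal(co$weighted_maize_fraction, 1)
  expect_equal(co$tier, "A")
  expect_equal(co$favored_allele, "maize")

  # 13 deep maize-biased + 2 shallow teosinte-biased: 13000/13100 -> B
  r2 <- cons_records(c(rep(1000, 13), 50, 50),
                     c(rep(TRUE, 13), FALSE, FALSE))
  co2 <- consistency_tier(r2)
  expect_equal(co2$weighted_maize_fraction, 13000 / 13100, tolerance = 1e-12)
  expect_equal(co2$tier, "B")

  # fraction 0.79 in either direction: below C
  r3 <- cons_records(c(79, 21), c(TRUE, FALSE))
  expect_equal(consistency_tier(r3)$tier, "none")
})

test_that("weighted fraction is invariant to uniform depth scaling", {
  r <- cons_records(c(800, 400, 200, 100), c(TRUE, TRUE, FALSE, TRUE))
  f1 <- consistency_tier(r)$weighted_maize_fraction
  r$depth_hybrid <- r$depth_hybrid * 7
  r$hybrid_m <- ifelse(r$hybrid_m > r$hybrid_t, r$depth_hybrid - 1, 1)
  r$hybrid_t <- r$depth_hybrid - r$hybrid_m
  expect_equal(consistency_tier(r)$weighted_maize_fraction, f1)
})

test_that("exact 1:1 crosses are direction-neutral but count in the denominator", {
  r <- cons_records(c(500, 500), c(TRUE, TRUE))
  r$hybrid_m[2] <- 250; r$hybrid_t[2] <- 250
  co <- consistency_tier(r)
  expect_equal(co$weighted_maize_fraction, 0.5)
})

test_that("tier monotonicity: raising the threshold never adds genes", {
  set.seed(40)
  recs <- do.call(rbind, lapply(1:30, function(i) {
    x <- cons_records(sample(50:2000, 16), runif(16) < 0.8)
    x$gene_id <- paste0("g", i)
    x
  }))
  co <- consistency_tier(recs)
  nA <- sum(co$tier == "A")
  nAB <- sum(co$tier %in% c("A", "B"))
  nABC <- sum(co$tier %in% c("A", "B", "C"))
  expect_lte(nA, nAB)
  expect_lte(nAB, nABC)
})

test_that("candidate lists respect category and coverage rules", {
  calls <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"), tissue = "ear",
    category = c("cis", "cis_plus_trans", "cis_x_trans", "trans",
                 "conserved"),
    stringsAsFactors = FALSE)
  cons <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"), tissue = "ear",
    n_crosses = c(15, 20, 20, 20, 20), n_unique_maize = c(3, 5, 5, 5, 5),
    n_unique_teosinte = c(5, 8, 8, 8, 8),
    weighted_maize_fraction = c(1, 0.95, 0.9, 0.05, 0.5),
    consistency = c(1, 0.95, 0.9, 0.95, 0.5),
    tier = c("A", "B", "B", "B", "none"),
    favored_allele = c("maize", "maize", "maize", "teosinte", "maize"),
    stringsAsFactors = FALSE)
  mem <- build_lists(calls, cons)
  cct <- mem[mem$list_class == "CCT", ]
  expect_setequal(cct$gene_id, c("g1", "g2"))       # cis_x_trans excluded
  expect_setequal(mem$gene_id[mem$list_class == "cis_only"], "g1")
  expect_setequal(mem$gene_id[mem$list_class == "trans_only"], "g4")
  expect_equal(list_members(mem, "CCT", tiers = "A"), "g1")
  expect_setequal(list_members(mem, "CCT", tiers = c("A", "B")),
                  c("g1", "g2"))

  # coverage failure drops the gene entirely
  cons$n_crosses[1] <- 14
  mem2 <- build_lists(calls, cons)
  expect_false("g1" %in% mem2$gene_id)

  # empty calls give empty lists
  expect_equal(nrow(build_lists(calls[0, ], cons)), 0)
})

test_that("union membership spans tissues", {
  calls <- data.frame(gene_id = c("g1", "g1"), tissue = c("ear", "leaf"),
                      category = c("cis", "conserved"),
                      stringsAsFactors = FALSE)
  cons <- data.frame(gene_id = c("g1", "g1"), tissue = c("ear", "leaf"),
                     n_crosses = 20, n_unique_maize = 5,
                     n_unique_teosinte = 6, weighted_maize_fraction = 1,
                     consistency = 1, tier = "A", favored_allele = "maize",
                     stringsAsFactors = FALSE)
  mem <- build_lists(calls, cons)
  expect_equal(list_members(mem, "CCT", "A"), "g1")            # union
  expect_equal(list_members(mem, "CCT", "A", tissue = "leaf"),
               character(0))                                   # ear-specific
  ov <- list_overlap(mem, "CCT", "A")
  expect_equal(ov$tissues, "ear")
})

test_that("directional bias test counts favored alleles", {
  mem <- data.frame(gene_id = paste0("g", 1:100), tissue = "ear",
                    list_class = "CCT", tier = "B",
                    favored_allele = rep(c("maize", "teosinte"), each = 50),
                    stringsAsFactors = FALSE)
  db <- directional_bias_test(mem)
  expect_equal(db$n_maize_biased, 50)
  expect_equal(db$p_value, 1)
  mem2 <- mem[1:10, ]; mem2$favored_allele <- "teosinte"
  db2 <- directional_bias_test(mem2)
  expect_equal(db2$p_value, 2 / 1024)
  expect_error(directional_bias_test(mem[0, ]), "empty")
})

test_that("reference bias check builds the 2x2 from cross subsets", {
  mk <- function(gene, maize, biased_m) {
    data.frame(gene_id = gene, tissue = "ear",
               cross = paste0(maize, "xT1"), maize_line = maize,
               teosinte_line = "T1",
               hybrid_m = if (biased_m) 900 else 100,
               hybrid_t = if (biased_m) 100 else 900,
               depth_hybrid = 1000, passes_depth = TRUE,
               stringsAsFactors = FALSE)
  }
  # 10 genes biased the same way in B73 and non-B73 crosses -> p = 1
  recs <- do.call(rbind, lapply(1:10, function(i)
    rbind(mk(paste0("g", i), "B73", i <= 5),
          mk(paste0("g", i), "MZ02", i <= 5))))
  rb <- reference_bias_check(recs, paste0("g", 1:10), "B73", "ear")
  expect_equal(rb$p_value, 1)
  expect_equal(unname(rb$table[1, ]), c(5, 5))

  # perfectly opposite biases: [[0,10],[10,0]] -> 2 / C(20,10)
  recs2 <- do.call(rbind, lapply(1:10, function(i)
    rbind(mk(paste0("g", i), "B73", TRUE),
          mk(paste0("g", i), "MZ02", FALSE))))
  rb2 <- reference_bias_check(recs2, paste0("g", 1:10), "B73", "ear")
  expect_equal(rb2$p_value, 2 / choose(20, 10), tolerance = 1e-9)

  expect_error(reference_bias_check(recs, paste0("g", 1:10), "NOPE", "ear"),
               "no crosses involving")
})
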