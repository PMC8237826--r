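test_that("accumulation curves: degenerate cases and exact expectation", {
  ## all records one species
  c1 <- accumulation_curve(rep("a", 10), n_orders = 20, seed = 1)
  expect_equal(c1$s_mean, rep(1, 10))
  expect_equal(c1$s_obs, 1)
  ## all records distinct
  c2 <- accumulation_curve(letters[1:5], n_orders = 20, seed = 1)
  expect_equal(c2$s_mean, 1:5)
  ## 2+2 records of two species: exact E[S(2)] = 5/3 by enumeration
  sp <- c("a", "a", "b", "b")
  exact <- expected_accumulation(sp)
  expect_equal(exact[2], 5 / 3)
  expect_equal(exact[4], 2)             # full curve ends at S_obs
  ## brute-force enumeration over all 4! orderings agrees with closed form
  perms <- expand.grid(rep(list(1:4), 4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  s2 <- mean(apply(perms, 1, function(p) length(unique(sp[unlist(p)[1:2]]))))
  expect_equal(exact[2], s2)
  ## Monte-Carlo mean within 3 SE of the exact expectation
  mc <- accumulation_curve(sp, n_orders = 2000, seed = 7)
  se <- sqrt(2 / 9) / sqrt(2000)  # S(2) is 1 w.p. 1/3, 2 w.p. 2/3: Var = 2/9
  expect_lt(abs(mc$s_mean[2] - 5 / 3), max(3 * se, 0.05))
  ## determinism and monotonicity
  mc2 <- accumulation_curve(sp, n_orders = 2000, seed = 7)
  expect_identical(mc$s_mean, mc2$s_mean)
  set.seed(8)
  spp <- sample(letters[1:6], 40, replace = TRUE)
  cc <- accumulation_curve(spp, n_orders = 50, seed = 2)
  expect_true(all(diff(cc$s_mean) >= -1e-12))
  expect_equal(cc$s_mean[40], cc$s_obs)
  expect_equal(cc$s_mean[1], 1)
})

test_that("Clench fit recovers noiseless parameters and ratios", {
  t <- 1:200
  curve <- list(t = t, s_mean = 5 * t / (1 + 0.05 * t), s_obs = 70)
  f <- fit_clench(curve)
  expect_true(f$converged)
  expect_equal(f$a, 5, tolerance = 1e-6)
  expect_equal(f$b, 0.05, tolerance = 1e-6)
  expect_equal(f$asymptote, 100, tolerance = 1e-4)
  ## S_obs = 70 against asymptote 100 -> completeness 0.7
  expect_equal(f$completeness, 0.7, tolerance = 1e-5)
  expect_error(fit_clench(list(t = 1:2, s_mean = c(1, 2), s_obs = 2)),
               "distinct")
  expect_error(fit_clench(list(t = 1:5, s_mean = rep(2, 5), s_obs = 2)),
               "non-constant")
})

test_that("completeness never decreases when effort doubles (noiseless)", {
  set.seed(11)
  sp <- sample(sprintf("s%02d", 1:20), 120, replace = TRUE)
  f1 <- fit_clench(list(t = seq_along(sp),
                        s_mean = expected_accumulation(sp),
                        s_obs = length(unique(sp))))
  sp2 <- c(sp, sp)                      # 2x effort, same species
  f2 <- fit_clench(list(t = seq_along(sp2),
                        s_mean = expected_accumulation(sp2),
                        s_obs = length(unique(sp2))))
  expect_gte(f2$completeness, f1$completeness - 1e-9)
})

test_that("completeness approaches 1 when sampling saturates", {
  set.seed(12)
  sp <- sample(sprintf("s%02d", 1:30), 3000, replace = TRUE)
  cur <- accumulation_curve(sp, n_orders = 30, seed = 3)
  f <- fit_clench(cur)
  expect_gte(f$completeness, 0.95)
})

test_that("well-sampled rule: strict thresholds and checklist override", {
  expect_true(classify_well_sampled(51, 0.71, FALSE)$decision)
  expect_false(classify_well_sampled(50, 0.99, FALSE)$decision)
  expect_false(classify_well_sampled(500, 0.70, FALSE)$decision)
  expect_false(classify_well_sampled(51, NA, FALSE)$decision)
  d <- classify_well_sampled(3, NA, TRUE)
  expect_true(d$decision)
  expect_equal(d$reason, "trusted_inventory")
  expect_equal(classify_well_sampled(51, 0.71, FALSE)$reason,
               "records_and_completeness")
  expect_equal(classify_well_sampled(2, 0.1, FALSE)$reason,
               "not_well_sampled")
  ## raw completeness above 1 still qualifies
  expect_true(classify_well_sampled(60, 1.2, FALSE)$decision)
})

test_that("completeness_by_cell assembles the per-cell table", {
  set.seed(13)
  cells <- list(`5` = sample(sprintf("s%d", 1:10), 120, replace = TRUE),
                `9` = rep("s1", 2),
                `12` = sample(sprintf("s%d", 1:40), 30, replace = TRUE))
  tab <- completeness_by_cell(cells, trusted_cells = c(9L, 77L),
                              n_orders = 30, seed = 4)
  expect_equal(tab$cell, c(5L, 9L, 12L, 77L))
  expect_equal(tab$n_records[tab$cell == 77], 0)
  expect_true(tab$well_sampled[tab$cell == 9])     # trusted, 2 records
  expect_true(tab$well_sampled[tab$cell == 77])    # trusted, no records
  expect_true(tab$well_sampled[tab$cell == 5])     # >50 records, saturated
  expect_false(tab$well_sampled[tab$cell == 12])   # 30 records
  ## deterministic under the same seed
  tab2 <- completeness_by_cell(cells, trusted_cells = c(9L, 77L),
                               n_orders = 30, seed = 4)
  expect_identical(tab, tab2)
})
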