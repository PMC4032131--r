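tiny_sweep <- function(grid, n_trees = 300, seed = 1) {
  sweep_spec(null_model_params(), grid = grid, n_trees = n_trees,
             sample = sample_config(n_european = 2), seed = seed)
}

test_that("a sweep evaluates every grid point deterministically", {
  spec <- tiny_sweep(list(f = c(0, 0.2)))
  rec1 <- run_sweep(spec)
  rec2 <- run_sweep(spec)
  expect_identical(nrow(rec1), 2L)
  expect_identical(rec1$d, rec2$d)
  expect_identical(rec1$dcfs, rec2$dcfs)
  one <- run_sweep(tiny_sweep(list(f = 0.1)))
  expect_identical(nrow(one), 1L)
  expect_true(all(is.na(one$error)))
})

test_that("per-combination failures are recorded, not raised", {
  rec <- run_sweep(tiny_sweep(list(f = c(0.1, -0.5))))
  expect_identical(nrow(rec), 2L)
  expect_true(is.na(rec$error[1]))
  expect_match(rec$error[2], "\\[0, 1\\]")
  expect_true(is.na(rec$d[2]))
})

test_that("filter_by_d applies the |d - target| <= tol rule and is idempotent", {
  rec <- run_sweep(tiny_sweep(list(f = c(0, 0.05, 0.1))))
  rec$d <- c(0.0457, 0.0478, NA)
  kept <- filter_by_d(rec, target_d = 0.0457, tol_d = 0.0020)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$d, 0.0457)
  # |0.0478 - 0.0457| = 0.0021 > 0.0020: excluded
  expect_false(0.0478 %in% kept$d)
  expect_identical(filter_by_d(kept, 0.0457, 0.0020), kept)
  all_kept <- filter_by_d(rec, target_d = 0.0457, tol_d = Inf)
  expect_identical(nrow(all_kept), 2L)  # NA d still dropped
  expect_message(filter_by_d(rec, target_d = 10, tol_d = 1e-6),
                 "no parameter combination")
})

test_that("rank_by_r2 sorts by fit, is order-invariant, and sinks undefined records", {
  rec <- run_sweep(tiny_sweep(list(f = c(0, 0.1, 0.3)), n_trees = 500))
  observed <- rec$dcfs[[2]]
  ranked <- rank_by_r2(rec, observed)
  expect_equal(ranked$f[1], 0.1)
  expect_equal(ranked$r2[1], 100)
  expect_true(all(diff(ranked$r2) <= 0))
  shuffled <- dcfsim:::restore_fit_records(rec[c(3, 1, 2), ], rec)
  expect_identical(rank_by_r2(shuffled, observed)$f, ranked$f)

  rec$dcfs[[3]] <- dcfs(c(0, 0))  # undefined spectrum sorts last
  ranked2 <- rank_by_r2(rec, observed)
  expect_true(is.na(ranked2$r2[3]))
  expect_equal(ranked2$f[3], 0.3)
})

test_that("compare_models reports best fits and regenerates identically", {
  rec <- run_sweep(tiny_sweep(list(f = c(0, 0.1))))
  observed <- rec$dcfs[[1]]
  cmp1 <- compare_models(rec, rec, rec, observed)
  cmp2 <- compare_models(rec, rec, rec, observed)
  expect_identical(cmp1, cmp2)
  expect_setequal(cmp1$summary$model, c("spatial", "two_pop", "admixture"))
  # all three collections identical => three-way tie
  expect_equal(diff(range(cmp1$summary$r2)), 0)
  expect_equal(cmp1$summary$class1,
               rep(observed$proportions[1], 3), tolerance = 1e-12)
})

test_that("simulated D decreases with ancestral migration on the spatial chain", {
  sc <- sample_config(1, 1, 1, 1)
  d_at <- function(m0) {
    demog <- build_spatial_model(spatial_params(m0 = m0))
    trees <- simulate_replicates(demog, sc, 30000, seed = 51)
    list(d = branch_patterson_d(trees)$d,
         se = block_se(trees, function(tr) branch_patterson_d(tr)$d))
  }
  lo <- d_at(5e-5)
  hi <- d_at(3e-3)
  expect_gt(lo$d - hi$d, 3 * sqrt(lo$se^2 + hi$se^2))
})
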