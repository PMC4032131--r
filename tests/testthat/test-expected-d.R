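test_that("the exact branch-expectation D matches the Monte Carlo branch path", {
  p <- spatial_params(m0 = 1e-3, m = 1e-3)
  exact <- expected_patterson_d(p)
  demog <- build_spatial_model(p)
  trees <- simulate_replicates(demog, sample_config(1, 1, 1, 1), 8000,
                               seed = 71)
  mc <- branch_patterson_d(trees)$d
  se <- block_se(trees, function(tr) branch_patterson_d(tr)$d)
  expect_lt(abs(exact$d - mc), 3 * se)
  expect_gt(exact$e_abba, 0)
  expect_gt(exact$e_baba, 0)
  expect_true(exact$p_pair_coalesced > 0 && exact$p_pair_coalesced < 1)
})

test_that("the exact D decreases monotonically in the ancestral migration rate", {
  m0_grid <- spatial_params()$m0 * 4^(-2:2)
  d <- vapply(m0_grid,
              function(m0) expected_patterson_d(spatial_params(m0 = m0))$d,
              0)
  expect_true(all(diff(d) < 0))
  expect_true(all(d > 0))
})

test_that("at the calibrated defaults the expected D sits at the reference value", {
  exact <- expected_patterson_d(spatial_params())
  expect_lt(abs(exact$d - 0.0457), 0.002)
})

test_that("exchangeable African and European sampling yields D consistent with zero", {
  # when both chromosomes are drawn from the same deme at the same time the
  # labels are exchangeable, so E[D] = 0 exactly (symmetry oracle)
  demog <- build_spatial_model(spatial_params())
  trees <- simulate_replicates(
    demog,
    sample_config(1, 1, 1, 1,
                  demes = list(african = "afr4", european = "afr4")),
    20000, seed = 72)
  d_sym <- branch_patterson_d(trees)$d
  se <- block_se(trees, function(tr) branch_patterson_d(tr)$d)
  expect_lt(abs(d_sym), 3 * se)
})
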