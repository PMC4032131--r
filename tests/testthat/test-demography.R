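test_that("spatial model with a 2-deme chain has a single adjacency before the split", {
  p <- spatial_params(k_demes = 2, n_neandertal_demes = 1)
  demog <- build_spatial_model(p)
  comp <- dcfsim:::compile_demography(demog)
  # epoch covering the reconnected chain, i.e. containing the split time
  e <- findInterval(p$t_neandertal_split, comp$breaks) + 1L
  m <- comp$migs[[e]]
  expect_identical(sum(m > 0), 2L)  # one symmetric edge pair
  expect_equal(m["nea1", "afr1"], p$m0)
})

test_that("default model constructors pass validation with zero issues", {
  expect_length(validate_demography(build_spatial_model(spatial_params())), 0)
  expect_length(
    validate_demography(build_two_population_model(two_pop_params())), 0)
  expect_length(
    validate_demography(build_admixture_model(admixture_params())), 0)
})

test_that("Neandertal split lands at 320 ky / generation time", {
  demog <- build_spatial_model(spatial_params(generation_time = 25))
  ev <- event_table(demog)
  expect_true(all(ev$time_generations[ev$kind == "chain_split"] == 12800))
  demog20 <- build_spatial_model(spatial_params(generation_time = 20))
  ev20 <- event_table(demog20)
  expect_true(all(ev20$time_generations[ev20$kind == "chain_split"] == 16000))
})

test_that("inconsistent time orderings are rejected with the violated inequality named", {
  expect_error(spatial_params(t_exit = 7000, t_modern = 6000),
               "t_exit < t_modern")
  expect_error(spatial_params(t_modern = 13000), "t_modern < t_neandertal_split")
  expect_error(spatial_params(founder_size = 5000), "founder_size")
  expect_error(two_pop_params(t_structure = 12000),
               "t_ooa < t_neandertal_split < t_structure")
  expect_error(admixture_params(t_admix = 3000), "t_admix < t_ooa")
})

test_that("validate_demography reports structural defects without raising", {
  demog <- build_spatial_model(spatial_params())
  demog$size0[["afr1"]] <- -5
  issues <- validate_demography(demog)
  expect_true(any(grepl("afr1", issues) & grepl("size", issues)))

  demog2 <- build_spatial_model(spatial_params())
  demog2$events <- c(demog2$events, list(dcfsim:::dem_event(
    1000, "parameter_change", "size", deme = "nowhere", value = 100)))
  expect_true(any(grepl("nowhere", validate_demography(demog2))))

  # migration edge surviving a deme's merge
  demog3 <- build_spatial_model(spatial_params())
  keep <- !vapply(demog3$events, function(e) {
    e$type == "migration" && e$value == 0 &&
      e$time == demog3$outgroup_split_time
  }, TRUE)
  demog3$events <- demog3$events[keep]
  expect_true(any(grepl("after its merge", validate_demography(demog3))))
})

test_that("two-population model keeps exactly one Neandertal deme and flags non-decreasing migration", {
  demog <- build_two_population_model(two_pop_params())
  expect_identical(sum(demog$demes$label == "neandertal"), 1L)
  bad <- build_two_population_model(two_pop_params(m_high = 1e-5,
                                                   m_low = 1e-4))
  issues <- validate_demography(bad)
  expect_true(any(startsWith(issues, "warning:")))
})

test_that("admixture pulse with f = 0 is the exact no-admixture model", {
  base <- two_pop_params()
  a0 <- build_admixture_model(admixture_params(f = 0, variant = "two_pop",
                                               base = base))
  tp <- build_two_population_model(base)
  expect_identical(a0$events, tp$events)
  expect_identical(a0$size0, tp$size0)
  expect_identical(a0$mig0, tp$mig0)
  # identical compiled model => identical trees under the same seed
  t1 <- simulate_genealogy(a0, sample_config(), seed = 99)
  t2 <- simulate_genealogy(tp, sample_config(), seed = 99)
  expect_identical(t1$parent, t2$parent)
  expect_identical(t1$time, t2$time)
})

test_that("admixture fraction is bounded and f = 1 moves every European lineage", {
  expect_error(admixture_params(f = 1.2), "\\[0, 1\\]")
  expect_error(admixture_params(f = -0.1), "\\[0, 1\\]")
  demog <- build_admixture_model(admixture_params(f = 1))
  ev <- event_table(demog)
  pulse <- ev[ev$kind == "mass_migration", ]
  expect_identical(nrow(pulse), 1L)
  expect_match(pulse$payload, "fraction 1")
})

test_that("deme counts balance over event replay: colonizations and merges", {
  p <- spatial_params()
  demog <- build_spatial_model(p)
  comp <- dcfsim:::compile_demography(demog)
  live <- rep(TRUE, length(comp$ids))
  names(live) <- comp$ids
  counts <- sum(live)
  for (e in seq_along(comp$breaks)) {
    act <- comp$actions[[e]]
    for (a in seq_along(act$from)) {
      if (act$frac[a] >= 1) live[act$from[a] + 1L] <- FALSE
    }
    counts <- c(counts, sum(live))
  }
  # present: nea + afr + eur + chimp + root demes all live
  expect_identical(counts[1], p$k_demes + p$n_eurasian_demes + 2L)
  # once the colonization reversals finish (break at t_exit) only the
  # chain, the chimp stem and the root remain, until the outgroup merge
  i_exit <- which(dcfsim:::compile_demography(demog)$breaks == p$t_exit) + 1L
  expect_identical(counts[i_exit], p$k_demes + 2L)
  expect_identical(counts[length(counts) - 1L], p$k_demes + 2L)
  # after the outgroup merge only the root remains
  expect_identical(counts[length(counts)], 1L)
})

test_that("a bare chain demography degenerates cleanly to a single deme", {
  expect_error(chain_demography(3, 100), "migration > 0")
  d1 <- chain_demography(1, 100)
  expect_length(validate_demography(d1), 0)
  d5 <- chain_demography(5, 100, 0.05)
  expect_length(validate_demography(d5), 0)
})
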