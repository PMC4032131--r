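test_that("toy panels round-trip exactly through the site dcfs", {
  sites <- data.frame(chimp = c("A", "A", "C"),
                      neandertal = c("G", "G", "T"),
                      african = c("A", "A", "C"),
                      eur_derived = c(1, 1, 2))
  tab <- build_toy_panel(toy_panel_spec(sites, nE = 5))
  x <- site_dcfs(tab)
  expect_equal(x$proportions, c(2 / 3, 1 / 3, 0, 0, 0))
  expect_equal(x$weight, 3)

  # descriptors outside the class range are rejected
  expect_error(toy_panel_spec(data.frame(chimp = "A", neandertal = "G",
                                         african = "A", eur_derived = 6),
                              nE = 5), "eur_derived")

  empty <- build_toy_panel(toy_panel_spec(
    data.frame(chimp = character(0), neandertal = character(0),
               african = character(0), eur_derived = integer(0)), nE = 5))
  expect_identical(nrow(empty$alleles), 0L)
  expect_true(site_dcfs(empty)$undefined)
})

test_that("non-conditioned descriptors are representable but excluded from the dcfs", {
  sites <- data.frame(chimp = c("A", "A"), neandertal = c("G", "A"),
                      african = c("A", "A"), eur_derived = c(3, 2))
  tab <- build_toy_panel(toy_panel_spec(sites, nE = 10))
  x <- site_dcfs(tab)  # second site has chimp == Neandertal
  expect_equal(x$weight, 1)
  expect_equal(which(x$proportions > 0), 3L)
})

test_that("pseudo-observed spectra are reproducible and concentrate with more loci", {
  spec <- pseudo_observed_spec(small_null_params(), n_dc_sites = 500,
                               n_trees = 2000, seed = 61)
  po1 <- generate_pseudo_observed(spec)
  po2 <- generate_pseudo_observed(spec)
  expect_identical(po1$dcfs$proportions, po2$dcfs$proportions)
  expect_equal(sum(po1$dcfs$proportions), 1)
  expect_identical(po1$provenance$seed, 61L)
  expect_identical(po1$provenance$n_dc_sites, 500L)

  one <- generate_pseudo_observed(
    pseudo_observed_spec(small_null_params(), n_dc_sites = 1,
                         n_trees = 2000, seed = 62))
  expect_identical(sum(one$dcfs$proportions == 1), 1L)
  expect_identical(sum(one$dcfs$proportions == 0), 9L)

  # total-variation distance to the underlying spectrum shrinks ~ 1/sqrt(n)
  tv <- function(n_dc, seed) {
    po <- generate_pseudo_observed(
      pseudo_observed_spec(null_model_params(), n_dc_sites = n_dc,
                           n_trees = 5000, seed = seed))
    sum(abs(po$dcfs$proportions - po$true_dcfs$proportions)) / 2
  }
  expect_lt(tv(1e6, 63), 0.01)
  expect_gt(tv(100, 63), tv(1e6, 63))
})
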