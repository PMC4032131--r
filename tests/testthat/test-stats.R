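test_that("a doubly conditioned site with three Neandertal alleles in Europeans lands in class 3", {
  # chimp A, Neandertal G, African A, 3 of 10 European chromosomes G
  tab <- genotype_table(chimp = "A", neandertal = "G", african = "A",
                        european = matrix(c(rep("G", 3), rep("A", 7)),
                                          nrow = 1))
  x <- site_dcfs(tab)
  expect_false(x$undefined)
  expect_equal(x$proportions, c(0, 0, 1, rep(0, 7)))
  expect_equal(x$weight, 1)
})

test_that("sites failing either condition are excluded and multiallelic sites are skipped", {
  eur <- function(...) matrix(c(...), nrow = 1)
  same <- genotype_table("A", "A", "A", eur(rep("G", 10)))   # chimp == Nea
  afr_derived <- genotype_table("A", "G", "G", eur(rep("G", 10)))
  zero_freq <- genotype_table("A", "G", "A", eur(rep("A", 10)))
  for (tab in list(same, afr_derived, zero_freq)) {
    x <- site_dcfs(tab)
    expect_true(x$undefined)
    expect_equal(x$weight, 0)
  }
  tri <- genotype_table(c("A", "A"), c("G", "G"), c("A", "T"),
                        rbind(rep("G", 10), rep("G", 10)))
  x <- site_dcfs(tri)  # second site has three alleles
  expect_identical(x$skipped, 1L)
  expect_equal(x$weight, 1)
})

test_that("conditioning on the full African panel is stricter than on one chromosome", {
  afr <- matrix(c("A", "G"), nrow = 1)  # first carries chimp allele
  tab <- genotype_table("A", "G", afr,
                        matrix(c("G", rep("A", 9)), nrow = 1))
  expect_false(site_dcfs(tab)$undefined)
  expect_true(site_dcfs(tab, condition_all_africans = TRUE)$undefined)
})

test_that("branch dcfs on a hand-enumerated caterpillar gives unit weight to classes 1 and 2", {
  # (((N, E1), E2), A) with unit internal branches
  cat4 <- list(parent = c(5L, 5L, 6L, 7L, 6L, 7L, 0L),
               time = c(0, 0, 0, 0, 1, 2, 3))
  trees <- as_collection(list(cat4), roles = c(1, 3, 3, 2))
  x <- branch_dcfs(trees)
  expect_equal(x$proportions, c(0.5, 0.5))
  expect_equal(x$weight, 2)
})

test_that("dcfs weight is zero when the African sits inside the Neandertal clade", {
  # topology ((N, A), (E1, E2)): branches above (N,A) contain A
  tr <- list(parent = c(5L, 5L, 6L, 6L, 7L, 7L, 0L),
             time = c(0, 0, 0, 0, 1, 1, 2))
  trees <- as_collection(list(tr), roles = c(1, 2, 3, 3))
  x <- branch_dcfs(trees)
  expect_true(x$undefined)
  expect_equal(x$weight, 0)
})

test_that("site-based D follows its counting definition", {
  eur2 <- function(v) cbind(v, v)
  abba <- data.frame(chimp = "A", nea = "G", afr = "A", eur = "G")
  baba <- data.frame(chimp = "A", nea = "G", afr = "G", eur = "A")
  mono <- data.frame(chimp = "A", nea = "A", afr = "A", eur = "A")
  build <- function(n_abba, n_baba, n_mono = 0) {
    rows <- rbind(abba[rep(1, n_abba), ], baba[rep(1, n_baba), ],
                  mono[rep(1, n_mono), ])
    genotype_table(rows$chimp, rows$nea, rows$afr, eur2(rows$eur))
  }
  d <- patterson_d_sites(build(6, 2))
  expect_equal(d$d, 0.5)
  expect_equal(d$n_abba, 6)
  expect_equal(d$n_baba, 2)
  expect_equal(patterson_d_sites(build(4, 4))$d, 0)
  expect_true(patterson_d_sites(build(0, 0, n_mono = 5))$undefined)
})

test_that("branch D is 1 for a lone Neandertal-European cherry and flips sign under label swap", {
  # ((N, E), A) with a (N, E) stem of length 2
  tr <- list(parent = c(4L, 4L, 5L, 5L, 0L),
             time = c(0, 0, 0, 1, 3))
  trees_ne <- as_collection(list(tr), roles = c(1, 3, 2))
  expect_equal(branch_patterson_d(trees_ne)$d, 1)
  trees_swapped <- as_collection(list(tr), roles = c(1, 2, 3))
  expect_equal(branch_patterson_d(trees_swapped)$d, -1)

  demog <- build_admixture_model(small_null_params())
  trees <- simulate_replicates(demog, sample_config(n_european = 2), 500,
                               seed = 31)
  d1 <- branch_patterson_d(trees)$d
  layout <- attr(trees, "layout")
  layout$role[layout$role == 2L] <- 9L
  layout$role[layout$role == 3L] <- 2L
  layout$role[layout$role == 9L] <- 3L
  swapped <- structure(unclass(trees), class = "genealogy_list",
                       layout = layout)
  expect_equal(branch_patterson_d(swapped, european = 1)$d, -d1)
})

test_that("panel-frequency branch D agrees with the single-chromosome form in expectation", {
  p <- admixture_params(f = 0.1, n_anc = 2000, n_afr = 2000, n_eur = 2000,
                        n_nea = 2000, n_bottleneck = 2000)
  demog <- build_admixture_model(p)
  trees <- simulate_replicates(demog, sample_config(), 8000, seed = 32)
  d_single <- branch_patterson_d(trees)$d
  d_panel <- branch_patterson_d(trees, panel = TRUE)$d
  se <- block_se(trees, function(tr) branch_patterson_d(tr)$d) +
    block_se(trees, function(tr) branch_patterson_d(tr, panel = TRUE)$d)
  expect_lt(abs(d_single - d_panel), 3 * se)
})

test_that("R-squared follows the coefficient-of-determination form", {
  obs <- dcfs(c(0.5, 0.3, 0.2))
  expect_equal(r_squared(obs, obs), 100)
  # predicting the observed mean gives exactly zero
  expect_equal(r_squared(rep(1 / 3, 3), obs), 0)
  pred <- dcfs(c(0.4, 0.4, 0.2))
  expect_equal(r_squared(pred, obs), 100 * (1 - 0.02 / (0.04 + 2 / 300)),
               tolerance = 1e-8)
  expect_equal(round(r_squared(pred, obs), 1), 57.1)
  # squared-correlation variant is invariant to affine maps of the prediction
  expect_equal(r_squared(c(0.45, 0.35, 0.2), obs, method = "pearson"),
               r_squared(c(0.9, 0.7, 0.4), obs, method = "pearson"))
  expect_warning(r_squared(c(0.4, 0.3, 0.2, 0.1), dcfs(rep(0.25, 4))),
                 "constant")
  expect_true(is.na(suppressWarnings(
    r_squared(dcfs(rep(0.25, 4)), dcfs(rep(0.25, 4))))))
  expect_error(r_squared(dcfs(c(0.5, 0.5)), obs), "different numbers")
})

test_that("dcfs proportions are a probability vector whenever weight is retained", {
  demog <- build_admixture_model(small_null_params())
  set.seed(33)
  for (rep in 1:5) {
    trees <- simulate_replicates(build_admixture_model(null_model_params()),
                                 sample_config(), 200)
    x <- branch_dcfs(trees)
    if (!x$undefined) {
      expect_equal(sum(x$proportions), 1)
      expect_true(all(x$proportions >= 0))
      expect_length(x$proportions, 10)
    }
  }
})

test_that("site and branch dcfs agree on mutation-dropped data from the same trees", {
  demog <- build_admixture_model(null_model_params())
  trees <- simulate_replicates(demog, sample_config(), 4000, seed = 34)
  bd <- branch_dcfs(trees)
  gt <- dcfsim:::mutate_replicates(trees, mu = 1e-4, seed = 35)
  sd_ <- site_dcfs(gt)
  n <- sd_$weight
  se <- sqrt(pmax(bd$proportions * (1 - bd$proportions), 1e-6) / n)
  expect_true(all(abs(sd_$proportions - bd$proportions) < 4 * se))
})
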