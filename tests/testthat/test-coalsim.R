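test_that("simulation is deterministic in the seed and varies across seeds", {
  demog <- build_spatial_model(spatial_params())
  g1 <- simulate_genealogy(demog, sample_config(), seed = 7)
  g2 <- simulate_genealogy(demog, sample_config(), seed = 7)
  expect_identical(g1, g2)
  r1 <- simulate_replicates(demog, sample_config(), 5, seed = 3)
  r2 <- simulate_replicates(demog, sample_config(), 5, seed = 3)
  expect_identical(unclass(r1), unclass(r2))
  r3 <- simulate_replicates(demog, sample_config(), 5, seed = 4)
  expect_false(identical(unclass(r1), unclass(r3)))
})

test_that("a single-locus collection equals one genealogy at the derived seed", {
  demog <- build_admixture_model(small_null_params())
  r <- simulate_replicates(demog, sample_config(), 1, seed = 11)
  set.seed(11)
  derived <- sample.int(.Machine$integer.max - 1L, 1)
  g <- simulate_genealogy(demog, sample_config(), seed = derived)
  expect_identical(r[[1]]$parent, g$parent)
  expect_identical(r[[1]]$time, g$time)
})

test_that("non-coalescing configurations are reported as errors", {
  # two demes with no connecting migration or ancestry event
  demog <- chain_demography(1, 100)
  demog$demes <- rbind(demog$demes,
                       data.frame(id = "d2", label = "ancestral"))
  demog$size0 <- c(demog$size0, d2 = 100)
  demog$mig0 <- dcfsim:::empty_mig(c("d1", "d2"))
  expect_error(
    simulate_genealogy(demog,
                       sample_config(0, 0, 2, 0,
                                     demes = list(african = "d1")),
                       seed = 1),
    "no path")
  # connected but far too slow for a short horizon
  slow <- chain_demography(2, 100, 1e-9)
  expect_error(
    simulate_genealogy(slow,
                       sample_config(0, 0, 2, 0,
                                     demes = list(african = "d1")),
                       seed = 1, max_time = 10),
    "failed to coalesce")
})

test_that("single-deme pairwise TMRCA is exponential with mean 2N", {
  demog <- chain_demography(1, 500)
  sc <- sample_config(0, 0, 2, 0)
  trees <- simulate_replicates(demog, sc, 10000, seed = 5)
  tm <- vapply(trees, function(t) max(t$time), 0)
  ks <- suppressWarnings(stats::ks.test(tm, "pexp", rate = 1 / 1000))
  expect_gt(ks$p.value, 0.01)
})

test_that("the ancient Neandertal chromosome enters at its sampling time", {
  demog <- build_admixture_model(small_null_params())
  g <- simulate_genealogy(demog, sample_config(), seed = 2)
  nea_leaf <- which(g$leaf_role == 1L)
  expect_equal(g$time[nea_leaf], 2000)
  expect_true(all(g$time[setdiff(seq_len(g$n_leaves), nea_leaf)] == 0))
  expect_gt(max(g$time), 2000)
  # configurable fossil age
  g2 <- simulate_genealogy(demog,
                           sample_config(neandertal_time = 3000), seed = 2)
  expect_equal(g2$time[which(g2$leaf_role == 1L)], 3000)
})

test_that("genealogies are well formed: single root, parent above child", {
  demog <- build_spatial_model(spatial_params())
  g <- simulate_genealogy(demog, sample_config(), seed = 13)
  expect_identical(sum(g$parent == 0), 1L)
  kids <- which(g$parent > 0)
  expect_true(all(g$time[g$parent[kids]] > g$time[kids] - 1e-9))
  expect_identical(length(g$parent), 2L * g$n_leaves - 1L)
})

test_that("mutation dropping matches its Poisson expectation on a star tree", {
  star <- make_genealogy(parent = c(5, 5, 5, 5, 0),
                         time = c(0, 0, 0, 0, 500),
                         roles = c(0, 1, 2, 3))
  expect_equal(total_branch_length(star), 2000)
  # each leaf equally likely to carry the sole derived allele
  gt <- drop_mutations(star, mu = 1, seed = 8)
  counts <- colSums(gt$alleles)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)
  expect_true(all(rowSums(gt$alleles) == 1))
  # expected site count = mu * total branch length
  set.seed(9)
  n_sites <- replicate(5000, nrow(drop_mutations(star, mu = 0.02)$alleles))
  expect_lt(abs(mean(n_sites) - 40),
            3 * stats::sd(n_sites) / sqrt(length(n_sites)))
  # vanishing mutation rate leaves no sites
  expect_identical(nrow(drop_mutations(star, mu = 1e-12, seed = 1)$alleles),
                   0L)
})

test_that("newick and phylo exports preserve topology and branch lengths", {
  demog <- build_admixture_model(small_null_params())
  g <- simulate_genealogy(demog, sample_config(n_european = 3), seed = 21)
  ph <- as_phylo(g)
  expect_s3_class(ph, "phylo")
  expect_setequal(ph$tip.label, g$leaf_label)
  expect_equal(sum(ph$edge.length), total_branch_length(g), tolerance = 1e-6)

  trees <- simulate_replicates(demog, sample_config(n_european = 3), 3,
                               seed = 22)
  path <- tempfile(fileext = ".nwk")
  write_newick(trees, path, provenance = list(seed = 22))
  lines <- readLines(path)
  expect_true(any(startsWith(lines, "#")))
  nwk <- lines[!startsWith(lines, "#")]
  expect_length(nwk, 3)
  parsed <- ape::read.tree(text = nwk[1])
  expect_setequal(parsed$tip.label,
                  attr(trees, "layout")$label)
})
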