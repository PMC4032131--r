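## Synthetic inputs: pseudo-observed spectra with multinomial sampling
## noise, and toy genotype panels for worked examples.

#' Specification of a pseudo-observed dcfs
#'
#' Stands in for an empirically estimated spectrum: the generating model's
#' expected dcfs is computed from branch lengths, then `n_dc_sites` doubly
#' conditioned loci are drawn multinomially across the frequency classes
#' (loci are unlinked, hence independent).
#'
#' @param params the generating model's parameter object (any of
#'   [spatial_params()], [two_pop_params()], [admixture_params()]).
#' @param n_dc_sites number of doubly conditioned loci to draw (>= 1).
#' @param n_trees genealogies used to estimate the underlying expectation.
#' @param sample a [sample_config()].
#' @param seed master seed for both the simulation and the multinomial
#'   draw.
#' @return an object of class `pseudo_observed_spec`.
#' @export
pseudo_observed_spec <- function(params, n_dc_sites, n_trees = 20000,
                                 sample = sample_config(), seed = 1) {
  stopifnot(inherits(params, "model_params"), n_dc_sites >= 1,
            n_trees >= 1)
  structure(list(params = params, n_dc_sites = as.integer(n_dc_sites),
                 n_trees = as.integer(n_trees), sample = sample,
                 seed = as.integer(seed)),
            class = "pseudo_observed_spec")
}

#' Generate a pseudo-observed dcfs with sampling noise
#'
#' @param spec a [pseudo_observed_spec()].
#' @return a list of class `pseudo_observed`: `$dcfs` (the noisy spectrum),
#'   `$true_dcfs` (the underlying branch-length expectation) and
#'   `$provenance` (generating parameters, sample sizes and seed, enough to
#'   regenerate the draw exactly).
#' @export
generate_pseudo_observed <- function(spec) {
  stopifnot(inherits(spec, "pseudo_observed_spec"))
  demog <- build_model(spec$params)
  trees <- simulate_replicates(demog, spec$sample, spec$n_trees,
                               seed = spec$seed)
  true_dcfs <- branch_dcfs(trees)
  if (true_dcfs$undefined) {
    stop("the generating model yields no doubly conditioned branch weight; ",
         "cannot draw a pseudo-observed spectrum")
  }
  counts <- as.vector(rmultinom(1, spec$n_dc_sites, true_dcfs$proportions))
  structure(list(
    dcfs = dcfs(counts, weight = spec$n_dc_sites),
    true_dcfs = true_dcfs,
    provenance = list(model = class(spec$params)[1],
                      params = unclass(spec$params),
                      n_dc_sites = spec$n_dc_sites,
                      n_trees = spec$n_trees,
                      seed = spec$seed)
  ), class = "pseudo_observed")
}

#' Specification of a toy genotype panel
#'
#' Each site descriptor gives the chimp, Neandertal and African alleles and
#' the number of European chromosomes carrying the Neandertal allele (the
#' remaining Europeans carry the chimp allele).
#'
#' @param sites a data frame with columns `chimp`, `neandertal`, `african`
#'   and `eur_derived` (integer count, `0..nE`).
#' @param nE European panel width.
#' @return an object of class `toy_panel_spec`.
#' @export
toy_panel_spec <- function(sites, nE = 10) {
  stopifnot(is.data.frame(sites),
            all(c("chimp", "neandertal", "african", "eur_derived") %in%
                  names(sites)))
  if (any(sites$eur_derived < 0 | sites$eur_derived > nE)) {
    stop("eur_derived count outside 0..", nE, " in site descriptor ",
         which(sites$eur_derived < 0 | sites$eur_derived > nE)[1])
  }
  structure(list(sites = sites, nE = as.integer(nE)),
            class = "toy_panel_spec")
}

#' Build a toy genotype panel
#'
#' Constructs a [genotype_table()] whose [site_dcfs()] reproduces the
#' descriptor counts exactly.  An empty descriptor list yields a
#' zero-site table (whose dcfs is flagged undefined).
#'
#' @param spec a [toy_panel_spec()].
#' @return a `genotype_table`.
#' @export
build_toy_panel <- function(spec) {
  stopifnot(inherits(spec, "toy_panel_spec"))
  s <- spec$sites
  n <- nrow(s)
  nE <- spec$nE
  eur <- matrix(NA_character_, nrow = n, ncol = nE)
  for (i in seq_len(n)) {
    eur[i, ] <- c(rep(as.character(s$neandertal[i]), s$eur_derived[i]),
                  rep(as.character(s$chimp[i]), nE - s$eur_derived[i]))
  }
  genotype_table(chimp = as.character(s$chimp),
                 neandertal = as.character(s$neandertal),
                 african = as.character(s$african),
                 european = eur)
}
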