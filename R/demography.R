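#' @useDynLib dcfsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rmultinom rpois setNames
#' @importFrom utils head modifyList read.table write.table
NULL

years_to_generations <- function(years, generation_time) years / generation_time

## ---------------------------------------------------------------------------
## Parameter containers
## ---------------------------------------------------------------------------

#' Parameters of the spatial stepping-stone model
#'
#' The ancestor of Neandertals and modern humans is represented as a linear
#' chain of `k_demes` demes with nearest-neighbour migration.  Reading the
#' model forward in time: before the Neandertal split the whole chain has
#' deme size `n_anc` and migration `m0`; at the split (320 ky by default) the
#' chain is cut into a Neandertal segment and an African segment with no
#' change in demographic parameters; at `t_modern` the African demes become
#' anatomically modern (size `n_mod`, migration `m`); at `t_exit` modern
#' humans expand serially into Eurasia from the African deme closest to the
#' Neandertal range, founding one new deme every `dt_colonize` generations
#' with `founder_size` founders, each growing to `n_mod` after one
#' colonization interval.  Migration within the modern-human range stays at
#' `m` throughout: the Africa/Eurasia separation is generated by the range
#' expansion, not by a migration change.
#'
#' The eight free parameters of the model are `k_demes`, `n_anc`, `m0`,
#' `n_mod`, `m`, `t_modern`, `t_exit` and `founder_size`.  The Neandertal
#' split time, outgroup (chimp) split time, generation time and the
#' partition of the chain between the two ranges are held fixed.
#'
#' @param k_demes total chain length before the split (count of demes).
#' @param n_anc ancestral deme size (diploid individuals per deme).
#' @param m0 ancestral nearest-neighbour migration rate (per lineage per
#'   generation, each direction).
#' @param n_mod modern-human deme size (diploid individuals per deme).
#' @param m modern-human migration rate.
#' @param t_modern time (generations before present) at which African demes
#'   become anatomically modern.
#' @param t_exit time (generations) of the out-of-Africa range expansion.
#' @param founder_size number of diploid founders of each newly colonized
#'   Eurasian deme.
#' @param n_neandertal_demes demes of the ancestral chain assigned to the
#'   Neandertal range at the split (held fixed).
#' @param n_eurasian_demes length of the Eurasian extension colonized at
#'   `t_exit` (held fixed).
#' @param dt_colonize generations between successive deme foundings during
#'   the expansion; the default colonizes the whole Eurasian chain within
#'   5 ky.
#' @param generation_time years per generation.
#' @param t_neandertal_split_years Neandertal split time in years (fixed,
#'   320 ky).
#' @param outgroup_split_years chimpanzee divergence in years (fixed, 6 My).
#' @param neandertal_sampling_years age of the sampled Neandertal in years.
#' @param chimp_size diploid size of the chimpanzee stem deme (it carries a
#'   single sampled lineage, so this has no effect on the statistics).
#' @return an object of class `spatial_params`.
#' @export
spatial_params <- function(k_demes = 10,
                           n_anc = 1200,
                           m0 = 0.00021,
                           n_mod = 1200,
                           m = 0.005,
                           t_modern = 6000,
                           t_exit = 2400,
                           founder_size = 600,
                           n_neandertal_demes = 2,
                           n_eurasian_demes = 4,
                           dt_colonize = NULL,
                           generation_time = 25,
                           t_neandertal_split_years = 320e3,
                           outgroup_split_years = 6e6,
                           neandertal_sampling_years = 50e3,
                           chimp_size = 10000) {
  if (is.null(dt_colonize)) {
    dt_colonize <- floor(5000 / generation_time / n_eurasian_demes)
  }
  p <- list(
    k_demes = as.integer(k_demes), n_anc = n_anc, m0 = m0, n_mod = n_mod,
    m = m, t_modern = t_modern, t_exit = t_exit, founder_size = founder_size,
    n_neandertal_demes = as.integer(n_neandertal_demes),
    n_eurasian_demes = as.integer(n_eurasian_demes),
    dt_colonize = dt_colonize,
    generation_time = generation_time,
    t_neandertal_split = years_to_generations(t_neandertal_split_years,
                                              generation_time),
    outgroup_split = years_to_generations(outgroup_split_years,
                                          generation_time),
    neandertal_sampling_time = years_to_generations(neandertal_sampling_years,
                                                    generation_time),
    chimp_size = chimp_size
  )
  class(p) <- c("spatial_params", "model_params")
  validate_spatial_params(p)
  p
}

validate_spatial_params <- function(p) {
  stopifnot(p$k_demes >= 2, p$n_neandertal_demes >= 1,
            p$n_neandertal_demes < p$k_demes, p$n_eurasian_demes >= 1)
  check_positive(p, c("n_anc", "n_mod", "founder_size", "m0", "m",
                      "chimp_size"))
  if (!(p$t_exit < p$t_modern)) {
    stop("time ordering violated: t_exit < t_modern required (t_exit = ",
         p$t_exit, ", t_modern = ", p$t_modern, ")")
  }
  if (!(p$t_modern < p$t_neandertal_split)) {
    stop("time ordering violated: t_modern < t_neandertal_split required")
  }
  if (!(p$t_neandertal_split < p$outgroup_split)) {
    stop("time ordering violated: t_neandertal_split < outgroup_split required")
  }
  if (p$founder_size > p$n_mod) {
    stop("founder_size must not exceed n_mod")
  }
  if (p$t_exit <= p$n_eurasian_demes * p$dt_colonize) {
    stop("t_exit must exceed n_eurasian_demes * dt_colonize so every ",
         "colonized deme finishes its founding phase after time zero")
  }
  invisible(p)
}

check_positive <- function(p, fields) {
  for (f in fields) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]))
      stop("parameter ", f, " must be a single number")
    if (f %in% c("m0", "m", "m_high", "m_low")) {
      if (p[[f]] < 0) stop("parameter ", f, " must be >= 0")
    } else if (p[[f]] <= 0) {
      stop("parameter ", f, " must be > 0")
    }
  }
}

#' Parameters of the two-population ancient-structure model
#'
#' The ancestor of Neandertals and modern humans is structured into two
#' populations exchanging migrants at rate `m_high`.  Neandertal branches
#' from one of them (`t_neandertal_split`); the two populations persist as
#' anatomically modern humans until the descendant of Neandertal's parent
#' population leaves Africa at `t_ooa`, when the exchange decreases (but
#' does not stop) to `m_low`.  Backward in time the two subpopulations merge
#' into a single ancestral population of size `n_anc` at `t_structure`.
#'
#' @param n_anc size of the merged ancestral population (diploid).
#' @param n1,n2 sizes of the two ancestral subpopulations (Neandertal
#'   branches from the second).
#' @param n_afr,n_eur present-day African / European population sizes.
#' @param n_nea Neandertal population size.
#' @param m_high migration rate between the two subpopulations before the
#'   out-of-Africa event.
#' @param m_low migration rate after the out-of-Africa event.
#' @param t_structure time (generations) at which the ancestral structure
#'   arose (backward: the two subpopulations merge).
#' @param t_ooa out-of-Africa time (generations).
#' @param n_bottleneck European founder size during the out-of-Africa
#'   bottleneck, which spans from `t_ooa` until `t_bottleneck_end`
#'   (generations before present), after which the population recovers to
#'   `n_eur`.
#' @param t_bottleneck_end end of the bottleneck phase (generations).
#' @inheritParams spatial_params
#' @return an object of class `two_pop_params`.
#' @export
two_pop_params <- function(n_anc = 10000,
                           n1 = 6000, n2 = 6000,
                           n_afr = 10000, n_eur = 10000,
                           n_nea = 2500,
                           m_high = 1e-4, m_low = 2.5e-5,
                           t_structure = 19200,
                           t_ooa = 2400,
                           n_bottleneck = 1500,
                           t_bottleneck_end = 1000,
                           generation_time = 25,
                           t_neandertal_split_years = 320e3,
                           outgroup_split_years = 6e6,
                           neandertal_sampling_years = 50e3,
                           chimp_size = 10000) {
  p <- list(
    n_anc = n_anc, n1 = n1, n2 = n2, n_afr = n_afr, n_eur = n_eur,
    n_nea = n_nea, m_high = m_high, m_low = m_low,
    t_structure = t_structure, t_ooa = t_ooa,
    n_bottleneck = n_bottleneck, t_bottleneck_end = t_bottleneck_end,
    generation_time = generation_time,
    t_neandertal_split = years_to_generations(t_neandertal_split_years,
                                              generation_time),
    outgroup_split = years_to_generations(outgroup_split_years,
                                          generation_time),
    neandertal_sampling_time = years_to_generations(neandertal_sampling_years,
                                                    generation_time),
    chimp_size = chimp_size
  )
  class(p) <- c("two_pop_params", "model_params")
  check_positive(p, c("n_anc", "n1", "n2", "n_afr", "n_eur", "n_nea",
                      "n_bottleneck", "m_high", "m_low", "chimp_size"))
  if (!(p$t_bottleneck_end >= 0 && p$t_bottleneck_end < p$t_ooa)) {
    stop("time ordering violated: 0 <= t_bottleneck_end < t_ooa required")
  }
  if (!(p$t_ooa < p$t_neandertal_split &&
        p$t_neandertal_split < p$t_structure &&
        p$t_structure < p$outgroup_split)) {
    stop("time ordering violated: t_ooa < t_neandertal_split < t_structure ",
         "< outgroup_split required")
  }
  p
}

#' Parameters of the clean-split model with an optional admixture pulse
#'
#' A panmictic ancestral population of size `n_anc` from which Neandertal
#' splits at `t_neandertal_split`; modern humans then split into Africans and
#' Europeans at `t_ooa`, the European founders passing through a bottleneck
#' of size `n_bottleneck` lasting `bottleneck_duration` generations.  A
#' hybridization pulse moves a fraction `f` of European lineages into the
#' Neandertal population at `t_admix` (backward-time reading).  With `f = 0`
#' the model is the clean-split null.  The nine free parameters are `n_anc`,
#' `n_afr`, `n_eur`, `n_nea`, `t_neandertal_split`, `t_ooa`, `n_bottleneck`,
#' `t_admix` and `f`.
#'
#' With `variant = "two_pop"` the pulse is grafted onto a two-population
#' ancient-structure model supplied in `base` instead.
#'
#' @param f admixture fraction in `[0, 1]`.
#' @param t_admix time of the pulse (generations); must precede `t_ooa`.
#' @param n_bottleneck European founder population size at the out-of-Africa
#'   split.
#' @param bottleneck_duration generations the founder size persists before
#'   growth to `n_eur` (held fixed).
#' @param t_neandertal_split Neandertal split time in generations (free in
#'   this model).
#' @param variant `"clean_split"` (default) or `"two_pop"`.
#' @param base a [two_pop_params()] object, used when
#'   `variant = "two_pop"`.
#' @inheritParams two_pop_params
#' @return an object of class `admixture_params`.
#' @export
admixture_params <- function(f = 0.03,
                             t_admix = 2200,
                             n_anc = 10000,
                             n_afr = 10000, n_eur = 10000,
                             n_nea = 2500,
                             n_bottleneck = 1500,
                             t_neandertal_split = 12800,
                             t_ooa = 2400,
                             bottleneck_duration = 100,
                             variant = c("clean_split", "two_pop"),
                             base = NULL,
                             generation_time = 25,
                             outgroup_split_years = 6e6,
                             neandertal_sampling_years = 50e3,
                             chimp_size = 10000) {
  variant <- match.arg(variant)
  if (f < 0 || f > 1) stop("admixture fraction f must lie in [0, 1]")
  p <- list(
    f = f, t_admix = t_admix, n_anc = n_anc, n_afr = n_afr, n_eur = n_eur,
    n_nea = n_nea, n_bottleneck = n_bottleneck,
    t_neandertal_split = t_neandertal_split, t_ooa = t_ooa,
    bottleneck_duration = bottleneck_duration, variant = variant,
    base = base,
    generation_time = generation_time,
    outgroup_split = years_to_generations(outgroup_split_years,
                                          generation_time),
    neandertal_sampling_time = years_to_generations(neandertal_sampling_years,
                                                    generation_time),
    chimp_size = chimp_size
  )
  class(p) <- c("admixture_params", "model_params")
  if (variant == "clean_split") {
    check_positive(p, c("n_anc", "n_afr", "n_eur", "n_nea", "n_bottleneck",
                        "chimp_size"))
    if (!(p$t_admix < p$t_ooa && p$t_ooa < p$t_neandertal_split &&
          p$t_neandertal_split < p$outgroup_split)) {
      stop("time ordering violated: t_admix < t_ooa < t_neandertal_split ",
           "< outgroup_split required")
    }
    if (p$t_ooa - p$bottleneck_duration <= 0) {
      stop("bottleneck_duration must be smaller than t_ooa")
    }
  } else {
    if (is.null(base) || !inherits(base, "two_pop_params")) {
      stop("variant = \"two_pop\" requires a two_pop_params object in `base`")
    }
    if (!(p$t_admix < base$t_ooa)) {
      stop("time ordering violated: t_admix < t_ooa required")
    }
  }
  p
}

## ---------------------------------------------------------------------------
## Demography container
## ---------------------------------------------------------------------------

dem_event <- function(time, kind, type, deme = NA_character_,
                      from = NA_character_, to = NA_character_,
                      value = NA_real_) {
  list(time = time, kind = kind, type = type, deme = deme,
       from = from, to = to, value = value)
}

# deterministic ordering of simultaneous events: mergers, then parameter
# changes (including chain splits), then expansions, then admixture pulses;
# ties broken by the affected deme id
event_kind_rank <- c(deme_merge = 1, parameter_change = 2, chain_split = 2,
                     range_expansion = 3, mass_migration = 4)

new_demography <- function(model, deme_ids, labels, size0, mig0, events,
                           generation_time, outgroup_split_time, root_deme,
                           sample_demes, params, free_parameters) {
  ord <- order(vapply(events, `[[`, 0, "time"),
               event_kind_rank[vapply(events, `[[`, "", "kind")],
               vapply(events, function(e) {
                 if (!is.na(e$deme)) e$deme else if (!is.na(e$from)) e$from
                 else ""
               }, ""))
  structure(list(
    model = model,
    demes = data.frame(id = deme_ids, label = labels,
                       stringsAsFactors = FALSE),
    size0 = setNames(size0, deme_ids),
    mig0 = mig0,
    events = events[ord],
    generation_time = generation_time,
    outgroup_split_time = outgroup_split_time,
    root_deme = root_deme,
    sample_demes = sample_demes,
    params = params,
    free_parameters = free_parameters
  ), class = "demography")
}

#' @method print demography
#' @export
print.demography <- function(x, ...) {
  cat("<demography>", x$model, "model:", nrow(x$demes), "demes,",
      length(x$events), "events\n")
  cat("  free parameters (", length(x$free_parameters), "): ",
      paste(x$free_parameters, collapse = ", "), "\n", sep = "")
  cat("  outgroup split:", x$outgroup_split_time, "generations\n")
  invisible(x)
}

#' Free parameters of a demographic model
#'
#' @param demog a `demography` object.
#' @return character vector naming the model's free parameters.
#' @export
free_params <- function(demog) {
  stopifnot(inherits(demog, "demography"))
  demog$free_parameters
}

#' Event table of a demographic model
#'
#' @param demog a `demography` object.
#' @return a data frame with columns `time_generations`, `kind` and
#'   `payload`, one row per demographic event, ordered as applied.
#' @export
event_table <- function(demog) {
  stopifnot(inherits(demog, "demography"))
  payload <- vapply(demog$events, function(e) {
    switch(e$type,
      size = paste0("size ", e$deme, " = ", e$value),
      migration = paste0("migration ", e$from, " -> ", e$to, " = ", e$value),
      move = paste0("move ", e$from, " -> ", e$to,
                    " fraction ", e$value))
  }, "")
  data.frame(
    time_generations = vapply(demog$events, `[[`, 0, "time"),
    kind = vapply(demog$events, `[[`, "", "kind"),
    payload = payload,
    stringsAsFactors = FALSE
  )
}

empty_mig <- function(ids) {
  matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
}

set_sym <- function(m, a, b, rate) {
  m[a, b] <- rate
  m[b, a] <- rate
  m
}

## ---------------------------------------------------------------------------
## Model builders
## ---------------------------------------------------------------------------

#' Build the spatial stepping-stone demography
#'
#' Constructs the chain-of-demes model described in [spatial_params()] as a
#' time-stamped deme graph ready for [simulate_genealogy()].  Deme ids run
#' `nea1..neaJ` (Neandertal range, `nea1` at the far chain end),
#' `afr1..afrK` (`afr1` adjacent to the former Neandertal range) and
#' `eur1..eurE` (the Eurasian extension, colonized from `afr1` outward).
#' Default sampling demes place the Neandertal at `nea1`, the African at the
#' chain end farthest from the Neandertal range, and the Europeans in the
#' terminal Eurasian deme.
#'
#' @param params a [spatial_params()] object.
#' @return a `demography` object.
#' @export
build_spatial_model <- function(params) {
  stopifnot(inherits(params, "spatial_params"))
  p <- validate_spatial_params(params)
  nN <- p$n_neandertal_demes
  nA <- p$k_demes - nN
  nE <- p$n_eurasian_demes
  nea <- paste0("nea", seq_len(nN))
  afr <- paste0("afr", seq_len(nA))
  eur <- paste0("eur", seq_len(nE))
  ids <- c(nea, afr, eur, "chimp", "root")
  labels <- c(rep("neandertal", nN), rep("african", nA),
              rep("eurasian", nE), "chimp-stem", "ancestral")
  size0 <- c(rep(p$n_anc, nN), rep(p$n_mod, nA), rep(p$n_mod, nE),
             p$chimp_size, p$n_anc)

  mig0 <- empty_mig(ids)
  # Neandertal range keeps the ancestral parameters throughout
  for (i in seq_len(nN - 1)) mig0 <- set_sym(mig0, nea[i], nea[i + 1], p$m0)
  # modern-human range: African chain + Eurasian extension, all at rate m
  for (i in seq_len(nA - 1)) mig0 <- set_sym(mig0, afr[i], afr[i + 1], p$m)
  mig0 <- set_sym(mig0, "afr1", "eur1", p$m)
  for (i in seq_len(nE - 1)) mig0 <- set_sym(mig0, eur[i], eur[i + 1], p$m)

  ev <- list()
  # serial colonization of Eurasia, reversed backward in time: eur1 founded
  # at t_exit from afr1, then one deme per dt_colonize interval outward
  for (j in seq_len(nE)) {
    t_found <- p$t_exit - (j - 1) * p$dt_colonize
    src <- if (j == 1) "afr1" else eur[j - 1]
    ev <- c(ev, list(
      dem_event(t_found, "range_expansion", "move", from = eur[j], to = src,
                value = 1),
      dem_event(t_found - p$dt_colonize, "range_expansion", "size",
                deme = eur[j], value = p$founder_size)
    ))
    # the deme (and its edges) does not exist before its founding
    ev <- c(ev, list(
      dem_event(t_found, "range_expansion", "migration", from = eur[j],
                to = src, value = 0),
      dem_event(t_found, "range_expansion", "migration", from = src,
                to = eur[j], value = 0)
    ))
    if (j < nE) {
      ev <- c(ev, list(
        dem_event(t_found, "range_expansion", "migration", from = eur[j],
                  to = eur[j + 1], value = 0),
        dem_event(t_found, "range_expansion", "migration", from = eur[j + 1],
                  to = eur[j], value = 0)
      ))
    }
  }
  # African demes revert to the ancestral regime beyond t_modern
  for (i in seq_len(nA)) {
    ev <- c(ev, list(dem_event(p$t_modern, "parameter_change", "size",
                               deme = afr[i], value = p$n_anc)))
  }
  for (i in seq_len(nA - 1)) {
    ev <- c(ev, list(
      dem_event(p$t_modern, "parameter_change", "migration", from = afr[i],
                to = afr[i + 1], value = p$m0),
      dem_event(p$t_modern, "parameter_change", "migration", from = afr[i + 1],
                to = afr[i], value = p$m0)
    ))
  }
  # the chain is whole before the Neandertal split, same parameters
  ev <- c(ev, list(
    dem_event(p$t_neandertal_split, "chain_split", "migration",
              from = nea[nN], to = "afr1", value = p$m0),
    dem_event(p$t_neandertal_split, "chain_split", "migration",
              from = "afr1", to = nea[nN], value = p$m0)
  ))
  # chimp divergence: everything merges into the root deme and the chain's
  # migration edges cease to exist
  for (d in setdiff(ids, "root")) {
    ev <- c(ev, list(dem_event(p$outgroup_split, "deme_merge", "move",
                               from = d, to = "root", value = 1)))
  }
  chain_adj <- rbind(
    if (nN > 1) cbind(nea[-nN], nea[-1]),
    if (nA > 1) cbind(afr[-nA], afr[-1]),
    cbind(nea[nN], "afr1")
  )
  for (r in seq_len(nrow(chain_adj))) {
    ev <- c(ev, list(
      dem_event(p$outgroup_split, "parameter_change", "migration",
                from = chain_adj[r, 1], to = chain_adj[r, 2], value = 0),
      dem_event(p$outgroup_split, "parameter_change", "migration",
                from = chain_adj[r, 2], to = chain_adj[r, 1], value = 0)
    ))
  }

  new_demography(
    model = "spatial", deme_ids = ids, labels = labels, size0 = size0,
    mig0 = mig0, events = ev, generation_time = p$generation_time,
    outgroup_split_time = p$outgroup_split, root_deme = "root",
    sample_demes = list(chimp = "chimp", neandertal = "nea1",
                        african = afr[nA], european = eur[nE]),
    params = p,
    free_parameters = c("k_demes", "n_anc", "m0", "n_mod", "m",
                        "t_modern", "t_exit", "founder_size")
  )
}

#' Build the two-population ancient-structure demography
#'
#' @param params a [two_pop_params()] object.
#' @return a `demography` object.  Deme `afrA` is the population that stays
#'   African; `afrB` is Neandertal's parent population, whose descendants
#'   colonize Eurasia at the out-of-Africa event.
#' @export
build_two_population_model <- function(params) {
  stopifnot(inherits(params, "two_pop_params"))
  p <- params
  ids <- c("afrA", "afrB", "nea", "chimp", "root")
  labels <- c("african", "eurasian", "neandertal", "chimp-stem", "ancestral")
  size0 <- c(p$n_afr, p$n_eur, p$n_nea, p$chimp_size, p$n_anc)
  mig0 <- empty_mig(ids)
  mig0 <- set_sym(mig0, "afrA", "afrB", p$m_low)
  ev <- list(
    dem_event(p$t_bottleneck_end, "parameter_change", "size", deme = "afrB",
              value = p$n_bottleneck),
    dem_event(p$t_ooa, "parameter_change", "migration", from = "afrA",
              to = "afrB", value = p$m_high),
    dem_event(p$t_ooa, "parameter_change", "migration", from = "afrB",
              to = "afrA", value = p$m_high),
    dem_event(p$t_ooa, "parameter_change", "size", deme = "afrA",
              value = p$n1),
    dem_event(p$t_ooa, "parameter_change", "size", deme = "afrB",
              value = p$n2),
    dem_event(p$t_neandertal_split, "deme_merge", "move", from = "nea",
              to = "afrB", value = 1),
    dem_event(p$t_structure, "deme_merge", "move", from = "afrB",
              to = "afrA", value = 1),
    dem_event(p$t_structure, "parameter_change", "size", deme = "afrA",
              value = p$n_anc),
    dem_event(p$t_structure, "parameter_change", "migration", from = "afrA",
              to = "afrB", value = 0),
    dem_event(p$t_structure, "parameter_change", "migration", from = "afrB",
              to = "afrA", value = 0)
  )
  for (d in c("afrA", "afrB", "nea", "chimp")) {
    ev <- c(ev, list(dem_event(p$outgroup_split, "deme_merge", "move",
                               from = d, to = "root", value = 1)))
  }
  new_demography(
    model = "two_pop", deme_ids = ids, labels = labels, size0 = size0,
    mig0 = mig0, events = ev, generation_time = p$generation_time,
    outgroup_split_time = p$outgroup_split, root_deme = "root",
    sample_demes = list(chimp = "chimp", neandertal = "nea",
                        african = "afrA", european = "afrB"),
    params = p,
    free_parameters = c("n_anc", "n1", "n2", "n_afr", "n_eur", "n_nea",
                        "m_high", "m_low", "t_structure", "t_ooa")
  )
}

#' Build the clean-split demography with an optional admixture pulse
#'
#' With the default `clean_split` variant this is the nine-parameter
#' admixture model: a panmictic ancestor, a Neandertal split, an
#' out-of-Africa split with bottleneck, and a pulse moving a fraction `f` of
#' European lineages into Neandertal at `t_admix` (backward in time).  With
#' `f = 0` the pulse is omitted and the model is the clean-split null used
#' as the no-structure baseline.  With `variant = "two_pop"` the pulse is
#' added to the two-population ancient-structure model instead.
#'
#' @param params an [admixture_params()] object.
#' @return a `demography` object.
#' @export
build_admixture_model <- function(params) {
  stopifnot(inherits(params, "admixture_params"))
  p <- params
  if (p$variant == "two_pop") {
    demog <- build_two_population_model(p$base)
    if (p$f > 0) {
      demog$events <- c(demog$events, list(
        dem_event(p$t_admix, "mass_migration", "move", from = "afrB",
                  to = "nea", value = p$f)
      ))
      ord <- order(vapply(demog$events, `[[`, 0, "time"),
                   event_kind_rank[vapply(demog$events, `[[`, "", "kind")])
      demog$events <- demog$events[ord]
    }
    demog$model <- "admixture"
    demog$params <- p
    demog$free_parameters <- c(demog$free_parameters, "t_admix", "f")
    return(demog)
  }
  ids <- c("afr", "eur", "nea", "chimp", "root")
  labels <- c("african", "eurasian", "neandertal", "chimp-stem", "ancestral")
  size0 <- c(p$n_afr, p$n_eur, p$n_nea, p$chimp_size, p$n_anc)
  mig0 <- empty_mig(ids)
  ev <- list(
    dem_event(p$t_ooa - p$bottleneck_duration, "parameter_change", "size",
              deme = "eur", value = p$n_bottleneck),
    dem_event(p$t_ooa, "deme_merge", "move", from = "eur", to = "afr",
              value = 1),
    dem_event(p$t_neandertal_split, "deme_merge", "move", from = "nea",
              to = "afr", value = 1),
    dem_event(p$t_neandertal_split, "parameter_change", "size", deme = "afr",
              value = p$n_anc)
  )
  if (p$f > 0) {
    ev <- c(ev, list(dem_event(p$t_admix, "mass_migration", "move",
                               from = "eur", to = "nea", value = p$f)))
  }
  for (d in c("afr", "eur", "nea", "chimp")) {
    ev <- c(ev, list(dem_event(p$outgroup_split, "deme_merge", "move",
                               from = d, to = "root", value = 1)))
  }
  new_demography(
    model = "admixture", deme_ids = ids, labels = labels, size0 = size0,
    mig0 = mig0, events = ev, generation_time = p$generation_time,
    outgroup_split_time = p$outgroup_split, root_deme = "root",
    sample_demes = list(chimp = "chimp", neandertal = "nea",
                        african = "afr", european = "eur"),
    params = p,
    free_parameters = c("n_anc", "n_afr", "n_eur", "n_nea",
                        "t_neandertal_split", "t_ooa", "n_bottleneck",
                        "t_admix", "f")
  )
}

## ---------------------------------------------------------------------------
## Compilation to epochs and validation
## ---------------------------------------------------------------------------

# Flatten the event list into piecewise-constant epochs for the simulator:
# breaks (ascending times), per-epoch size matrix and migration matrices,
# and per-break lineage-movement actions.
compile_demography <- function(demog) {
  ids <- demog$demes$id
  K <- length(ids)
  idx <- setNames(seq_len(K), ids)
  times <- sort(unique(vapply(demog$events, `[[`, 0, "time")))
  times <- times[times > 0]
  n_epochs <- length(times) + 1

  sizes <- matrix(0, K, n_epochs, dimnames = list(ids, NULL))
  sizes[, 1] <- demog$size0[ids]
  migs <- vector("list", n_epochs)
  migs[[1]] <- demog$mig0[ids, ids, drop = FALSE]
  actions <- vector("list", length(times))

  cur_size <- sizes[, 1]
  cur_mig <- migs[[1]]
  for (e in seq_along(times)) {
    moves_from <- integer(0)
    moves_to <- integer(0)
    moves_frac <- numeric(0)
    for (ev in demog$events) {
      if (ev$time != times[e]) next
      if (ev$type == "size") {
        cur_size[ev$deme] <- ev$value
      } else if (ev$type == "migration") {
        cur_mig[ev$from, ev$to] <- ev$value
      } else if (ev$type == "move") {
        moves_from <- c(moves_from, idx[[ev$from]] - 1L)
        moves_to <- c(moves_to, idx[[ev$to]] - 1L)
        moves_frac <- c(moves_frac, ev$value)
      }
    }
    actions[[e]] <- list(from = moves_from, to = moves_to, frac = moves_frac)
    sizes[, e + 1] <- cur_size
    migs[[e + 1]] <- cur_mig
  }
  list(ids = ids, breaks = times, sizes = sizes, migs = migs,
       actions = actions)
}

#' Validate a demographic model
#'
#' Checks the structural invariants of a `demography` object: positive deme
#' sizes at all times, non-negative migration rates, events referencing
#' existing demes, no migration into or out of a deme after it has merged
#' away, connectivity of all sampled demes to the root, and model-specific
#' rules (for the two-population model, post-out-of-Africa migration must be
#' lower than the ancestral rate).
#'
#' @param demog a `demography` object.
#' @return a character vector of issues, each naming the violated invariant
#'   and the offending element; empty when the model is well formed.
#'   Problems are returned, never raised.
#' @export
validate_demography <- function(demog) {
  issues <- character(0)
  ids <- demog$demes$id
  if (anyDuplicated(ids)) {
    issues <- c(issues, paste0("duplicate deme id: ",
                               ids[duplicated(ids)][1]))
  }
  for (ev in demog$events) {
    refs <- c(ev$deme, ev$from, ev$to)
    refs <- refs[!is.na(refs)]
    bad <- setdiff(refs, ids)
    if (length(bad)) {
      issues <- c(issues,
                  paste0("event at time ", ev$time,
                         " references unknown deme: ", bad[1]))
    }
    if (ev$time < 0) {
      issues <- c(issues, paste0("event with negative time: ", ev$time))
    }
  }
  comp <- tryCatch(compile_demography(demog), error = function(e) NULL)
  if (is.null(comp)) {
    return(c(issues, "demography could not be compiled into epochs"))
  }
  for (e in seq_len(ncol(comp$sizes))) {
    bad <- comp$ids[comp$sizes[, e] <= 0]
    for (d in bad) {
      issues <- c(issues, paste0("non-positive size for deme ", d,
                                 " in epoch ", e))
    }
    if (any(comp$migs[[e]] < 0)) {
      w <- which(comp$migs[[e]] < 0, arr.ind = TRUE)[1, ]
      issues <- c(issues, paste0("negative migration rate ",
                                 comp$ids[w[1]], " -> ", comp$ids[w[2]],
                                 " in epoch ", e))
    }
  }
  # once a deme has fully merged away, no migration edge may touch it
  retire_epoch <- rep(Inf, length(comp$ids))
  names(retire_epoch) <- comp$ids
  for (e in seq_along(comp$breaks)) {
    act <- comp$actions[[e]]
    for (a in seq_along(act$from)) {
      if (act$frac[a] >= 1) {
        d <- comp$ids[act$from[a] + 1L]
        retire_epoch[d] <- min(retire_epoch[d], e + 1)
      }
      # a later inbound move revives the deme (not used by the builders)
      d_to <- comp$ids[act$to[a] + 1L]
      retire_epoch[d_to] <- Inf
    }
  }
  for (d in comp$ids) {
    re <- retire_epoch[[d]]
    if (!is.finite(re)) next
    for (e in seq(re, length(comp$migs))) {
      if (any(comp$migs[[e]][d, ] > 0) || any(comp$migs[[e]][, d] > 0)) {
        issues <- c(issues, paste0("migration edge touches deme ", d,
                                   " after its merge (epoch ", e, ")"))
        break
      }
    }
  }
  # every deme must reach the root through migration or merge events so all
  # lineage pairs have finite expected coalescence time
  reach <- reaches_root(comp, demog$root_deme)
  for (d in comp$ids[!reach]) {
    issues <- c(issues, paste0("deme ", d, " has no path (migration or ",
                               "ancestry event) to the root deme"))
  }
  if (identical(demog$model, "two_pop") &&
      demog$params$m_low >= demog$params$m_high) {
    issues <- c(issues, paste0(
      "warning: post-out-of-Africa migration (m_low = ",
      demog$params$m_low, ") is not lower than the ancestral rate ",
      "(m_high = ", demog$params$m_high,
      "); the exchange should decrease, not stop or grow"))
  }
  issues
}

#' A bare stepping-stone chain
#'
#' A time-homogeneous linear chain of demes with symmetric nearest-neighbour
#' migration and no demographic events.  Mainly a test bed for coalescent
#' properties: migration is conservative on this graph, so the mean
#' within-deme pairwise coalescence time equals that of a panmictic
#' population of the total size (2 k N generations for diploid demes),
#' independent of the migration rate.  With `k_demes = 1` it is a single
#' panmictic deme.
#'
#' @param k_demes chain length.
#' @param deme_size diploid size of every deme.
#' @param migration nearest-neighbour migration rate (per lineage per
#'   generation, each direction); ignored when `k_demes = 1`.
#' @param generation_time years per generation (metadata only).
#' @return a `demography` object with demes `d1..dk`; all default sampling
#'   demes point at `d1`.
#' @export
chain_demography <- function(k_demes, deme_size, migration = 0,
                             generation_time = 25) {
  stopifnot(k_demes >= 1, deme_size > 0, migration >= 0)
  ids <- paste0("d", seq_len(k_demes))
  mig0 <- empty_mig(ids)
  for (i in seq_len(k_demes - 1)) {
    mig0 <- set_sym(mig0, ids[i], ids[i + 1], migration)
  }
  if (k_demes > 1 && migration <= 0) {
    stop("a chain with more than one deme needs migration > 0 to coalesce")
  }
  new_demography(
    model = "chain", deme_ids = ids, labels = rep("ancestral", k_demes),
    size0 = rep(deme_size, k_demes), mig0 = mig0, events = list(),
    generation_time = generation_time, outgroup_split_time = NA_real_,
    root_deme = ids[1],
    sample_demes = list(chimp = ids[1], neandertal = ids[1],
                        african = ids[1], european = ids[1]),
    params = list(neandertal_sampling_time = 0),
    free_parameters = character(0)
  )
}

# breadth-first closure: a deme reaches the root if, in some epoch, it can
# migrate to (or is moved into) a deme that reaches the root
reaches_root <- function(comp, root) {
  K <- length(comp$ids)
  reach <- comp$ids == root
  repeat {
    changed <- FALSE
    for (e in seq_along(comp$migs)) {
      m <- comp$migs[[e]]
      for (i in seq_len(K)) {
        if (reach[i]) next
        if (any(m[i, ] > 0 & reach)) {
          reach[i] <- TRUE
          changed <- TRUE
        }
      }
    }
    for (e in seq_along(comp$actions)) {
      act <- comp$actions[[e]]
      for (a in seq_along(act$from)) {
        i <- act$from[a] + 1L
        j <- act$to[a] + 1L
        if (!reach[i] && reach[j] && act$frac[a] >= 1) {
          reach[i] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  reach
}
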