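## Parameter sweeps, subsetting by Patterson's D, and ranking by dcfs fit.

#' Build a demography from a parameter object
#'
#' Dispatches to the matching model builder.
#'
#' @param params a [spatial_params()], [two_pop_params()] or
#'   [admixture_params()] object.
#' @return a `demography` object.
#' @export
build_model <- function(params) {
  if (inherits(params, "spatial_params")) return(build_spatial_model(params))
  if (inherits(params, "two_pop_params")) {
    return(build_two_population_model(params))
  }
  if (inherits(params, "admixture_params")) {
    return(build_admixture_model(params))
  }
  stop("not a recognized model parameter object")
}

apply_overrides <- function(base, changes) {
  p <- base
  for (nm in names(changes)) {
    if (!nm %in% names(p)) stop("unknown parameter in sweep grid: ", nm)
    p[[nm]] <- changes[[nm]]
  }
  if (inherits(p, "spatial_params")) validate_spatial_params(p)
  if (inherits(p, "admixture_params") && (p$f < 0 || p$f > 1)) {
    stop("admixture fraction f must lie in [0, 1]")
  }
  p
}

#' Specification of a demographic parameter sweep
#'
#' @param base the parameter object whose fields the grid overrides.
#' @param grid named list of value vectors; the sweep evaluates their full
#'   cross product.
#' @param target_d observed Patterson's D to subset around (default the
#'   African/European reference value 0.0457).
#' @param tol_d absolute tolerance on D for [filter_by_d()] (default
#'   0.0020).
#' @param n_trees genealogies simulated per parameter combination.
#' @param sample a [sample_config()]; the default ten-chromosome European
#'   panel serves both the dcfs and (through its first chromosome) D.
#' @param seed master seed; every combination derives its own seed from it.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(base, grid, target_d = 0.0457, tol_d = 0.0020,
                       n_trees = 20000, sample = sample_config(),
                       seed = 1) {
  stopifnot(inherits(base, "model_params"), tol_d > 0, n_trees >= 1)
  if (length(grid) == 0 || any(lengths(grid) == 0)) {
    stop("sweep grid must be nonempty")
  }
  if (is.null(names(grid)) || any(names(grid) == "")) {
    stop("every grid component must be named after a parameter")
  }
  structure(list(base = base, grid = grid, target_d = target_d,
                 tol_d = tol_d, n_trees = as.integer(n_trees),
                 sample = sample, seed = as.integer(seed)),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' Evaluates every grid point independently: builds the demography,
#' simulates `n_trees` unlinked genealogies, and records the
#' branch-expectation Patterson's D and dcfs.  The branch (expectation)
#' path is used because the D filter targets the statistic's expectation
#' and branch lengths are free of mutation-rate noise.  Each combination
#' has its own seed derived from the master seed, so results do not depend
#' on evaluation order and any single record can be re-simulated exactly.
#'
#' @param spec a [sweep_spec()].
#' @return a `fit_records` data frame: one row per grid point with the
#'   swept parameter values, `d`, the dcfs proportions (list column
#'   `dcfs`), `n_trees`, `seed`, and an `error` column (`NA` on success;
#'   per-combination failures are recorded, not raised).
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  combos <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  set.seed(spec$seed)
  combo_seeds <- sample.int(.Machine$integer.max - 1L, nrow(combos))
  model <- class(spec$base)[1]
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    changes <- as.list(combos[i, , drop = FALSE])
    rec <- list(model = model, d = NA_real_, dcfs = list(NULL),
                n_trees = spec$n_trees, seed = combo_seeds[i],
                error = NA_character_)
    res <- tryCatch({
      params <- apply_overrides(spec$base, changes)
      demog <- build_model(params)
      trees <- simulate_replicates(demog, spec$sample, spec$n_trees,
                                   seed = combo_seeds[i])
      list(d = branch_patterson_d(trees)$d,
           dcfs = if (spec$sample$n_european >= 2) branch_dcfs(trees))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rec$error <- res
    } else {
      rec$d <- res$d
      rec$dcfs <- list(res$dcfs)
    }
    rows[[i]] <- cbind(combos[i, , drop = FALSE],
                       data.frame(model = rec$model, d = rec$d,
                                  n_trees = rec$n_trees, seed = rec$seed,
                                  error = rec$error,
                                  stringsAsFactors = FALSE))
    rows[[i]]$dcfs <- rec$dcfs
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "swept") <- names(spec$grid)
  attr(out, "target_d") <- spec$target_d
  attr(out, "tol_d") <- spec$tol_d
  class(out) <- c("fit_records", "data.frame")
  out
}

restore_fit_records <- function(records, template) {
  attr(records, "swept") <- attr(template, "swept")
  attr(records, "target_d") <- attr(template, "target_d")
  attr(records, "tol_d") <- attr(template, "tol_d")
  class(records) <- c("fit_records", "data.frame")
  records
}

#' Subset sweep records by agreement with an observed D
#'
#' Retains exactly the records with `|d - target_d| <= tol_d`,
#' order-preserving.  Records whose simulation failed (`d` is `NA`) are
#' dropped.  An empty result is valid and reported via a message.
#'
#' @param records a `fit_records` data frame from [run_sweep()].
#' @param target_d,tol_d the subsetting criterion; default to the values
#'   recorded in the sweep (reference D 0.0457, tolerance 0.0020).
#' @return the retained records, same class.
#' @export
filter_by_d <- function(records, target_d = NULL, tol_d = NULL) {
  stopifnot(inherits(records, "fit_records"), nrow(records) > 0)
  if (is.null(target_d)) target_d <- attr(records, "target_d")
  if (is.null(tol_d)) tol_d <- attr(records, "tol_d")
  keep <- !is.na(records$d) & abs(records$d - target_d) <= tol_d
  out <- restore_fit_records(records[keep, , drop = FALSE], records)
  if (nrow(out) == 0) {
    message("no parameter combination predicts D within ", tol_d,
            " of ", target_d)
  }
  out
}

#' Rank sweep records by dcfs fit
#'
#' Computes each record's R-squared against the observed dcfs and sorts
#' descending; records with an undefined R-squared sort last; ties are
#' broken by the lexicographic order of the swept parameter values so the
#' ranking is deterministic and invariant to input order.
#'
#' @param records a `fit_records` data frame.
#' @param observed a `dcfs` object (or proportion vector).
#' @return the records with an `r2` column, sorted by decreasing fit.
#' @export
rank_by_r2 <- function(records, observed) {
  stopifnot(inherits(records, "fit_records"), nrow(records) > 0)
  r2 <- vapply(records$dcfs, function(d) {
    if (is.null(d) || d$undefined) return(NA_real_)
    suppressWarnings(r_squared(d, observed))
  }, 0)
  records$r2 <- r2
  key <- -r2
  key[is.na(key)] <- Inf
  swept <- intersect(attr(records, "swept"), names(records))
  ord <- do.call(order, c(list(key), as.list(records[swept])))
  restore_fit_records(records[ord, , drop = FALSE], records)
}

#' Compare the three demographic models on an observed dcfs
#'
#' The headline comparison surface: for each model's (D-filtered) records,
#' the best R-squared, the best-fit dcfs vector, and the rare-allele
#' (class 1 and class 2) proportions.
#'
#' @param spatial_records,structure_records,admixture_records nonempty
#'   `fit_records` for the spatial stepping-stone, two-population
#'   ancient-structure, and admixture models.
#' @param observed a `dcfs` object.
#' @return an object of class `model_comparison`: `$summary` (data frame
#'   with model, best r2, class-1 and class-2 proportions), `$best_dcfs`
#'   (named list of proportion vectors) and `$observed`.
#' @export
compare_models <- function(spatial_records, structure_records,
                           admixture_records, observed) {
  pick_best <- function(records) {
    stopifnot(inherits(records, "fit_records"), nrow(records) > 0)
    ranked <- rank_by_r2(records, observed)
    ranked[1, , drop = FALSE]
  }
  best <- list(spatial = pick_best(spatial_records),
               two_pop = pick_best(structure_records),
               admixture = pick_best(admixture_records))
  summary <- do.call(rbind, lapply(names(best), function(nm) {
    b <- best[[nm]]
    p <- b$dcfs[[1]]$proportions
    data.frame(model = nm, r2 = b$r2, d = b$d,
               class1 = p[1], class2 = p[2],
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  obs <- if (inherits(observed, "dcfs")) observed$proportions else observed
  structure(list(summary = summary,
                 best_dcfs = lapply(best, function(b) {
                   b$dcfs[[1]]$proportions
                 }),
                 best_records = best,
                 observed = obs),
            class = "model_comparison")
}

#' @method print model_comparison
#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> best fits against the observed dcfs\n")
  df <- x$summary
  df$r2 <- sprintf("%.1f%%", df$r2)
  df$class1 <- round(df$class1, 4)
  df$class2 <- round(df$class2, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
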