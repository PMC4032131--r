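## Structured-coalescent simulation of genealogies under a demography.

#' Sample configuration
#'
#' Describes the chromosomes drawn from a demography: one chimpanzee
#' chromosome, one Neandertal (sampled in the past), one or more African
#' chromosomes, and a European panel of `n_european` chromosomes (ten by
#' default, i.e. five diploid Europeans).  Sampling demes default to the
#' demography's own suggestions and can be overridden per population class.
#'
#' @param n_chimp,n_neandertal,n_african,n_european chromosome counts;
#'   `n_european` must be at least 2 so the spectrum has at least two
#'   frequency classes.
#' @param demes optional named list overriding the sampling demes, with any
#'   of the names `chimp`, `neandertal`, `african`, `european`.
#' @param neandertal_time sampling time of the Neandertal chromosome in
#'   generations before present; `NULL` uses the demography's configured
#'   fossil age (50 ky by default).
#' @return an object of class `sample_config`.
#' @export
sample_config <- function(n_chimp = 1, n_neandertal = 1, n_african = 1,
                          n_european = 10, demes = NULL,
                          neandertal_time = NULL) {
  stopifnot(n_chimp >= 0, n_neandertal >= 0, n_african >= 0,
            n_european >= 0)
  if (n_chimp + n_neandertal + n_african + n_european < 2) {
    stop("at least two chromosomes must be sampled")
  }
  structure(list(n_chimp = as.integer(n_chimp),
                 n_neandertal = as.integer(n_neandertal),
                 n_african = as.integer(n_african),
                 n_european = as.integer(n_european),
                 demes = demes,
                 neandertal_time = neandertal_time),
            class = "sample_config")
}

default_horizon <- function(demog) {
  ot <- demog$outgroup_split_time
  if (is.finite(ot) && !is.na(ot)) 100 * ot else 1e9
}

# leaf-level layout: roles 0 = chimp, 1 = neandertal, 2 = african,
# 3 = european, in fixed sample order
sample_layout <- function(demog, sample) {
  demes <- demog$sample_demes
  if (!is.null(sample$demes)) demes <- modifyList(demes, sample$demes)
  counts <- c(sample$n_chimp, sample$n_neandertal, sample$n_african,
              sample$n_european)
  used <- c("chimp", "neandertal", "african", "european")[counts > 0]
  for (nm in used) {
    if (is.null(demes[[nm]]) || !demes[[nm]] %in% demog$demes$id) {
      stop("sampling deme ", demes[[nm]], " for the ", nm,
           " sample does not exist in the demography")
    }
  }
  nea_t <- sample$neandertal_time
  if (is.null(nea_t)) nea_t <- demog$params$neandertal_sampling_time
  if (is.null(nea_t)) nea_t <- 0
  role <- rep(0:3, counts)
  deme_of_role <- c(demes$chimp, demes$neandertal, demes$african,
                    demes$european)
  idx <- setNames(seq_len(nrow(demog$demes)), demog$demes$id)
  leaf_deme <- idx[deme_of_role[role + 1L]] - 1L
  leaf_time <- ifelse(role == 1L, nea_t, 0)
  pop <- c("chimp", "nea", "afr", "eur")[role + 1L]
  leaf_label <- paste0(pop, "_", unlist(lapply(counts, seq_len)))
  list(role = as.integer(role), deme = as.integer(leaf_deme),
       time = as.numeric(leaf_time), label = leaf_label)
}

new_genealogy <- function(parent, time, layout) {
  structure(list(parent = parent, time = time,
                 n_leaves = length(layout$role),
                 leaf_role = layout$role,
                 leaf_label = layout$label),
            class = "genealogy")
}

#' @method print genealogy
#' @export
print.genealogy <- function(x, ...) {
  cat("<genealogy>", x$n_leaves, "leaves, TMRCA",
      format(max(x$time), digits = 6), "generations\n")
  invisible(x)
}

#' Simulate one genealogy under a demographic model
#'
#' Runs the exact continuous-time structured coalescent: within a deme of
#' diploid size N, each pair of lineages coalesces at rate 1/(2N) per
#' generation; lineages migrate along the current migration edges at their
#' per-lineage rates; demographic events (deme mergers, colonization
#' reversals, admixture pulses, size and rate changes) are applied at their
#' times.  The ancient Neandertal chromosome joins the process at its
#' sampling time (serial coalescent).  A given `(seed, demog, sample)`
#' triple always returns the identical tree.
#'
#' @param demog a `demography` object (see [build_spatial_model()] and
#'   friends).
#' @param sample a [sample_config()].
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param max_time horizon (generations) after which a failure to coalesce
#'   is reported as an error; defaults to 100 times the outgroup split.
#' @return a `genealogy` object: 1-based parent pointers (`0` marks the
#'   root), node times in generations, and leaf labels in sample order
#'   (chimp, Neandertal, Africans, Europeans).
#' @export
simulate_genealogy <- function(demog, sample = sample_config(), seed = NULL,
                               max_time = NULL) {
  stopifnot(inherits(demog, "demography"))
  issues <- validate_demography(demog)
  issues <- issues[!startsWith(issues, "warning:")]
  if (length(issues)) {
    stop("invalid demography:\n  ", paste(issues, collapse = "\n  "))
  }
  if (!is.null(seed)) set.seed(seed)
  comp <- compile_demography(demog)
  layout <- sample_layout(demog, sample)
  if (is.null(max_time)) max_time <- default_horizon(demog)
  res <- sim_genealogy_cpp(comp$sizes, comp$migs, comp$breaks, comp$actions,
                           layout$deme, layout$time, max_time)
  new_genealogy(res$parent, res$time, layout)
}

#' Simulate a collection of unlinked genealogies
#'
#' Each locus receives its own seed drawn once from the master seed, so the
#' collection is reproducible and each locus is independent of execution
#' order (the per-locus seeds can be replayed individually).
#'
#' @inheritParams simulate_genealogy
#' @param n_loci number of independent (unlinked) loci.
#' @return an object of class `genealogy_list`: a list of `genealogy`
#'   objects with the sample layout attached as attributes.
#' @export
simulate_replicates <- function(demog, sample = sample_config(), n_loci,
                                seed = NULL, max_time = NULL) {
  stopifnot(n_loci >= 1)
  issues <- validate_demography(demog)
  issues <- issues[!startsWith(issues, "warning:")]
  if (length(issues)) {
    stop("invalid demography:\n  ", paste(issues, collapse = "\n  "))
  }
  if (!is.null(seed)) set.seed(seed)
  locus_seeds <- sample.int(.Machine$integer.max - 1L, n_loci)
  comp <- compile_demography(demog)
  layout <- sample_layout(demog, sample)
  if (is.null(max_time)) max_time <- default_horizon(demog)
  trees <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    set.seed(locus_seeds[i])
    res <- tryCatch(
      sim_genealogy_cpp(comp$sizes, comp$migs, comp$breaks, comp$actions,
                        layout$deme, layout$time, max_time),
      error = function(e) stop("locus ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    trees[[i]] <- list(parent = res$parent, time = res$time)
  }
  structure(trees, class = "genealogy_list", layout = layout,
            locus_seeds = locus_seeds)
}

#' @method print genealogy_list
#' @export
print.genealogy_list <- function(x, ...) {
  cat("<genealogy_list>", length(x), "unlinked loci,",
      length(attr(x, "layout")$role), "leaves each\n")
  invisible(x)
}

# accept either a genealogy_list or a plain list of genealogy objects
trees_and_layout <- function(trees, sample = NULL, demog = NULL) {
  if (inherits(trees, "genealogy_list")) {
    return(list(trees = unclass(trees), layout = attr(trees, "layout")))
  }
  if (inherits(trees, "genealogy")) trees <- list(trees)
  stopifnot(length(trees) > 0)
  first <- trees[[1]]
  if (!is.null(first$leaf_role)) {
    layout <- list(role = first$leaf_role, label = first$leaf_label)
    return(list(trees = trees, layout = layout))
  }
  stop("cannot recover the sample layout; pass a genealogy_list from ",
       "simulate_replicates() or genealogy objects")
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Places Poisson(`mu` x branch length) mutations on every branch; each
#' mutation defines one biallelic site whose derived allele is carried by
#' the branch's descendant leaves.  The chimpanzee lineage anchors the
#' ancestral state, so a site's 0/1 coding is relative to the chimp-rooted
#' state.  There is no back-mutation.
#'
#' @param tree a `genealogy` object.
#' @param mu per-locus mutation rate per generation.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return a [genotype_table()] with one row per segregating site (possibly
#'   zero rows), columns in sample order.
#' @export
drop_mutations <- function(tree, mu, seed = NULL) {
  stopifnot(inherits(tree, "genealogy"), mu > 0)
  if (!is.null(seed)) set.seed(seed)
  m <- drop_mutations_cpp(tree$parent, tree$time, tree$n_leaves, mu)
  colnames(m) <- tree$leaf_label
  genotype_table_from_matrix(m, tree$leaf_role)
}

# mutation-drop a whole collection; locus column records the tree index
mutate_replicates <- function(trees, mu, seed = NULL) {
  tl <- trees_and_layout(trees)
  if (!is.null(seed)) set.seed(seed)
  mats <- vector("list", length(tl$trees))
  for (i in seq_along(tl$trees)) {
    tr <- tl$trees[[i]]
    mats[[i]] <- drop_mutations_cpp(tr$parent, tr$time,
                                    length(tl$layout$role), mu)
  }
  n_sites <- vapply(mats, nrow, 0L)
  m <- do.call(rbind, mats)
  colnames(m) <- tl$layout$label
  gt <- genotype_table_from_matrix(m, tl$layout$role)
  attr(gt, "locus") <- rep(seq_along(mats), n_sites)
  gt
}

#' Total branch length of a genealogy
#'
#' @param tree a `genealogy` object.
#' @return total branch length in generations.
#' @export
total_branch_length <- function(tree) {
  stopifnot(inherits(tree, "genealogy"))
  total_branch_length_cpp(tree$parent, tree$time)
}

#' Time to the most recent common ancestor
#'
#' @param tree a `genealogy` object.
#' @return root node time in generations.
#' @export
tmrca <- function(tree) {
  stopifnot(inherits(tree, "genealogy"))
  max(tree$time)
}

## ---------------------------------------------------------------------------
## Exports to standard formats
## ---------------------------------------------------------------------------

#' Newick representation of a genealogy
#'
#' Branch lengths are in generations; leaves are named `<pop>_<idx>` with
#' pop one of `chimp`, `nea`, `afr`, `eur`.
#'
#' @param tree a `genealogy` object.
#' @return a single newick string.
#' @export
as_newick <- function(tree) {
  stopifnot(inherits(tree, "genealogy"))
  n_nodes <- length(tree$parent)
  children <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    p <- tree$parent[i]
    if (p > 0) children[[p]] <- c(children[[p]], i)
  }
  root <- which(tree$parent == 0)
  build <- function(node) {
    kids <- children[[node]]
    if (is.null(kids)) return(tree$leaf_label[node])
    inner <- vapply(kids, function(k) {
      paste0(build(k), ":",
             format(tree$time[node] - tree$time[k], scientific = FALSE))
    }, "")
    paste0("(", paste(inner, collapse = ","), ")")
  }
  paste0(build(root), ";")
}

#' Convert a genealogy to an ape phylo object
#'
#' @param tree a `genealogy` object.
#' @return an object of class `phylo`.
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = as_newick(tree))
}

#' Write a collection of genealogies as newick
#'
#' One tree per line, preceded by '#'-prefixed provenance lines.
#'
#' @param trees a `genealogy_list` or list of `genealogy` objects.
#' @param path output file.
#' @param provenance optional named list recorded in the header.
#' @export
write_newick <- function(trees, path, provenance = list()) {
  tl <- trees_and_layout(trees)
  lines <- provenance_header("newick genealogies", provenance)
  nwk <- vapply(seq_along(tl$trees), function(i) {
    tr <- tl$trees[[i]]
    g <- structure(list(parent = tr$parent, time = tr$time,
                        n_leaves = length(tl$layout$role),
                        leaf_role = tl$layout$role,
                        leaf_label = tl$layout$label),
                   class = "genealogy")
    as_newick(g)
  }, "")
  writeLines(c(lines, nwk), path)
}
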