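## dcfs and Patterson's D, from genotype tables (site path) and from
## genealogical branch lengths (expectation path), plus the R-squared fit.

#' Genotype table of a four-population panel
#'
#' Per-site alleles for one chimpanzee chromosome, one Neandertal
#' chromosome, one or more African chromosomes, and a European panel.
#' Alleles may be coded as bases ("A", "G", ...) or 0/1; only equality is
#' ever used.  `NA` marks a missing call.
#'
#' @param chimp,neandertal vectors of alleles, one per site (or single-column
#'   matrices).
#' @param african,european vectors or site-by-chromosome matrices.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(chimp, neandertal, african, european) {
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 1)
  chimp <- as_mat(chimp); neandertal <- as_mat(neandertal)
  african <- as_mat(african); european <- as_mat(european)
  n <- nrow(chimp)
  stopifnot(nrow(neandertal) == n, nrow(african) == n, nrow(european) == n)
  if (ncol(european) < 2) {
    stop("the European panel needs at least 2 chromosomes")
  }
  m <- cbind(chimp, neandertal, african, european)
  role <- rep(0:3, c(ncol(chimp), ncol(neandertal), ncol(african),
                     ncol(european)))
  colnames(m) <- paste0(c("chimp", "nea", "afr", "eur")[role + 1L], "_",
                        unlist(lapply(c(ncol(chimp), ncol(neandertal),
                                        ncol(african), ncol(european)),
                                      seq_len)))
  genotype_table_from_matrix(m, role)
}

genotype_table_from_matrix <- function(m, role) {
  structure(list(alleles = m, role = as.integer(role)),
            class = "genotype_table")
}

#' @method print genotype_table
#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table>", nrow(x$alleles), "sites,",
      sum(x$role == 3), "European chromosomes\n")
  invisible(x)
}

#' @method dim genotype_table
#' @export
dim.genotype_table <- function(x) dim(x$alleles)

role_cols <- function(table, role) which(table$role == role)

new_dcfs <- function(proportions, weight, undefined = FALSE, skipped = 0L) {
  structure(list(proportions = proportions,
                 n_classes = length(proportions),
                 weight = weight,
                 undefined = undefined,
                 skipped = skipped),
            class = "dcfs")
}

#' Construct a dcfs object from class proportions
#'
#' @param proportions non-negative vector over derived-count classes
#'   `1..nE`; normalized to sum to one.
#' @param weight number of doubly conditioned sites (or total branch
#'   weight) behind the proportions.
#' @return an object of class `dcfs`.
#' @export
dcfs <- function(proportions, weight = NA_real_) {
  stopifnot(is.numeric(proportions), all(proportions >= 0))
  s <- sum(proportions)
  if (s <= 0) return(new_dcfs(proportions, weight = 0, undefined = TRUE))
  new_dcfs(proportions / s, weight = if (is.na(weight)) s else weight)
}

#' @method print dcfs
#' @export
print.dcfs <- function(x, ...) {
  if (x$undefined) {
    cat("<dcfs> undefined (no doubly conditioned sites retained)\n")
  } else {
    cat("<dcfs>", x$n_classes, "classes, weight",
        format(x$weight, digits = 6), "\n")
    print(round(setNames(x$proportions, seq_len(x$n_classes)), 4))
  }
  invisible(x)
}

#' Site-based doubly conditioned frequency spectrum
#'
#' A site enters the spectrum iff (i) chimp and Neandertal carry different
#' alleles, (ii) the conditioning African chromosome(s) carry the chimp
#' allele, and (iii) the count i of European chromosomes carrying the
#' Neandertal allele satisfies 1 <= i <= nE.  Class i is incremented and
#' the class counts are normalized over retained sites.  Sites with more
#' than two alleles or missing calls are skipped and counted.
#'
#' @param table a [genotype_table()].
#' @param nE number of European chromosomes (defaults to the panel width).
#' @param condition_all_africans if `TRUE`, every African chromosome must
#'   carry the chimp allele; by default only the first African chromosome
#'   conditions, matching a single conditioning African genome.
#' @return a `dcfs` object; `$undefined` is `TRUE` when no site is
#'   retained, `$skipped` counts multiallelic/missing sites.
#' @export
site_dcfs <- function(table, nE = NULL, condition_all_africans = FALSE) {
  stopifnot(inherits(table, "genotype_table"))
  m <- table$alleles
  chimp <- m[, role_cols(table, 0L)[1]]
  nea <- m[, role_cols(table, 1L)[1]]
  afr_cols <- role_cols(table, 2L)
  if (!condition_all_africans) afr_cols <- afr_cols[1]
  eur_cols <- role_cols(table, 3L)
  if (is.null(nE)) nE <- length(eur_cols)
  stopifnot(nE == length(eur_cols))

  n_sites <- nrow(m)
  counts <- numeric(nE)
  skipped <- 0L
  if (n_sites > 0) {
    any_na <- rowSums(is.na(m)) > 0
    n_alleles <- apply(m, 1, function(r) length(unique(r[!is.na(r)])))
    bad <- any_na | n_alleles > 2
    skipped <- sum(bad)
    keep <- which(!bad)
    for (s in keep) {
      if (chimp[s] == nea[s]) next
      if (any(m[s, afr_cols] != chimp[s])) next
      i <- sum(m[s, eur_cols] == nea[s])
      if (i >= 1 && i <= nE) counts[i] <- counts[i] + 1
    }
  }
  tot <- sum(counts)
  if (tot == 0) return(new_dcfs(numeric(nE), 0, TRUE, skipped))
  new_dcfs(counts / tot, tot, FALSE, skipped)
}

#' Branch-length doubly conditioned frequency spectrum
#'
#' Accumulates, over a collection of genealogies, the total length of
#' branches whose descendant leaves are exactly the Neandertal leaf plus i
#' European leaves (no African, no chimpanzee), for i = 1..nE.  Under
#' infinite sites these lengths are proportional to the expected number of
#' doubly conditioned sites in each class, so the normalized vector is the
#' expected dcfs, free of the mutation rate.
#'
#' @param trees a `genealogy_list` from [simulate_replicates()], a single
#'   `genealogy`, or a list of them.
#' @return a `dcfs` object whose `$weight` is the total qualifying branch
#'   length in generations.
#' @export
branch_dcfs <- function(trees) {
  tl <- trees_and_layout(trees)
  if (sum(tl$layout$role == 3L) < 2) {
    stop("the dcfs needs a European panel of at least two chromosomes")
  }
  w <- branch_dcfs_weights_cpp(tl$trees, tl$layout$role)
  tot <- sum(w)
  if (tot == 0) return(new_dcfs(numeric(length(w)), 0, TRUE))
  new_dcfs(w / tot, tot)
}

new_dstat <- function(n_abba, n_baba, n_informative = NA_real_) {
  denom <- n_abba + n_baba
  structure(list(n_abba = n_abba, n_baba = n_baba,
                 d = if (denom > 0) (n_abba - n_baba) / denom else NA_real_,
                 n_informative = n_informative,
                 undefined = denom <= 0),
            class = "dstat")
}

#' @method print dstat
#' @export
print.dstat <- function(x, ...) {
  if (x$undefined) {
    cat("<dstat> undefined (no informative sites)\n")
  } else {
    cat("<dstat> D =", format(x$d, digits = 4),
        " (ABBA", format(x$n_abba, digits = 6),
        ", BABA", format(x$n_baba, digits = 6), ")\n")
  }
  invisible(x)
}

#' Site-based Patterson's D
#'
#' Over biallelic sites where the Neandertal differs from the chimp and
#' exactly one of the African / European chromosomes matches the
#' Neandertal, D is the fraction of sites where the European matches the
#' Neandertal minus the fraction where the African does:
#' `D = (n_ABBA - n_BABA) / (n_ABBA + n_BABA)`.  Positive D means the
#' European genome matches the Neandertal more often.
#'
#' @param table a [genotype_table()].
#' @param african,european index of the African / European chromosome used
#'   for the four-taxon panel (larger panels are reduced to one chromosome
#'   each).
#' @return a `dstat` object with counts, `d`, and an `undefined` flag when
#'   no informative site exists.
#' @export
patterson_d_sites <- function(table, african = 1, european = 1) {
  stopifnot(inherits(table, "genotype_table"))
  m <- table$alleles
  chimp <- m[, role_cols(table, 0L)[1]]
  nea <- m[, role_cols(table, 1L)[1]]
  afr <- m[, role_cols(table, 2L)[african]]
  eur <- m[, role_cols(table, 3L)[european]]
  sub <- cbind(chimp, nea, afr, eur)
  ok <- rowSums(is.na(sub)) == 0
  if (any(ok)) {
    n_alleles <- apply(sub[ok, , drop = FALSE], 1,
                       function(r) length(unique(r)))
    ok[ok] <- n_alleles <= 2
  }
  informative <- ok & nea != chimp & ((eur == nea) != (afr == nea))
  informative[is.na(informative)] <- FALSE
  n_abba <- sum(informative & eur == nea, na.rm = TRUE)
  n_baba <- sum(informative & afr == nea, na.rm = TRUE)
  new_dstat(n_abba, n_baba, sum(informative))
}

#' Branch-length Patterson's D
#'
#' The expectation form of the statistic: `n_abba` is the total length of
#' branches ancestral to exactly the Neandertal and the chosen European
#' chromosome (chimp excluded), `n_baba` the length ancestral to exactly
#' the Neandertal and the chosen African chromosome.  Leaves outside the
#' four-taxon panel are marginalized out.
#'
#' @inheritParams branch_dcfs
#' @param african,european which African / European chromosome forms the
#'   panel (ignored when `panel = TRUE`).
#' @param panel if `TRUE`, use the frequency-weighted form over the whole
#'   African and European panels (a branch with derived frequencies xA, xE
#'   contributes `len * xE * (1 - xA)` to ABBA and `len * xA * (1 - xE)`
#'   to BABA), the standard population-sample D; it has the same
#'   expectation as the single-chromosome form when panel members are
#'   exchangeable.
#' @return a `dstat` object whose counts are branch lengths (generations).
#' @export
branch_patterson_d <- function(trees, african = 1, european = 1,
                               panel = FALSE) {
  tl <- trees_and_layout(trees)
  if (panel) {
    w <- branch_abba_baba_freq_cpp(tl$trees, tl$layout$role)
    return(new_dstat(w[1], w[2]))
  }
  afr_leaf <- which(tl$layout$role == 2L)[african]
  eur_leaf <- which(tl$layout$role == 3L)[european]
  if (is.na(afr_leaf) || is.na(eur_leaf)) {
    stop("requested African/European chromosome not present in the sample")
  }
  w <- branch_abba_baba_cpp(tl$trees, tl$layout$role,
                            eur_leaf - 1L, afr_leaf - 1L)
  new_dstat(w[1], w[2])
}

#' R-squared fit between a predicted and an observed dcfs
#'
#' The coefficient of determination over frequency classes,
#' `1 - SS_res / SS_tot` with `SS_res = sum((obs - pred)^2)` and
#' `SS_tot = sum((obs - mean(obs))^2)`, reported as a percentage.  A
#' squared-Pearson-correlation variant is available behind
#' `method = "pearson"`.
#'
#' @param predicted,observed `dcfs` objects (or bare proportion vectors)
#'   with equal numbers of classes.
#' @param method `"ss"` (default, coefficient of determination) or
#'   `"pearson"`.
#' @return the fit as a percentage (can be negative under `"ss"` for fits
#'   worse than the observed mean); `NA` with a warning when the observed
#'   vector is constant.
#' @export
r_squared <- function(predicted, observed, method = c("ss", "pearson")) {
  method <- match.arg(method)
  p <- if (inherits(predicted, "dcfs")) predicted$proportions else predicted
  o <- if (inherits(observed, "dcfs")) observed$proportions else observed
  if (length(p) != length(o)) {
    stop("predicted and observed spectra have different numbers of classes (",
         length(p), " vs ", length(o), ")")
  }
  if ((inherits(predicted, "dcfs") && predicted$undefined) ||
      (inherits(observed, "dcfs") && observed$undefined)) {
    warning("undefined dcfs; R-squared is NA")
    return(NA_real_)
  }
  ss_tot <- sum((o - mean(o))^2)
  if (ss_tot == 0) {
    warning("observed spectrum is constant across classes; R-squared is ",
            "undefined")
    return(NA_real_)
  }
  if (method == "pearson") {
    return(100 * stats::cor(p, o)^2)
  }
  100 * (1 - sum((o - p)^2) / ss_tot)
}
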