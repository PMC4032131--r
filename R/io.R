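## Readers and writers: '#'-headed TSV as the universal tabular dialect,
## JSON model configs and reports, optional read-only VCF support.

pkg_version <- function() {
  as.character(utils::packageVersion("dcfsim"))
}

provenance_header <- function(title, provenance = list()) {
  lines <- c(paste0("# dcfsim ", pkg_version(), " - ", title))
  for (nm in names(provenance)) {
    lines <- c(lines, paste0("# ", nm, ": ",
                             paste(format(provenance[[nm]]), collapse = " ")))
  }
  lines
}

write_headed_tsv <- function(df, path, title, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(title, provenance), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

read_headed_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a dcfs to TSV
#'
#' Columns `class`, `proportion`, `weight`, preceded by '#'-prefixed
#' provenance lines.
#'
#' @param x a `dcfs` object.
#' @param path output file.
#' @param provenance optional named list recorded in the header.
#' @export
write_dcfs <- function(x, path, provenance = list()) {
  stopifnot(inherits(x, "dcfs"))
  df <- data.frame(class = seq_len(x$n_classes),
                   proportion = x$proportions,
                   weight = x$proportions * x$weight)
  write_headed_tsv(df, path, "doubly conditioned frequency spectrum",
                   provenance)
}

#' Read a dcfs from TSV
#'
#' @param path a file written by [write_dcfs()] (or any TSV with `class`
#'   and `proportion` columns; '#' lines are ignored).
#' @return a `dcfs` object.
#' @export
read_dcfs <- function(path) {
  df <- read_headed_tsv(path)
  stopifnot(all(c("class", "proportion") %in% names(df)))
  df <- df[order(df$class), ]
  if (!identical(as.integer(df$class), seq_len(nrow(df)))) {
    stop("dcfs classes must be 1..nE without gaps")
  }
  w <- if ("weight" %in% names(df)) sum(df$weight) else NA_real_
  dcfs(df$proportion, weight = w)
}

#' Write a genotype table to TSV
#'
#' Columns `locus`, `site`, then one column per sampled chromosome
#' (0 = chimp/ancestral allele under simulated data).
#'
#' @param table a [genotype_table()].
#' @param path output file.
#' @param provenance optional named list recorded in the header.
#' @export
write_genotype_table <- function(table, path, provenance = list()) {
  stopifnot(inherits(table, "genotype_table"))
  locus <- attr(table, "locus")
  n <- nrow(table$alleles)
  if (is.null(locus)) locus <- rep(1L, n)
  df <- data.frame(locus = locus, site = seq_len(n),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(table$alleles,
                                stringsAsFactors = FALSE))
  write_headed_tsv(df, path, "genotype table", provenance)
}

#' Read a genotype table from TSV
#'
#' Chromosome roles are recovered from the column-name prefixes `chimp_`,
#' `nea_`, `afr_`, `eur_`.
#'
#' @param path a file written by [write_genotype_table()].
#' @return a `genotype_table` (with a `locus` attribute).
#' @export
read_genotype_table <- function(path) {
  df <- read_headed_tsv(path)
  chrom <- setdiff(names(df), c("locus", "site"))
  prefix <- sub("_.*$", "", chrom)
  role_map <- c(chimp = 0L, nea = 1L, afr = 2L, eur = 3L)
  if (any(!prefix %in% names(role_map))) {
    stop("unrecognized chromosome column prefix: ",
         chrom[!prefix %in% names(role_map)][1])
  }
  m <- as.matrix(df[chrom])
  gt <- genotype_table_from_matrix(m, role_map[prefix])
  attr(gt, "locus") <- df$locus
  gt
}

#' Read a genotype table from a VCF
#'
#' Maps one named sample each to the chimp, Neandertal and African roles
#' and a sample list to the European panel.  Only biallelic SNPs are used;
#' multiallelic or non-SNP records are skipped and counted in a message.
#' Unphased diploid genotypes contribute both allele calls as separate
#' chromosomes; haploid calls contribute one.
#'
#' @param path VCF file (may be bgzipped).
#' @param chimp,neandertal,african sample names for the three single roles.
#' @param europeans character vector of European sample names.
#' @return a `genotype_table` with 0/1 coding (0 = reference allele).
#' @export
read_vcf_genotypes <- function(path, chimp, neandertal, african, europeans) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  keep <- vcfR::is.biallelic(v)
  snp <- nchar(vcfR::getREF(v)) == 1 & nchar(vcfR::getALT(v)) == 1
  skipped <- sum(!(keep & snp))
  if (skipped > 0) {
    message(skipped, " multiallelic or non-SNP record(s) skipped")
  }
  v <- v[keep & snp, ]
  gt <- vcfR::extract.gt(v)
  samples <- c(chimp, neandertal, african, europeans)
  missing <- setdiff(samples, colnames(gt))
  if (length(missing)) {
    stop("sample(s) not in VCF: ", paste(missing, collapse = ", "))
  }
  haplos <- function(sample_name) {
    calls <- gt[, sample_name]
    parts <- strsplit(ifelse(is.na(calls), ".", calls), "[/|]")
    n_h <- max(lengths(parts))
    m <- matrix(NA_integer_, length(calls), n_h)
    for (i in seq_along(parts)) {
      p <- suppressWarnings(as.integer(parts[[i]]))
      m[i, seq_along(p)] <- p
    }
    m
  }
  eur <- do.call(cbind, lapply(europeans, haplos))
  genotype_table(chimp = haplos(chimp)[, 1],
                 neandertal = haplos(neandertal)[, 1],
                 african = haplos(african)[, 1],
                 european = eur)
}

#' Write a Patterson's D report as JSON
#'
#' @param d a `dstat` object.
#' @param path output file.
#' @param provenance optional named list merged into the record.
#' @export
write_dstat_json <- function(d, path, provenance = list()) {
  stopifnot(inherits(d, "dstat"))
  rec <- c(list(n_abba = d$n_abba, n_baba = d$n_baba, d = d$d,
                n_informative = d$n_informative,
                undefined = d$undefined),
           provenance)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a demography's event table to TSV
#'
#' Human-readable export for inspection and cross-validation against other
#' simulators: one row per event with its time in generations, kind, and a
#' payload description.
#'
#' @param demog a `demography` object.
#' @param path output file.
#' @export
write_event_table <- function(demog, path) {
  write_headed_tsv(event_table(demog), path, "demographic event table",
                   provenance = list(model = demog$model))
}

## ---------------------------------------------------------------------------
## Model configuration files
## ---------------------------------------------------------------------------

#' Read a model configuration file
#'
#' JSON with a `model` discriminator (`spatial`, `two_pop` or `admixture`),
#' a mandatory `units` field (`generations` or `years`) governing all time
#' parameters, and parameter fields passed to the matching constructor.
#' Time fields given in years are converted with the configured
#' `generation_time` (default 25).
#'
#' @param path JSON file.
#' @return a parameter object ready for [build_model()].
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$model)) stop("config lacks the 'model' discriminator")
  if (is.null(cfg$units) || !cfg$units %in% c("generations", "years")) {
    stop("config must state units: \"generations\" or \"years\"")
  }
  model <- cfg$model
  gen_time <- if (!is.null(cfg$generation_time)) cfg$generation_time else 25
  args <- cfg[setdiff(names(cfg), c("model", "units"))]
  time_fields <- c("t_modern", "t_exit", "t_structure", "t_ooa", "t_admix",
                   "t_neandertal_split", "dt_colonize")
  if (cfg$units == "years") {
    for (f in intersect(names(args), time_fields)) {
      args[[f]] <- args[[f]] / gen_time
    }
  }
  ctor <- switch(model,
                 spatial = spatial_params,
                 two_pop = two_pop_params,
                 admixture = admixture_params,
                 stop("unknown model kind: ", model))
  unknown <- setdiff(names(args), names(formals(ctor)))
  if (length(unknown)) {
    stop("unknown parameter(s) for model ", model, ": ",
         paste(unknown, collapse = ", "))
  }
  do.call(ctor, args)
}

#' Write sweep records to TSV
#'
#' The dcfs list column is expanded into `dcfs_1..dcfs_nE` proportion
#' columns.
#'
#' @param records a `fit_records` data frame.
#' @param path output file.
#' @param provenance optional named list recorded in the header.
#' @export
write_fit_records <- function(records, path, provenance = list()) {
  stopifnot(inherits(records, "fit_records"))
  flat <- as.data.frame(records[setdiff(names(records), "dcfs")])
  n_classes <- max(c(0, vapply(records$dcfs, function(d) {
    if (is.null(d)) 0L else d$n_classes
  }, 0L)))
  for (k in seq_len(n_classes)) {
    flat[[paste0("dcfs_", k)]] <- vapply(records$dcfs, function(d) {
      if (is.null(d) || d$undefined) NA_real_ else d$proportions[k]
    }, 0)
  }
  write_headed_tsv(flat, path, "parameter sweep records", provenance)
}
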