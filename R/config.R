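#' Pipeline run configuration
#'
#' Builds the configuration object holding every tunable threshold of the
#' prioritization cascade. Defaults reproduce the published protocol: PASS
#' sites supported by at least 10 reads, population allele frequency below
#' 0.5% (gnomAD-style), internal cohort carrier caps (fewer than 5
#' heterozygotes and fewer than 3 homozygotes), CADD above 20 (or
#' unassigned), CNV segment filters (log2 ratio > 0.35 or < -0.4, p < 1e-5,
#' weight > 20), 50-kb same-type CNV merging, a 2-of-4 caller consensus for
#' deletions/duplications under 500 kb, SV population frequency < 0.01,
#' insertion/MEI breakpoints under 20 bp from an exon, exclusion of loci
#' seen in more than 10% of families, and dosage-sensitivity prioritization
#' (pHaplo >= 0.55, pTriplo >= 0.68, pLI > 0.9).
#'
#' @param ... named overrides of any default field.
#' @return An object of class \code{ndd_config} (a named list).
#' @examples
#' cfg <- run_config(dp_min = 15)
#' cfg$gnomad_af_max
#' @export
run_config <- function(...) {
  cfg <- list(
    # short-variant cascade
    dp_min = 10,                 # proband depth, kept when DP >= dp_min
    multiallelic = "reject",     # or "decompose"
    half_call = "missing",       # half-called genotypes treated as missing
    gnomad_af_max = 0.005,       # strict <
    internal_het_max = 5,        # strict < (carrier count in internal cohort)
    internal_hom_max = 3,        # strict <
    cadd_min = 20,               # strict >, missing passes
    benign_labels = c("Benign", "Likely benign", "Benign/Likely benign"),
    # X-linked logic
    x_contig = "chrX",
    par_intervals = empty_df(list(contig = character(), start = integer(),
                                  end = integer())),
    # CNV segment filters
    cnv_log2_dup = 0.35,         # strict >
    cnv_log2_del = -0.4,         # strict <
    cnv_p_max = 1e-5,            # strict <
    cnv_weight_min = 20,         # strict >
    cnv_merge_gap = 50000,       # merge same-type segments with gap < this
    # SV consensus / family merge
    sv_max_size = 500000,        # DEL/DUP strictly smaller than this
    consensus_min_callers = 2,
    reciprocal_overlap = 0.5,
    family_merge_bp = 1000,      # breakpoint distance <= this merges
    sv_af_max = 0.01,            # strict <, missing treated as rare
    ins_exon_dist = 20,          # strict < distance from exon for INS/MEI
    max_family_frac = 0.10,      # drop loci in > 10% of families
    family_count_rule = NA_integer_, # optional absolute count alternative
    # dosage prioritization
    phaplo_min = 0.55,           # >=
    ptriplo_min = 0.68,          # >=
    pli_min = 0.9,               # strict >
    # delta scoring
    window_size = 8000,
    deletion_extension = "right",  # or "symmetric"
    clinvar_cap = 450,
    # kinship
    kinship_first_degree = c(0.177, 0.354),
    kinship_unrelated_max = 0.0442,
    seed = 1L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0L)
    ndd_stop(paste("unknown config field(s):", paste(unknown, collapse = ", ")),
             "config_error")
  cfg[names(override)] <- override
  structure(cfg, class = "ndd_config")
}

#' Write a run configuration to YAML
#'
#' @param config an \code{ndd_config} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$par_intervals <- if (nrow(config$par_intervals) == 0L) list() else
    as.list(config$par_intervals)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Round-trips the output of \code{\link{write_config}} unchanged.
#'
#' @param path YAML file written by \code{write_config}.
#' @return An \code{ndd_config} object.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  par <- x$par_intervals
  x$par_intervals <- NULL
  cfg <- do.call(run_config, x)
  if (length(par) > 0L) {
    cfg$par_intervals <- data.frame(contig = as.character(par$contig),
                                    start = as.integer(par$start),
                                    end = as.integer(par$end),
                                    stringsAsFactors = FALSE)
  }
  cfg
}

#' @export
print.ndd_config <- function(x, ...) {
  cat("<ndd_config> pipeline thresholds:\n")
  scalars <- Filter(function(v) is.atomic(v) && length(v) <= 2, unclass(x))
  for (nm in names(scalars))
    cat(sprintf("  %-22s %s\n", nm, paste(scalars[[nm]], collapse = ", ")))
  invisible(x)
}
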