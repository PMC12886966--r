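# End-to-end orchestration: from cohort inputs to the final report.

#' Run the full prioritization pipeline on a cohort
#'
#' Applies the short-variant cascade per family, builds the SV consensus,
#' family-level merge, filters and dosage tiers, detects cross-class
#' compound heterozygotes, categorizes variants, derives per-proband
#' diagnostic status, screens secondary findings, and computes the yield
#' table with group-comparison statistics (chi-squared homogeneity plus
#' all pairwise Fisher tests).
#'
#' @param cohort an \code{\link{generate_cohort}} result, or an
#'   equivalent list with pedigree, groups, family_variants, variants,
#'   annotations, sv_calls, reference and families entries built from
#'   files via the readers of this package.
#' @param config \code{\link{run_config}}; the X contig and PAR intervals
#'   default to the cohort reference's.
#' @return list(filtered_shorts, prioritized, consensus, family_svs,
#'   filtered_svs, compound_het, statuses, secondary, yield, tests).
#' @export
run_pipeline <- function(cohort, config = NULL) {
  if (is.null(config))
    config <- run_config(x_contig = cohort$reference$x_contig,
                         par_intervals = cohort$reference$par_intervals)
  genes <- cohort$reference$genes
  filtered <- list()
  for (f in names(cohort$family_variants)) {
    vs <- attach_annotations(cohort$family_variants[[f]],
                             cohort$annotations)
    filtered[[f]] <- run_short_cascade(vs, cohort$pedigree,
                                       cohort$variants, genes, config)
  }
  counts <- rbind_df(lapply(filtered, attr, "cascade_counts"))
  filtered_shorts <- rbind_df(filtered) %||% filtered[[1]]
  attr(filtered_shorts, "cascade_counts") <- counts
  prioritized <- prioritize_variants(filtered_shorts, genes)

  consensus <- consensus_sv(cohort$sv_calls, config)
  family_svs <- merge_family_svs(consensus, cohort$pedigree, config)
  filtered_svs <- filter_family_svs(family_svs, genes,
                                    nrow(cohort$families), config)
  filtered_svs <- prioritize_dosage(filtered_svs, genes, config)

  compound_het <- detect_cross_class_compound_het(filtered_shorts,
                                                  filtered_svs,
                                                  cohort$pedigree)
  probands <- cohort$pedigree$sample_id[cohort$pedigree$role == "proband"]
  statuses <- cohort_status(prioritized, probands)
  statuses$group <- cohort$groups$group[match(statuses$proband_id,
                                              cohort$groups$proband_id)]
  secondary <- screen_secondary_findings(cohort$variants, genes)

  ytab <- yield_table(statuses)
  tests <- chisq_homogeneity(ytab)
  tests$comparison <- "ASD vs ID vs ASD-ID"
  tab <- as.data.frame(ytab)
  groups <- tab$group[tab$group != "Total"]
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (i >= j) next
    m <- as.matrix(tab[tab$group %in% groups[c(i, j)],
                       c("n_positive", "n_negative")])
    ft <- fisher_exact_2x2(m)
    ft$df <- NA_real_
    ft$comparison <- paste(groups[i], "vs", groups[j])
    tests <- rbind(tests[, c("statistic", "df", "p_value", "method",
                             "comparison")],
                   ft[, c("statistic", "df", "p_value", "method",
                          "comparison")])
  }
  list(filtered_shorts = filtered_shorts, prioritized = prioritized,
       consensus = consensus, family_svs = family_svs,
       filtered_svs = filtered_svs, compound_het = compound_het,
       statuses = statuses, secondary = secondary, yield = ytab,
       tests = tests, config = config)
}
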