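# Diagnostic-yield tables and group-comparison statistics.

#' Diagnostic-yield table by clinical group
#'
#' @param statuses data.frame(proband_id, status, group) with status in
#'   \{positive, negative\} and group one of ASD, ID, ASD-ID.
#' @return An object of class \code{yield_table}: data.frame(group,
#'   n_positive, n_negative, n_total, yield_pct, yield_pct_display) plus
#'   an overall row; yield_pct is exact, yield_pct_display rounded to one
#'   decimal.
#' @examples
#' st <- data.frame(proband_id = as.character(1:4),
#'                  status = c("positive", "negative", "positive",
#'                             "negative"),
#'                  group = c("ASD", "ASD", "ID", "ID"))
#' yield_table(st)
#' @export
yield_table <- function(statuses) {
  groups <- c("ASD", "ID", "ASD-ID")
  bad <- setdiff(unique(statuses$group), groups)
  if (length(bad) > 0L)
    ndd_stop(paste("unknown group label(s):", paste(bad, collapse = ", ")),
             "stats_error")
  if (!all(statuses$status %in% c("positive", "negative")))
    ndd_stop("status must be positive or negative", "stats_error")
  rows <- lapply(intersect(groups, unique(statuses$group)), function(g) {
    sub <- statuses[statuses$group == g, ]
    data.frame(group = g, n_positive = sum(sub$status == "positive"),
               n_negative = sum(sub$status == "negative"),
               stringsAsFactors = FALSE)
  })
  tab <- rbind_df(rows) %||%
    empty_df(list(group = character(), n_positive = integer(),
                  n_negative = integer()))
  overall <- data.frame(group = "Total",
                        n_positive = sum(tab$n_positive),
                        n_negative = sum(tab$n_negative),
                        stringsAsFactors = FALSE)
  tab <- rbind(tab, overall)
  tab$n_total <- tab$n_positive + tab$n_negative
  tab$yield_pct <- 100 * tab$n_positive / tab$n_total
  tab$yield_pct_display <- round(tab$yield_pct, 1)
  structure(tab, class = c("yield_table", "data.frame"))
}

#' Build a yield table directly from per-group counts
#' @param counts matrix or data.frame with columns n_positive, n_negative
#'   and rownames (or a group column) naming the groups.
#' @return A \code{\link{yield_table}}.
#' @export
yield_table_from_counts <- function(counts) {
  counts <- as.data.frame(counts)
  if (!("group" %in% names(counts))) counts$group <- rownames(counts)
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    rows[[i]] <- data.frame(
      proband_id = sprintf("%s_%03d", counts$group[i],
                           seq_len(counts$n_positive[i] +
                                     counts$n_negative[i])),
      status = rep(c("positive", "negative"),
                   c(counts$n_positive[i], counts$n_negative[i])),
      group = counts$group[i], stringsAsFactors = FALSE)
  }
  yield_table(rbind_df(rows))
}

#' Chi-squared homogeneity test on a yield table
#'
#' Pearson chi-squared without continuity correction on the R x 2
#' positive/negative table (per-group rows, the Total row excluded);
#' df = R - 1.
#'
#' @param ytab a \code{\link{yield_table}}.
#' @return data.frame(statistic, df, p_value, method).
#' @export
chisq_homogeneity <- function(ytab) {
  tab <- as.data.frame(ytab)
  tab <- tab[tab$group != "Total", , drop = FALSE]
  m <- as.matrix(tab[, c("n_positive", "n_negative")])
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    ndd_stop("zero marginal in yield table", "stats_error")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  data.frame(statistic = unname(ct$statistic), df = unname(ct$parameter),
             p_value = unname(ct$p.value),
             method = "Pearson chi-squared (no continuity correction)",
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact enumeration: with margins fixed, the two-sided p-value sums the
#' hypergeometric probabilities of all tables whose probability does not
#' exceed that of the observed table (the minimum-likelihood convention
#' of mainstream statistical software).
#'
#' @param table 2x2 matrix of nonnegative integers.
#' @return data.frame(statistic = odds-ratio estimate (sample), p_value,
#'   method).
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)))
    ndd_stop("fisher_exact_2x2 needs a 2x2 table", "stats_error")
  if (any(m < 0) || any(m != round(m)))
    ndd_stop("table cells must be nonnegative integers", "stats_error")
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  # tolerance against floating-point ties, as in standard implementations
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  odds <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  data.frame(statistic = odds, p_value = min(1, p),
             method = "Fisher exact (two-sided, minimum likelihood)",
             stringsAsFactors = FALSE)
}

#' Render the cohort report
#'
#' Writes the yield table, the group-comparison tests, the prioritized
#' variants and secondary findings as TSVs plus a short text summary.
#' Output ordering is deterministic (group, proband, gene); all counts in
#' the summary are recomputed from the tables written. Interval columns
#' in the variant tables are 1-based inclusive.
#'
#' @param ytab a \code{\link{yield_table}}.
#' @param tests data.frame of test results (rbind of
#'   \code{\link{chisq_homogeneity}} / \code{\link{fisher_exact_2x2}}
#'   rows with a \code{comparison} column).
#' @param prioritized prioritized-variant data.frame.
#' @param secondary secondary-findings data.frame.
#' @param dir output directory.
#' @return Named list of written paths.
#' @export
render_report <- function(ytab, tests, prioritized, secondary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(yield = file.path(dir, "yield_table.tsv"),
                tests = file.path(dir, "group_tests.tsv"),
                variants = file.path(dir, "prioritized_variants.tsv"),
                secondary = file.path(dir, "secondary_findings.tsv"),
                summary = file.path(dir, "summary.txt"))
  write_tsv(as.data.frame(ytab), paths$yield)
  write_tsv(tests, paths$tests)
  pv <- prioritized[order(prioritized$proband_id, prioritized$gene,
                          prioritized$variant_id), , drop = FALSE]
  write_tsv(pv, paths$variants)
  sf <- secondary[order(secondary$sample_id, secondary$gene), , drop = FALSE]
  write_tsv(sf, paths$secondary)
  total <- as.data.frame(ytab)[as.data.frame(ytab)$group == "Total", ]
  lines <- c(
    sprintf("Probands analysed: %d", total$n_total),
    sprintf("Positive probands (candidate P/LP/hot-warm VUS): %d",
            total$n_positive),
    sprintf("Overall diagnostic yield: %.1f%%", total$yield_pct),
    sprintf("Prioritized variants reported: %d", nrow(pv)),
    sprintf("  candidate: %d", sum(pv$category == "candidate")),
    sprintf("  suggestive: %d", sum(pv$category == "suggestive")),
    sprintf("Secondary findings: %d", nrow(sf)))
  writeLines(lines, paths$summary)
  paths
}
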