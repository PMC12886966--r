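# Proband-level integration of short-variant and SV findings:
# cross-class compound heterozygotes, candidate/suggestive
# categorization, diagnostic status, ACMG secondary findings, and
# de novo database matching.

YIELD_CLASSES <- c("P", "LP", "VUS_hot", "VUS_warm")

#' Detect cross-class compound heterozygotes
#'
#' Finds probands who carry at least one filtered SV and one filtered
#' short variant in the same gene, inherited from different parents —
#' the two-variant recessive configuration only whole-genome analysis
#' can expose when one allele is structural.
#'
#' @param filtered_shorts output of \code{\link{run_short_cascade}}
#'   (cohort-wide).
#' @param filtered_svs output of \code{\link{filter_family_svs}} (the
#'   \code{genes} column is used for gene assignment).
#' @param pedigree pedigree data.frame (used to require both parents).
#' @return data.frame(proband_id, gene, sv_key, short_variant_id,
#'   sv_origin, short_origin).
#' @export
detect_cross_class_compound_het <- function(filtered_shorts, filtered_svs,
                                            pedigree) {
  proto <- list(proband_id = character(), gene = character(),
                sv_key = character(), short_variant_id = character(),
                sv_origin = character(), short_origin = character())
  if (nrow(filtered_shorts) == 0L || nrow(filtered_svs) == 0L)
    return(empty_df(proto))
  inherited <- c(inherited_maternal = "maternal",
                 inherited_paternal = "paternal")
  sh <- filtered_shorts[filtered_shorts$inheritance_raw %in%
                          names(inherited), , drop = FALSE]
  sv <- filtered_svs[filtered_svs$segregation %in% names(inherited), ,
                     drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(sv))) {
    x <- sv[i, ]
    sv_genes <- strsplit(x$genes, ",")[[1]]
    cand <- sh[sh$proband_id == x$proband_id & sh$gene %in% sv_genes, ,
               drop = FALSE]
    if (nrow(cand) == 0L) next
    opp <- cand[inherited[cand$inheritance_raw] !=
                  inherited[[x$segregation]], , drop = FALSE]
    for (j in seq_len(nrow(opp)))
      out[[length(out) + 1L]] <- data.frame(
        proband_id = x$proband_id, gene = opp$gene[j],
        sv_key = sprintf("%s:%d-%d:%s", x$contig, x$start, x$end, x$sv_type),
        short_variant_id = opp$variant_id[j],
        sv_origin = unname(inherited[[x$segregation]]),
        short_origin = unname(inherited[opp$inheritance_raw[j]]),
        stringsAsFactors = FALSE)
  }
  rbind_df(out) %||% empty_df(proto)
}

inheritance_compatible <- function(inheritance, mode) {
  if (is.na(mode) || mode == "unknown") return(inheritance != "unknown")
  switch(mode,
    AD = inheritance %in% c("de_novo", "putative_de_novo",
                            "inherited_maternal", "inherited_paternal"),
    AR = inheritance %in% c("homozygous_recessive", "composite_recessive"),
    XL = inheritance %in% c("x_linked", "de_novo"),
    FALSE)
}

#' Categorize a prioritized variant as candidate / suggestive / none
#'
#' Candidate: the gene is an established neurodevelopmental disease gene,
#' the ACMG class is not benign/likely benign, and the observed
#' inheritance is compatible with the gene's inheritance mode.
#' Suggestive: the gene is on the neurodevelopmental list but not yet
#' established, with a non-benign ACMG class. Anything else: none.
#'
#' @param gene_flags one row of the gene table (or a list with
#'   established_ndd_gene, ndd_list, inheritance_mode).
#' @param acmg_class one of P, LP, VUS_hot, VUS_warm, VUS, LB, B or NA.
#' @param inheritance inheritance label.
#' @return "candidate", "suggestive" or "none".
#' @export
categorize_variant <- function(gene_flags, acmg_class, inheritance) {
  if (is.na(acmg_class)) acmg_class <- "VUS"
  if (acmg_class %in% c("B", "LB")) return("none")
  if (isTRUE(gene_flags$established_ndd_gene) &&
      inheritance_compatible(inheritance, gene_flags$inheritance_mode))
    return("candidate")
  if (isTRUE(gene_flags$ndd_list) && !isTRUE(gene_flags$established_ndd_gene))
    return("suggestive")
  "none"
}

#' Build the prioritized-variant table for a cohort
#'
#' Applies \code{\link{categorize_variant}} to every filtered short
#' variant and sets the yield flag: a variant contributes to the
#' diagnostic yield iff it is a candidate classified P, LP or hot/warm
#' VUS.
#'
#' @param filtered_shorts output of \code{\link{run_short_cascade}}.
#' @param genes gene table.
#' @return The input with \code{category} and \code{contributes_to_yield}
#'   columns.
#' @export
prioritize_variants <- function(filtered_shorts, genes) {
  n <- nrow(filtered_shorts)
  category <- character(n)
  for (i in seq_len(n)) {
    gf <- genes[match(filtered_shorts$gene[i], genes$symbol), ]
    category[i] <- categorize_variant(
      as.list(gf), filtered_shorts$acmg_class[i],
      filtered_shorts$inheritance[i])
  }
  filtered_shorts$category <- category
  filtered_shorts$contributes_to_yield <- category == "candidate" &
    filtered_shorts$acmg_class %in% YIELD_CLASSES
  filtered_shorts
}

#' Diagnostic status of a proband
#'
#' Positive iff at least one prioritized variant contributes to the
#' yield (candidate and P/LP/hot-warm VUS); suggestive variants and plain
#' VUS candidates never drive the yield.
#'
#' @param prioritized prioritized-variant data.frame for one proband
#'   (\code{\link{prioritize_variants}} rows).
#' @return "positive" or "negative".
#' @export
proband_status <- function(prioritized) {
  if (nrow(prioritized) > 0L && any(prioritized$contributes_to_yield))
    "positive" else "negative"
}

#' Cohort-wide diagnostic status table
#'
#' @param prioritized prioritized-variant data.frame (whole cohort).
#' @param probands character vector of all proband ids (so probands with
#'   no surviving variant are counted negative).
#' @return data.frame(proband_id, status).
#' @export
cohort_status <- function(prioritized, probands) {
  status <- vapply(probands, function(p)
    proband_status(prioritized[prioritized$proband_id == p, , drop = FALSE]),
    "")
  data.frame(proband_id = probands, status = unname(status),
             stringsAsFactors = FALSE)
}

pathogenic_clinvar <- function(x)
  !is.na(x) & x %in% c("Pathogenic", "Likely pathogenic",
                       "Pathogenic/Likely pathogenic")

#' Screen for ACMG secondary findings
#'
#' Runs on the unfiltered cohort genotypes (parents included), restricted
#' to the ACMG secondary-findings gene panel: reports variants classified
#' pathogenic or likely pathogenic by ClinVar, InterVar, or both, carried
#' heterozygously in an autosomal-dominant gene or
#' homozygously/hemizygously in a recessive gene — one row per carrier.
#'
#' @param vs annotated cohort \code{variant_set}.
#' @param genes gene table with \code{acmg_sf_gene} flags and inheritance
#'   modes.
#' @return data.frame(sample_id, variant_id, gene, zygosity,
#'   trigger_source).
#' @export
screen_secondary_findings <- function(vs, genes) {
  proto <- list(sample_id = character(), variant_id = character(),
                gene = character(), zygosity = character(),
                trigger_source = character())
  sf_genes <- genes[genes$acmg_sf_gene, , drop = FALSE]
  v <- vs$variants
  cv <- pathogenic_clinvar(v$clinvar_class)
  iv <- pathogenic_clinvar(v$intervar_class)
  idx <- which(!is.na(v$gene) & v$gene %in% sf_genes$symbol & (cv | iv))
  out <- list()
  for (i in idx) {
    mode <- sf_genes$inheritance_mode[match(v$gene[i], sf_genes$symbol)]
    src <- if (cv[i] && iv[i]) "both" else if (cv[i]) "ClinVar" else "InterVar"
    for (s in vs$samples) {
      g <- vs$gt[i, s]; pl <- vs$ploidy[i, s]
      if (is.na(g) || g == 0L) next
      zyg <- if (pl == 1L && g == 1L) "hemizygous"
             else if (g == pl) "homozygous" else "heterozygous"
      hit <- switch(mode,
        AD = zyg == "heterozygous",
        AR = zyg %in% c("homozygous", "hemizygous"),
        XL = zyg %in% c("homozygous", "hemizygous"),
        FALSE)
      if (hit)
        out[[length(out) + 1L]] <- data.frame(
          sample_id = s, variant_id = v$variant_id[i], gene = v$gene[i],
          zygosity = zyg, trigger_source = src, stringsAsFactors = FALSE)
    }
  }
  rbind_df(out) %||% empty_df(proto)
}

#' Match variants against an external de novo database
#'
#' Three correspondence levels against a table of published de novo
#' variants: exact (same contig, position, ref and alt), exon (another de
#' novo variant in the same gene whose position falls in the same exon
#' interval), and gene (any de novo variant in the same gene). The
#' highest applicable level is reported per variant.
#'
#' @param variants data.frame with variant_id, contig, pos, ref, alt,
#'   gene.
#' @param denovo_table data.frame with gene, contig, pos, ref, alt rows.
#' @param genes gene table (for exon intervals).
#' @return The input with a \code{denovo_db_match} column in
#'   \{exact, exon, gene, none\}.
#' @export
match_denovo_db <- function(variants, denovo_table, genes) {
  n <- nrow(variants)
  level <- rep("none", n)
  db_key <- variant_key(denovo_table$contig, denovo_table$pos,
                        denovo_table$ref, denovo_table$alt)
  for (i in seq_len(n)) {
    g <- variants$gene[i]
    if (is.na(g)) next
    in_gene <- denovo_table[denovo_table$gene == g, , drop = FALSE]
    if (nrow(in_gene) == 0L) next
    key <- variant_key(variants$contig[i], variants$pos[i],
                       variants$ref[i], variants$alt[i])
    if (key %in% db_key) { level[i] <- "exact"; next }
    gi <- match(g, genes$symbol)
    if (!is.na(gi)) {
      es <- genes$exon_start[[gi]]; ee <- genes$exon_end[[gi]]
      my_exon <- which(variants$pos[i] > es & variants$pos[i] <= ee)
      if (length(my_exon) == 1L &&
          any(in_gene$pos > es[my_exon] & in_gene$pos <= ee[my_exon])) {
        level[i] <- "exon"; next
      }
    }
    level[i] <- "gene"
  }
  variants$denovo_db_match <- level
  variants
}
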