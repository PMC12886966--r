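# Seven-filter short-variant prioritization cascade and inheritance
# classification.
#
# Stages (all conjunctions, applied to every proband of every family):
#   1. site QC      - FILTER == PASS, single ALT, proband called at DP >= 10
#   2. frequency    - gnomAD AF < 0.005 (or missing) AND internal cohort
#                     het carriers < 5 AND hom carriers < 3
#   3. consequence  - exonic/splicing, not synonymous, not Benign/Likely
#                     benign by ClinVar or InterVar, CADD_phred > 20 or
#                     unassigned
#   4. gene list    - gene on the curated neurodevelopmental list
# followed by per-variant inheritance labelling and the gene-level
# composite-recessive relabel.

INHERITANCE_LEVELS <- c("inherited_maternal", "inherited_paternal",
                        "de_novo", "putative_de_novo",
                        "homozygous_recessive", "x_linked",
                        "composite_recessive", "unknown")

#' Site-level QC filter
#'
#' Keeps PASS, single-ALT records where the proband genotype is called
#' with depth at least \code{config$dp_min}. Single-ALT is structural in a
#' \code{variant_set} (multiallelics are excluded or decomposed at parse
#' time), so the predicate here is PASS + proband call quality.
#'
#' @param vs a \code{variant_set}.
#' @param proband_id proband sample id.
#' @param config \code{\link{run_config}}.
#' @return Logical vector over the sites of \code{vs}.
#' @export
site_qc_filter <- function(vs, proband_id, config = run_config()) {
  pass <- vs$variants$filter == "PASS"
  called <- !is.na(vs$gt[, proband_id])
  depth_ok <- vs$dp[, proband_id] >= config$dp_min
  unname(pass & called & depth_ok)
}

# Internal cohort carrier counts per site: heterozygous and homozygous-ALT
# (a hemizygous ALT call counts as homozygous).
internal_cohort_counts <- function(vs) {
  gt <- vs$gt
  pl <- vs$ploidy
  het <- rowSums(gt == 1L & pl == 2L, na.rm = TRUE)
  hom <- rowSums(gt == pl & gt > 0L, na.rm = TRUE)
  data.frame(het = het, hom = hom)
}

#' Population and internal-cohort frequency filter
#'
#' @param vs annotated \code{variant_set} for one family.
#' @param cohort_vs cohort-wide \code{variant_set} used for internal
#'   carrier counts (298-individual internal cohort in the published
#'   protocol).
#' @param config \code{\link{run_config}}.
#' @return Logical vector over the sites of \code{vs}.
#' @export
frequency_filter <- function(vs, cohort_vs, config = run_config()) {
  af <- vs$variants$gnomad_af
  af_ok <- is.na(af) | af < config$gnomad_af_max
  counts <- internal_cohort_counts(cohort_vs)
  idx <- match(vs$variants$variant_id, cohort_vs$variants$variant_id)
  het <- ifelse(is.na(idx), 0L, counts$het[idx])
  hom <- ifelse(is.na(idx), 0L, counts$hom[idx])
  unname(af_ok & het < config$internal_het_max & hom < config$internal_hom_max)
}

is_benign_label <- function(label, config) {
  !is.na(label) & label %in% config$benign_labels
}

#' Consequence/pathogenicity annotation filter
#'
#' Exonic or splicing, not synonymous, not Benign/Likely benign by
#' ClinVar or InterVar, and CADD_phred above 20 (missing CADD passes, as
#' unassigned scores did in the published cascade). Unrecognized
#' ClinVar/InterVar labels are treated as non-benign.
#'
#' @param vs annotated \code{variant_set}.
#' @param config \code{\link{run_config}}.
#' @return Logical vector over the sites of \code{vs}.
#' @export
consequence_filter <- function(vs, config = run_config()) {
  v <- vs$variants
  region_ok <- !is.na(v$func_region) & v$func_region %in% c("exonic", "splicing")
  not_syn <- is.na(v$exonic_consequence) | v$exonic_consequence != "synonymous"
  not_benign <- !is_benign_label(v$clinvar_class, config) &
    !is_benign_label(v$intervar_class, config)
  cadd_ok <- is.na(v$cadd_phred) | v$cadd_phred > config$cadd_min
  unname(region_ok & not_syn & not_benign & cadd_ok)
}

#' Curated gene-list filter
#'
#' Keeps records whose gene is on the neurodevelopmental gene list.
#' Records without a gene symbol cannot lie within a listed gene and are
#' dropped.
#'
#' @param vs annotated \code{variant_set}.
#' @param genes gene table (\code{\link{read_gene_table}}).
#' @return Logical vector over the sites of \code{vs}.
#' @export
gene_list_filter <- function(vs, genes) {
  listed <- genes$symbol[genes$ndd_list]
  g <- vs$variants$gene
  unname(!is.na(g) & g %in% listed)
}

in_par <- function(contig, pos, par_intervals) {
  if (is.null(par_intervals) || nrow(par_intervals) == 0L) return(FALSE)
  any(par_intervals$contig == contig & pos > par_intervals$start &
        pos <= par_intervals$end)
}

# Family context for one proband: sample ids + sequenced flags.
family_context <- function(pedigree, proband_id) {
  row <- pedigree[pedigree$sample_id == proband_id, ]
  if (nrow(row) != 1L) ndd_stop("unknown proband", "pedigree_error")
  seqd <- function(id) !is.na(id) && id %in%
    pedigree$sample_id[pedigree$sequenced]
  list(family_id = row$family_id, proband = proband_id, sex = row$sex,
       father = row$father_id, mother = row$mother_id,
       father_seq = seqd(row$father_id), mother_seq = seqd(row$mother_id))
}

#' Classify the inheritance pattern of one variant in one proband
#'
#' Implements the published pattern definitions: inherited (heterozygous
#' in a parent and the proband), de novo (present only in the proband,
#' with both parents confidently homozygous reference at depth), putative
#' de novo (one parental genome unavailable, the available parent
#' reference), recessive (homozygous proband, both parents heterozygous),
#' X-linked (hemizygous male proband, heterozygous mother, father not a
#' carrier), and unknown when no pattern applies unambiguously.
#' Pseudoautosomal positions follow the autosomal rules.
#'
#' @param vs \code{variant_set} containing the family's genotypes.
#' @param site_idx row index of the variant in \code{vs}.
#' @param ctx family context (internal) or a pedigree data.frame plus
#'   \code{proband_id}.
#' @param proband_id proband sample id (when \code{ctx} is a pedigree).
#' @param config \code{\link{run_config}} (PAR intervals, X contig, depth).
#' @return One label from the inheritance vocabulary.
#' @export
classify_inheritance <- function(vs, site_idx, ctx, proband_id = NULL,
                                 config = run_config()) {
  if (is.data.frame(ctx)) ctx <- family_context(ctx, proband_id)
  g <- function(s) if (!is.null(s) && !is.na(s) && s %in% vs$samples)
    vs$gt[site_idx, s] else NA_integer_
  d <- function(s) if (!is.null(s) && !is.na(s) && s %in% vs$samples)
    vs$dp[site_idx, s] else 0L
  p_gt <- g(ctx$proband)
  if (is.na(p_gt) || p_gt == 0L) return("unknown")
  p_ploidy <- vs$ploidy[site_idx, ctx$proband]
  contig <- vs$variants$contig[site_idx]
  pos <- vs$variants$pos[site_idx]
  on_x <- contig == config$x_contig &&
    !in_par(contig, pos, config$par_intervals)

  fa <- if (ctx$father_seq) g(ctx$father) else NA_integer_
  mo <- if (ctx$mother_seq) g(ctx$mother) else NA_integer_
  fa_dp_ok <- ctx$father_seq && !is.na(fa) && d(ctx$father) >= config$dp_min
  mo_dp_ok <- ctx$mother_seq && !is.na(mo) && d(ctx$mother) >= config$dp_min

  # hemizygous male proband on X
  if (on_x && ctx$sex == "M" && p_ploidy == 1L && p_gt == 1L) {
    father_clear <- !ctx$father_seq || (!is.na(fa) && fa == 0L)
    if (!is.na(mo) && mo == 1L && father_clear) return("x_linked")
  }

  fa_carrier <- !is.na(fa) & fa > 0L
  mo_carrier <- !is.na(mo) & mo > 0L

  if (p_gt == p_ploidy && p_ploidy == 2L) {
    # homozygous proband
    if (!is.na(fa) && fa == 1L && !is.na(mo) && mo == 1L)
      return("homozygous_recessive")
    return("unknown")
  }
  # heterozygous (or hemizygous non-X-pattern) proband
  if (mo_carrier && fa_carrier) return("unknown")  # ambiguous origin
  if (mo_carrier) return("inherited_maternal")
  if (fa_carrier) return("inherited_paternal")
  # neither parent carries the allele
  if (ctx$father_seq && ctx$mother_seq) {
    if (!is.na(fa) && fa == 0L && !is.na(mo) && mo == 0L &&
        fa_dp_ok && mo_dp_ok)
      return("de_novo")
    return("unknown")   # low-depth or missing parental call
  }
  if (xor(ctx$father_seq, ctx$mother_seq)) {
    avail <- if (ctx$father_seq) fa else mo
    if (!is.na(avail) && avail == 0L) return("putative_de_novo")
  }
  "unknown"
}

#' Detect composite (compound) recessive gene hits
#'
#' Flags genes in which a proband inherited at least one variant from
#' each parent among its filtered variants; all involved variants are
#' relabelled composite_recessive at gene level (the per-variant
#' inherited label is retained in \code{inheritance_raw}). Probands
#' without both parents sequenced are skipped, since parental origin is
#' unresolvable.
#'
#' @param filtered data.frame of filtered variants (from
#'   \code{\link{run_short_cascade}}) with proband_id, gene, inheritance.
#' @param pedigree pedigree data.frame.
#' @return data.frame(proband_id, gene, maternal_ids, paternal_ids).
#' @export
detect_composite_recessive <- function(filtered, pedigree) {
  out <- list()
  for (p in unique(filtered$proband_id)) {
    ctx <- family_context(pedigree, p)
    if (!ctx$father_seq || !ctx$mother_seq) next
    sub <- filtered[filtered$proband_id == p & !is.na(filtered$gene), ]
    for (g in unique(sub$gene)) {
      gv <- sub[sub$gene == g, ]
      mat <- gv$variant_id[gv$inheritance == "inherited_maternal"]
      pat <- gv$variant_id[gv$inheritance == "inherited_paternal"]
      if (length(mat) > 0L && length(pat) > 0L)
        out[[length(out) + 1L]] <- data.frame(
          proband_id = p, gene = g,
          maternal_ids = paste(mat, collapse = ","),
          paternal_ids = paste(pat, collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  rbind_df(out) %||%
    empty_df(list(proband_id = character(), gene = character(),
                  maternal_ids = character(), paternal_ids = character()))
}

#' Run the full short-variant cascade for a family
#'
#' Applies site QC, frequency, consequence and gene-list filters per
#' proband, labels inheritance for the survivors, and applies the
#' gene-level composite-recessive relabel. Per-stage drop counts are kept
#' in the \code{cascade_counts} attribute.
#'
#' @param vs annotated family \code{variant_set}.
#' @param pedigree pedigree data.frame (whole cohort or the family).
#' @param cohort_vs cohort \code{variant_set} for internal frequency
#'   counts; defaults to \code{vs}.
#' @param genes gene table.
#' @param config \code{\link{run_config}}.
#' @param probands proband ids to process; defaults to every sequenced
#'   proband of \code{vs}'s samples.
#' @return data.frame of filtered variants: proband_id, family_id,
#'   variant_id, contig, pos, ref, alt, gene, acmg_class, inheritance,
#'   inheritance_raw, carrier_parents.
#' @export
run_short_cascade <- function(vs, pedigree, cohort_vs = vs, genes,
                              config = run_config(), probands = NULL) {
  if (is.null(probands))
    probands <- intersect(
      pedigree$sample_id[pedigree$role == "proband" & pedigree$sequenced],
      vs$samples)
  rows <- list()
  counts <- list()
  freq_ok <- frequency_filter(vs, cohort_vs, config)
  cons_ok <- consequence_filter(vs, config)
  gene_ok <- gene_list_filter(vs, genes)
  for (p in probands) {
    ctx <- family_context(pedigree, p)
    qc_ok <- site_qc_filter(vs, p, config)
    carrier <- !is.na(vs$gt[, p]) & vs$gt[, p] > 0L
    keep <- carrier & qc_ok & freq_ok & cons_ok & gene_ok
    counts[[p]] <- data.frame(
      proband_id = p,
      n_input = sum(carrier, na.rm = TRUE),
      n_after_qc = sum(carrier & qc_ok),
      n_after_freq = sum(carrier & qc_ok & freq_ok),
      n_after_consequence = sum(carrier & qc_ok & freq_ok & cons_ok),
      n_after_gene_list = sum(keep), stringsAsFactors = FALSE)
    for (i in which(keep)) {
      lab <- classify_inheritance(vs, i, ctx, config = config)
      parents <- character()
      if (lab %in% c("inherited_maternal", "x_linked")) parents <- "mother"
      if (lab == "inherited_paternal") parents <- "father"
      if (lab == "homozygous_recessive") parents <- c("mother", "father")
      rows[[length(rows) + 1L]] <- data.frame(
        proband_id = p, family_id = ctx$family_id,
        variant_id = vs$variants$variant_id[i],
        contig = vs$variants$contig[i], pos = vs$variants$pos[i],
        ref = vs$variants$ref[i], alt = vs$variants$alt[i],
        gene = vs$variants$gene[i] %||% NA_character_,
        acmg_class = vs$variants$acmg_class[i] %||% NA_character_,
        inheritance = lab, inheritance_raw = lab,
        carrier_parents = paste(parents, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  filtered <- rbind_df(rows) %||%
    empty_df(list(proband_id = character(), family_id = character(),
                  variant_id = character(), contig = character(),
                  pos = integer(), ref = character(), alt = character(),
                  gene = character(), acmg_class = character(),
                  inheritance = character(), inheritance_raw = character(),
                  carrier_parents = character()))
  comp <- detect_composite_recessive(filtered, pedigree)
  if (nrow(comp) > 0L) {
    for (k in seq_len(nrow(comp))) {
      ids <- unlist(strsplit(c(comp$maternal_ids[k], comp$paternal_ids[k]),
                             ","))
      hit <- filtered$proband_id == comp$proband_id[k] &
        filtered$variant_id %in% ids
      filtered$inheritance[hit] <- "composite_recessive"
    }
  }
  attr(filtered, "cascade_counts") <- rbind_df(counts)
  attr(filtered, "composite_genes") <- comp
  filtered
}
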