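# Synthetic cohort generator: pedigrees, genotypes, planted events with
# truth labels, per-caller SV calls, CNV segments, annotation table.
#
# Design: background common SNPs give the cohort its population structure
# (Hardy-Weinberg founders, Mendelian transmission, used by kinship QC and
# the internal-cohort frequency filter); planted events carry the
# statistical signal each pipeline stage must recover; benign-noise events
# each fail exactly one cascade filter so filter attribution is testable.

new_counter <- function() {
  env <- new.env(parent = emptyenv())
  env$items <- list()
  env
}
push <- function(env, x) env$items[[length(env$items) + 1L]] <- x

# ---- pedigree construction -------------------------------------------

build_families <- function(config) {
  n <- config$n_families
  fam_ids <- sprintf("FAM%03d", seq_len(n))
  quad <- rep(FALSE, n)
  quad[sample.int(n, config$n_quad_families)] <- TRUE
  single_parent <- rep(FALSE, n); no_parent <- rep(FALSE, n)
  single_parent[sample(which(!quad), config$n_single_parent)] <- TRUE
  # the no-parent families are quads, so two probands each lack parental
  # genomes while the sequenced-individual total matches the study (298)
  no_parent[sample(which(quad), config$n_no_parent)] <- TRUE

  ped_rows <- list(); fam_rows <- list()
  for (i in seq_len(n)) {
    f <- fam_ids[i]
    fa <- paste0(f, "_F"); mo <- paste0(f, "_M")
    n_pro <- if (quad[i]) 2L else 1L
    pros <- if (n_pro == 2L) paste0(f, "_P", 1:2) else paste0(f, "_P")
    pro_sex <- ifelse(stats::runif(n_pro) < config$p_male, "M", "F")
    fa_seq <- TRUE; mo_seq <- TRUE
    if (single_parent[i]) {
      if (stats::runif(1) < 0.5) fa_seq <- FALSE else mo_seq <- FALSE
    }
    if (no_parent[i]) { fa_seq <- FALSE; mo_seq <- FALSE }
    ped_rows[[length(ped_rows) + 1L]] <- data.frame(
      family_id = f,
      sample_id = c(fa, mo, pros),
      father_id = c(NA, NA, rep(fa, n_pro)),
      mother_id = c(NA, NA, rep(mo, n_pro)),
      role = c("father", "mother", rep("proband", n_pro)),
      sex = c("M", "F", pro_sex),
      affected = c(FALSE, FALSE, rep(TRUE, n_pro)),
      sequenced = c(fa_seq, mo_seq, rep(TRUE, n_pro)),
      stringsAsFactors = FALSE)
    fam_rows[[length(fam_rows) + 1L]] <- data.frame(
      family_id = f, father_id = fa, mother_id = mo,
      father_seq = fa_seq, mother_seq = mo_seq, n_probands = n_pro,
      stringsAsFactors = FALSE)
  }
  list(pedigree = rbind_df(ped_rows), families = rbind_df(fam_rows))
}

assign_groups <- function(pedigree, fractions) {
  probands <- pedigree$sample_id[pedigree$role == "proband"]
  n <- length(probands)
  counts <- floor(fractions * n)
  while (sum(counts) < n) {
    k <- which.max(fractions * n - counts)
    counts[k] <- counts[k] + 1L
  }
  labels <- sample(rep(names(fractions), counts))
  data.frame(proband_id = probands, group = labels, stringsAsFactors = FALSE)
}

# ---- gene pools -------------------------------------------------------

make_gene_pools <- function(genes) {
  env <- new.env(parent = emptyenv())
  env$est_AD <- sample(genes$symbol[genes$sim_class == "est_AD"])
  env$est_AR <- sample(genes$symbol[genes$sim_class == "est_AR"])
  env$est_XL <- sample(genes$symbol[genes$sim_class == "est_XL"])
  env$listed_only <- sample(genes$symbol[genes$sim_class == "listed_only"])
  env$unlisted <- sample(genes$symbol[genes$sim_class == "unlisted"])
  env$acmg_sf <- sample(genes$symbol[genes$sim_class == "acmg_sf"])
  env
}

pop_gene <- function(pools, pool) {
  v <- pools[[pool]]
  if (length(v) == 0L)
    ndd_stop(paste("planted events exceed available genes in pool", pool),
             "config_error")
  pools[[pool]] <- v[-1L]
  v[1L]
}

# Random exonic position (1-based) in a gene, avoiding used positions
exon_position <- function(reference, gene_symbol, used) {
  g <- reference$genes[reference$genes$symbol == gene_symbol, ]
  all_pos <- unlist(mapply(function(s, e) (s + 1L):e,
                           g$exon_start[[1]], g$exon_end[[1]],
                           SIMPLIFY = FALSE))
  free <- setdiff(all_pos, used)
  list(contig = g$contig, pos = free[sample.int(length(free), 1L)])
}

random_alt <- function(ref) sample(setdiff(BASES, ref), 1L)

default_annotation <- function() {
  list(gene = NA_character_, func_region = "exonic",
       exonic_consequence = "nonsynonymous", gnomad_af = NA_real_,
       cadd_phred = NA_real_, gerp_rs = NA_real_,
       clinvar_class = NA_character_, intervar_class = NA_character_,
       acmg_class = "VUS", alphamissense_class = NA_character_)
}

passing_annotation <- function(gene) {
  ann <- default_annotation()
  ann$gene <- gene
  ann$gnomad_af <- if (stats::runif(1) < 0.7) NA_real_ else
    stats::runif(1, 0, 0.004)
  ann$cadd_phred <- round(stats::runif(1, 22, 35), 2)
  ann$gerp_rs <- round(stats::runif(1, 3, 6), 2)
  ann$alphamissense_class <- sample(c("LP", "VUS", "LB"), 1L)
  ann
}

# ---- the generator ----------------------------------------------------

#' Generate a synthetic family cohort with planted, truth-labelled events
#'
#' Simulates the full input set of the prioritization pipeline: pedigrees
#' (trios and multiplex quads, some with unsequenced parents), background
#' common SNPs (founders in Hardy-Weinberg equilibrium at uniform MAFs,
#' offspring by Mendelian transmission), planted short-variant events per
#' class (de novo, X-linked, homozygous recessive, composite recessive,
#' inherited candidates), cross-class compound events (an exonic SV and a
#' short variant in the same gene from different parents), benign-noise
#' variants each failing exactly one cascade filter, noisy per-caller SV
#' calls with breakpoint jitter and configurable caller dropout, read-depth
#' CNV segments, and the annotation table the filters consume. Every
#' planted event has exactly one truth record.
#'
#' @param config a \code{\link{sim_config}}.
#' @param reference an \code{\link{generate_reference}} result; generated
#'   from \code{config} when NULL.
#' @param seed overrides \code{config$seed} when given.
#' @return An object of class \code{ndd_cohort}.
#' @export
generate_cohort <- function(config = sim_config(), reference = NULL,
                            seed = NULL) {
  seed <- as.integer(seed %||% config$seed)
  if (is.null(reference)) reference <- generate_reference(config, seed)
  set.seed(seed + 1000L)

  fam <- build_families(config)
  pedigree <- fam$pedigree
  families <- fam$families
  groups <- assign_groups(pedigree, config$group_fractions)
  pools <- make_gene_pools(reference$genes)

  autos <- setdiff(names(reference$sequences), reference$x_contig)
  auto_lens <- Biostrings::width(reference$sequences[autos])

  # -- background common SNPs ------------------------------------------
  n_bg <- config$n_common_snps
  bg_contig <- sample(autos, n_bg, replace = TRUE,
                      prob = auto_lens / sum(auto_lens))
  bg_pos <- integer(n_bg)
  for (i in seq_len(n_bg))
    bg_pos[i] <- sample.int(length(
      reference$sequences[[bg_contig[i]]]) - 200L, 1L) + 100L
  dup <- duplicated(paste(bg_contig, bg_pos))
  bg_contig <- bg_contig[!dup]; bg_pos <- bg_pos[!dup]
  n_bg <- length(bg_pos)
  bg_ref <- vapply(seq_len(n_bg), function(i)
    ref_base(reference, bg_contig[i], bg_pos[i]), "")
  bg_alt <- vapply(bg_ref, random_alt, "")
  bg_maf <- stats::runif(n_bg, config$maf_range[1], config$maf_range[2])
  bg_id <- variant_key(bg_contig, bg_pos, bg_ref, bg_alt)
  used_positions <- split(bg_pos, bg_contig)

  # -- planted short-variant events ------------------------------------
  planted <- new_counter()   # per-variant carrier specs
  truth <- new_counter()
  ann_rows <- new_counter()

  mark_used <- function(contig, pos) {
    used_positions[[contig]] <<- c(used_positions[[contig]], pos)
  }
  new_snv <- function(pool) {
    gene <- pop_gene(pools, pool)
    loc <- exon_position(reference, gene, used_positions[[
      reference$genes$contig[reference$genes$symbol == gene]]])
    mark_used(loc$contig, loc$pos)
    ref <- ref_base(reference, loc$contig, loc$pos)
    list(gene = gene, contig = loc$contig, pos = loc$pos, ref = ref,
         alt = random_alt(ref))
  }
  pathogenic_acmg <- function() sample(c("P", "LP", "VUS_hot", "VUS_warm"), 1L)

  fam_pick <- function(pool_df, n) {
    if (nrow(pool_df) < 1L)
      ndd_stop("no eligible family for planted event", "config_error")
    pool_df[sample.int(nrow(pool_df), n, replace = TRUE), , drop = FALSE]
  }
  proband_of <- function(family_id) {
    pros <- pedigree$sample_id[pedigree$family_id == family_id &
                                 pedigree$role == "proband"]
    sample(pros, 1L)
  }
  add_variant <- function(v, family_id, gt, ploidy = NULL, dp = NULL,
                          filter = "PASS", ann) {
    push(planted, list(variant_id = variant_key(v$contig, v$pos, v$ref, v$alt),
                       contig = v$contig, pos = v$pos, ref = v$ref,
                       alt = v$alt, filter = filter, family_id = family_id,
                       gt = gt, ploidy = ploidy, dp = dp))
    if (!is.null(ann)) {
      ann$variant_id <- variant_key(v$contig, v$pos, v$ref, v$alt)
      push(ann_rows, ann)
    }
  }
  complete_trios <- families[families$father_seq & families$mother_seq, ]
  one_parent <- families[xor(families$father_seq, families$mother_seq), ]

  ev <- config$events
  # de novo: both parents hom-ref at depth
  for (k in seq_len(ev[["de_novo"]])) {
    f <- fam_pick(complete_trios, 1L)
    p <- proband_of(f$family_id)
    v <- new_snv("est_AD")
    ann <- passing_annotation(v$gene); ann$acmg_class <- pathogenic_acmg()
    gt <- stats::setNames(c(1L, 0L, 0L), c(p, f$father_id, f$mother_id))
    add_variant(v, f$family_id, gt, ann = ann)
    push(truth, list(family_id = f$family_id, proband_id = p,
                     class = "de_novo", gene = v$gene,
                     variant_ids = variant_key(v$contig, v$pos, v$ref, v$alt),
                     variant_type = "short",
                     expected_label = "de_novo",
                     expected_category = "candidate",
                     expected_yield = ann$acmg_class %in%
                       c("P", "LP", "VUS_hot", "VUS_warm"),
                     noise_type = NA_character_))
  }
  # X-linked: hemizygous male proband, heterozygous mother
  male_ok <- pedigree[pedigree$role == "proband" & pedigree$sex == "M", ]
  male_ok <- male_ok[male_ok$family_id %in%
                       families$family_id[families$mother_seq], ]
  xl_picks <- male_ok[sample.int(nrow(male_ok), ev[["x_linked"]],
                                 replace = TRUE), ]
  for (k in seq_len(ev[["x_linked"]])) {
    p <- xl_picks$sample_id[k]
    fr <- families[families$family_id == xl_picks$family_id[k], ]
    v <- new_snv("est_XL")
    ann <- passing_annotation(v$gene); ann$acmg_class <- pathogenic_acmg()
    gt <- stats::setNames(c(1L, 1L, 0L), c(p, fr$mother_id, fr$father_id))
    pl <- stats::setNames(c(1L, 2L, 1L), c(p, fr$mother_id, fr$father_id))
    add_variant(v, fr$family_id, gt, ploidy = pl, ann = ann)
    push(truth, list(family_id = fr$family_id, proband_id = p,
                     class = "x_linked", gene = v$gene,
                     variant_ids = variant_key(v$contig, v$pos, v$ref, v$alt),
                     variant_type = "short", expected_label = "x_linked",
                     expected_category = "candidate",
                     expected_yield = ann$acmg_class %in%
                       c("P", "LP", "VUS_hot", "VUS_warm"),
                     noise_type = NA_character_))
  }
  # homozygous recessive
  for (k in seq_len(ev[["hom_recessive"]])) {
    f <- fam_pick(complete_trios, 1L)
    p <- proband_of(f$family_id)
    v <- new_snv("est_AR")
    ann <- passing_annotation(v$gene); ann$acmg_class <- pathogenic_acmg()
    gt <- stats::setNames(c(2L, 1L, 1L), c(p, f$father_id, f$mother_id))
    add_variant(v, f$family_id, gt, ann = ann)
    push(truth, list(family_id = f$family_id, proband_id = p,
                     class = "hom_recessive", gene = v$gene,
                     variant_ids = variant_key(v$contig, v$pos, v$ref, v$alt),
                     variant_type = "short",
                     expected_label = "homozygous_recessive",
                     expected_category = "candidate",
                     expected_yield = ann$acmg_class %in%
                       c("P", "LP", "VUS_hot", "VUS_warm"),
                     noise_type = NA_character_))
  }
  # composite recessive: one maternal + one paternal SNV in the same gene
  for (k in seq_len(ev[["composite_recessive"]])) {
    f <- fam_pick(complete_trios, 1L)
    p <- proband_of(f$family_id)
    gene <- pop_gene(pools, "est_AR")
    ids <- character(2)
    for (side in 1:2) {
      loc <- exon_position(reference, gene,
                           used_positions[[reference$genes$contig[
                             reference$genes$symbol == gene]]])
      mark_used(loc$contig, loc$pos)
      ref <- ref_base(reference, loc$contig, loc$pos)
      v <- list(gene = gene, contig = loc$contig, pos = loc$pos, ref = ref,
                alt = random_alt(ref))
      ann <- passing_annotation(gene); ann$acmg_class <- pathogenic_acmg()
      parent <- if (side == 1L) f$mother_id else f$father_id
      gt <- stats::setNames(c(1L, 1L), c(p, parent))
      add_variant(v, f$family_id, gt, ann = ann)
      ids[side] <- variant_key(v$contig, v$pos, v$ref, v$alt)
    }
    push(truth, list(family_id = f$family_id, proband_id = p,
                     class = "composite_recessive", gene = gene,
                     variant_ids = paste(ids, collapse = ","),
                     variant_type = "short",
                     expected_label = "composite_recessive",
                     expected_category = "candidate",
                     expected_yield = TRUE,
                     noise_type = NA_character_))
  }
  # inherited candidate (het parent -> het proband)
  for (k in seq_len(ev[["inherited_candidate"]])) {
    f <- fam_pick(complete_trios, 1L)
    p <- proband_of(f$family_id)
    v <- new_snv("est_AD")
    ann <- passing_annotation(v$gene)
    ann$acmg_class <- sample(c("LP", "VUS"), 1L)
    maternal <- stats::runif(1) < 0.5
    parent <- if (maternal) f$mother_id else f$father_id
    other <- if (maternal) f$father_id else f$mother_id
    gt <- stats::setNames(c(1L, 1L, 0L), c(p, parent, other))
    add_variant(v, f$family_id, gt, ann = ann)
    push(truth, list(family_id = f$family_id, proband_id = p,
                     class = "inherited_candidate", gene = v$gene,
                     variant_ids = variant_key(v$contig, v$pos, v$ref, v$alt),
                     variant_type = "short",
                     expected_label = if (maternal) "inherited_maternal"
                                      else "inherited_paternal",
                     expected_category = "candidate",
                     expected_yield = ann$acmg_class %in%
                       c("P", "LP", "VUS_hot", "VUS_warm"),
                     noise_type = NA_character_))
  }

  # -- benign noise: each fails exactly one named filter ----------------
  noise_types <- rep(c("non_pass", "low_depth", "common_gnomad",
                       "internal_het", "internal_hom", "not_exonic",
                       "synonymous", "benign_label", "low_cadd",
                       "not_in_list"),
                     length.out = ev[["benign_noise"]])
  other_parents <- function(family_id, n) {
    cand <- pedigree[pedigree$family_id != family_id &
                       pedigree$role %in% c("father", "mother") &
                       pedigree$sequenced, ]
    cand[sample.int(nrow(cand), n), ]
  }
  for (k in seq_along(noise_types)) {
    type <- noise_types[k]
    f <- fam_pick(complete_trios, 1L)
    p <- proband_of(f$family_id)
    pool <- if (type == "not_in_list") "unlisted" else "listed_only"
    v <- new_snv(pool)
    ann <- passing_annotation(v$gene)
    filter <- "PASS"; dp <- NULL
    if (type == "common_gnomad") ann$gnomad_af <- 0.02
    if (type == "not_exonic") ann$func_region <- "intronic"
    if (type == "synonymous") ann$exonic_consequence <- "synonymous"
    if (type == "benign_label")
      ann[[sample(c("clinvar_class", "intervar_class"), 1L)]] <-
        sample(c("Benign", "Likely benign", "Benign/Likely benign"), 1L)
    if (type == "low_cadd") ann$cadd_phred <- 15
    if (type == "non_pass") filter <- "LowQual"
    if (type == "low_depth") dp <- stats::setNames(5L, p)
    gt <- stats::setNames(c(1L, 1L, 0L), c(p, f$mother_id, f$father_id))
    add_variant(v, f$family_id, gt, dp = dp, filter = filter, ann = ann)
    if (type == "internal_het") {
      extra <- other_parents(f$family_id, 5L)
      for (j in seq_len(nrow(extra)))
        add_variant(v, extra$family_id[j],
                    stats::setNames(1L, extra$sample_id[j]), ann = NULL)
    }
    if (type == "internal_hom") {
      extra <- other_parents(f$family_id, 3L)
      for (j in seq_len(nrow(extra)))
        add_variant(v, extra$family_id[j],
                    stats::setNames(2L, extra$sample_id[j]), ann = NULL)
    }
    push(truth, list(family_id = f$family_id, proband_id = p,
                     class = "benign_noise", gene = v$gene,
                     variant_ids = variant_key(v$contig, v$pos, v$ref, v$alt),
                     variant_type = "short",
                     expected_label = "inherited_maternal",
                     expected_category = "none",
                     expected_yield = FALSE, noise_type = type))
  }

  # -- secondary findings: ClinVar/InterVar P/LP in ACMG-SF genes -------
  for (k in seq_len(config$n_secondary)) {
    f <- fam_pick(complete_trios, 1L)
    gene <- pop_gene(pools, "acmg_sf")
    mode <- reference$genes$inheritance_mode[
      reference$genes$symbol == gene]
    loc <- exon_position(reference, gene,
                         used_positions[[reference$genes$contig[
                           reference$genes$symbol == gene]]])
    mark_used(loc$contig, loc$pos)
    ref <- ref_base(reference, loc$contig, loc$pos)
    v <- list(gene = gene, contig = loc$contig, pos = loc$pos, ref = ref,
              alt = random_alt(ref))
    ann <- passing_annotation(gene)
    src <- sample(c("clinvar_class", "intervar_class", "both"), 1L)
    lab <- sample(c("Pathogenic", "Likely pathogenic"), 1L)
    if (src %in% c("clinvar_class", "both")) ann$clinvar_class <- lab
    if (src %in% c("intervar_class", "both")) ann$intervar_class <- lab
    carrier <- sample(c(f$father_id, f$mother_id), 1L)
    gt <- if (mode == "AR") stats::setNames(2L, carrier) else
      stats::setNames(1L, carrier)
    add_variant(v, f$family_id, gt, ann = ann)
    push(truth, list(family_id = f$family_id, proband_id = carrier,
                     class = "secondary_finding", gene = gene,
                     variant_ids = variant_key(v$contig, v$pos, v$ref,
                                               v$alt),
                     variant_type = "short",
                     expected_label = NA_character_,
                     expected_category = "secondary",
                     expected_yield = FALSE, noise_type = NA_character_))
  }

  # -- structural variants ---------------------------------------------
  sv <- new_counter()      # true SV events with carrier lists
  sv_id_n <- 0L
  next_sv_id <- function() { sv_id_n <<- sv_id_n + 1L
    sprintf("SV%04d", sv_id_n) }
  gene_row <- function(symbol)
    reference$genes[reference$genes$symbol == symbol, ]

  sv_over_exon <- function(gene, pad = 300L) {
    g <- gene_row(gene)
    k <- sample(seq_along(g$exon_start[[1]]), 1L)
    start <- max(0L, g$exon_start[[1]][k] - pad)
    end <- g$exon_end[[1]][k] + pad
    list(contig = g$contig, start = start, end = end)
  }

  # compound SV+SNV: SV from one parent, SNV from the other, same AR gene
  for (k in seq_len(ev[["compound_sv_snv"]])) {
    f <- fam_pick(complete_trios, 1L)
    p <- proband_of(f$family_id)
    gene <- pop_gene(pools, "est_AR")
    sv_from_mother <- stats::runif(1) < 0.5
    sv_parent <- if (sv_from_mother) f$mother_id else f$father_id
    snv_parent <- if (sv_from_mother) f$father_id else f$mother_id
    loc <- sv_over_exon(gene)
    push(sv, list(sv_id = next_sv_id(), family_id = f$family_id,
                  sv_type = "DEL", contig = loc$contig, start = loc$start,
                  end = loc$end, length = loc$end - loc$start,
                  population_af = NA_real_,
                  carriers = c(p, sv_parent), truth_class = "compound_sv_snv"))
    # the short-variant half, in a different exon
    loc2 <- exon_position(reference, gene,
                          c(used_positions[[gene_row(gene)$contig]],
                            (loc$start + 1L):loc$end))
    mark_used(loc2$contig, loc2$pos)
    ref <- ref_base(reference, loc2$contig, loc2$pos)
    v <- list(gene = gene, contig = loc2$contig, pos = loc2$pos, ref = ref,
              alt = random_alt(ref))
    ann <- passing_annotation(gene); ann$acmg_class <- pathogenic_acmg()
    gt <- stats::setNames(c(1L, 1L, 0L), c(p, snv_parent, sv_parent))
    add_variant(v, f$family_id, gt, ann = ann)
    push(truth, list(family_id = f$family_id, proband_id = p,
                     class = "compound_sv_snv", gene = gene,
                     variant_ids = paste(variant_key(v$contig, v$pos, v$ref,
                                                     v$alt),
                                         sprintf("SV%04d", sv_id_n),
                                         sep = ","),
                     variant_type = "short+SV",
                     expected_label = if (sv_from_mother)
                       "inherited_paternal" else "inherited_maternal",
                     expected_category = "compound",
                     expected_yield = FALSE, noise_type = NA_character_))
  }

  # passing INS/MEI near exons of listed genes
  for (type in c(rep("INS", config$n_ins), rep("MEI", config$n_mei))) {
    f <- fam_pick(complete_trios, 1L)
    p <- proband_of(f$family_id)
    gene <- pop_gene(pools, "listed_only")
    g <- gene_row(gene)
    k <- sample(seq_along(g$exon_start[[1]]), 1L)
    start <- max(0L, g$exon_start[[1]][k] - sample(5:15, 1L))
    parent <- sample(c(f$father_id, f$mother_id), 1L)
    push(sv, list(sv_id = next_sv_id(), family_id = f$family_id,
                  sv_type = type, contig = g$contig, start = start,
                  end = start + 1L, length = sample(300:6000, 1L),
                  population_af = NA_real_, carriers = c(p, parent),
                  truth_class = "sv_extra"))
    push(truth, list(family_id = f$family_id, proband_id = p,
                     class = "sv_extra", gene = gene,
                     variant_ids = sprintf("SV%04d", sv_id_n),
                     variant_type = type, expected_label = "inherited",
                     expected_category = "retained",
                     expected_yield = FALSE, noise_type = NA_character_))
  }

  # SV noise
  sv_noise_types <- c(rep(c("single_caller", "common_af", "non_exonic"),
                          length.out = max(0L, config$n_sv_noise - 1L)),
                      if (config$n_sv_noise > 0L) "frequent_locus")
  for (type in sv_noise_types) {
    f <- fam_pick(complete_trios, 1L)
    p <- proband_of(f$family_id)
    if (type == "non_exonic") {
      contig <- sample(autos, 1L)
      gx <- gene_exons(reference$genes)
      gx <- gx[gx$contig == contig, ]
      # place between the last exon and the contig end
      start <- max(gx$end) + 5000L
      loc <- list(contig = contig, start = start, end = start + 2000L)
      af <- NA_real_
    } else {
      gene <- pop_gene(pools, "listed_only")
      loc <- sv_over_exon(gene)
      af <- if (type == "common_af") 0.05 else NA_real_
    }
    carriers <- c(p, sample(c(f$father_id, f$mother_id), 1L))
    fams <- f$family_id
    if (type == "frequent_locus") {
      n_rec <- min(nrow(families), max(2L, ceiling(0.15 * nrow(families))))
      many <- families[sample.int(nrow(families), n_rec), ]
      carriers <- vapply(many$family_id, proband_of, "")
      fams <- many$family_id
    }
    push(sv, list(sv_id = next_sv_id(), family_id = fams[1],
                  sv_type = "DEL", contig = loc$contig, start = loc$start,
                  end = loc$end, length = loc$end - loc$start,
                  population_af = af, carriers = carriers,
                  truth_class = paste0("sv_noise_", type)))
    push(truth, list(family_id = fams[1], proband_id = p,
                     class = "benign_noise", gene = NA_character_,
                     variant_ids = sprintf("SV%04d", sv_id_n),
                     variant_type = "SV", expected_label = NA_character_,
                     expected_category = "none", expected_yield = FALSE,
                     noise_type = paste0("sv_", type)))
  }
  sv_truth <- rbind_df(lapply(sv$items, function(x)
    data.frame(sv_id = x$sv_id, family_id = x$family_id, sv_type = x$sv_type,
               contig = x$contig, start = x$start, end = x$end,
               length = x$length, population_af = x$population_af,
               carriers = paste(x$carriers, collapse = ","),
               truth_class = x$truth_class, stringsAsFactors = FALSE)))

  # -- per-caller SV calls with dropout + jitter ------------------------
  sens <- config$caller_sensitivity
  cnv_callers <- c("manta", "cnvnator", "breakdancer", "lumpy")
  call_rows <- new_counter()
  for (x in sv$items) {
    emitters <- if (x$sv_type == "INS") "manta"
      else if (x$sv_type == "MEI") "melt"
      else if (x$truth_class == "sv_noise_single_caller") "lumpy"
      else cnv_callers
    for (carrier in x$carriers) {
      for (cl in emitters) {
        if (stats::runif(1) > sens[[cl]]) next
        j1 <- as.integer(round(stats::rnorm(1, 0, config$jitter_sd)))
        j2 <- as.integer(round(stats::rnorm(1, 0, config$jitter_sd)))
        s <- max(0L, x$start + j1)
        e <- if (x$sv_type %in% c("INS", "MEI")) s + 1L
             else max(s + 50L, x$end + j2)
        push(call_rows, data.frame(
          sample_id = carrier, caller = cl, sv_type = x$sv_type,
          contig = x$contig, start = s, end = e,
          length = if (x$sv_type %in% c("INS", "MEI")) x$length else e - s,
          genotype = 1L, population_af = x$population_af,
          stringsAsFactors = FALSE))
      }
    }
  }
  sv_calls <- rbind_df(call_rows$items) %||%
    empty_df(list(sample_id = character(), caller = character(),
                  sv_type = character(), contig = character(),
                  start = integer(), end = integer(), length = integer(),
                  genotype = integer(), population_af = numeric()))

  # -- CNV segments -----------------------------------------------------
  seg_rows <- new_counter()
  for (x in sv$items) {
    if (!(x$sv_type %in% c("DEL", "DUP"))) next
    mu <- if (x$sv_type == "DEL") config$cnv_log2_del else config$cnv_log2_dup
    for (carrier in x$carriers)
      push(seg_rows, data.frame(
        sample_id = carrier, contig = x$contig, start = x$start, end = x$end,
        log2 = round(stats::rnorm(1, mu, config$cnv_log2_sd), 3),
        p_value = 1e-8, weight = round(stats::runif(1, 30, 60), 1),
        stringsAsFactors = FALSE))
  }
  # per-sample background segments failing exactly one segment filter
  seq_samples <- pedigree$sample_id[pedigree$sequenced]
  for (s in sample(seq_samples, min(60L, length(seq_samples)))) {
    contig <- sample(autos, 1L)
    st <- sample.int(200000L, 1L)
    fail <- sample(c("log2", "p", "weight"), 1L)
    push(seg_rows, data.frame(
      sample_id = s, contig = contig, start = st, end = st + 5000L,
      log2 = if (fail == "log2") 0.2 else round(stats::rnorm(1, -1, 0.05), 3),
      p_value = if (fail == "p") 1e-3 else 1e-8,
      weight = if (fail == "weight") 5 else 40,
      stringsAsFactors = FALSE))
  }
  cnv_segments <- rbind_df(seg_rows$items)
  cnv_segments$cnv_type <- ifelse(cnv_segments$log2 > 0, "DUP", "DEL")
  names(cnv_segments)[names(cnv_segments) == "log2"] <- "log2_ratio"

  # -- assemble per-family variant sets --------------------------------
  planted_by_fam <- split(planted$items,
                          vapply(planted$items, `[[`, "", "family_id"))
  fam_sets <- list()
  for (i in seq_len(nrow(families))) {
    f <- families$family_id[i]
    members <- pedigree[pedigree$family_id == f & pedigree$sequenced, ]
    sams <- members$sample_id
    is_male <- stats::setNames(members$sex == "M", sams)
    # background genotypes: founders HWE, children Mendelian
    fa_gt <- stats::rbinom(n_bg, 2L, bg_maf)
    mo_gt <- stats::rbinom(n_bg, 2L, bg_maf)
    gts <- list()
    for (s in sams) {
      role <- members$role[members$sample_id == s]
      gts[[s]] <- switch(role,
        father = fa_gt, mother = mo_gt,
        stats::rbinom(n_bg, 1L, fa_gt / 2) + stats::rbinom(n_bg, 1L, mo_gt / 2))
    }
    if (config$genotype_error_rate > 0) {
      for (s in sams) {
        flip <- stats::runif(n_bg) < config$genotype_error_rate
        gts[[s]][flip] <- sample(0:2, sum(flip), replace = TRUE)
      }
    }
    pl_items <- planted_by_fam[[f]] %||% list()
    n_pl <- length(pl_items)
    n_sites <- n_bg + n_pl
    v <- data.frame(
      variant_id = c(bg_id, vapply(pl_items, `[[`, "", "variant_id")),
      contig = c(bg_contig, vapply(pl_items, `[[`, "", "contig")),
      pos = c(bg_pos, vapply(pl_items, function(x) as.integer(x$pos), 1L)),
      ref = c(bg_ref, vapply(pl_items, `[[`, "", "ref")),
      alt = c(bg_alt, vapply(pl_items, `[[`, "", "alt")),
      filter = c(rep("PASS", n_bg), vapply(pl_items, `[[`, "", "filter")),
      stringsAsFactors = FALSE)
    gm <- matrix(0L, n_sites, length(sams), dimnames = list(NULL, sams))
    pm <- matrix(2L, n_sites, length(sams), dimnames = list(NULL, sams))
    dm <- matrix(stats::rpois(n_sites * length(sams),
                              max(1, config$mean_depth - 10)) + 10L,
                 n_sites, length(sams), dimnames = list(NULL, sams))
    for (s in sams) gm[seq_len(n_bg), s] <- gts[[s]]
    if (n_pl > 0L) {
      for (j in seq_len(n_pl)) {
        x <- pl_items[[j]]
        row <- n_bg + j
        on_x <- x$contig == reference$x_contig
        if (on_x) pm[row, is_male[sams]] <- 1L
        for (s in intersect(names(x$gt), sams)) gm[row, s] <- x$gt[[s]]
        if (!is.null(x$ploidy))
          for (s in intersect(names(x$ploidy), sams)) pm[row, s] <- x$ploidy[[s]]
        if (!is.null(x$dp))
          for (s in intersect(names(x$dp), sams)) dm[row, s] <- x$dp[[s]]
      }
    }
    keep <- !duplicated(v$variant_id)
    o <- order(v$contig[keep], v$pos[keep], v$alt[keep])
    idx <- which(keep)[o]
    fam_sets[[f]] <- new_variant_set(v[idx, , drop = FALSE],
                                     gm[idx, , drop = FALSE],
                                     dm[idx, , drop = FALSE],
                                     pm[idx, , drop = FALSE])
  }

  # -- annotation table -------------------------------------------------
  ann_df <- rbind_df(lapply(ann_rows$items, function(a)
    as.data.frame(a, stringsAsFactors = FALSE)))
  bg_ann <- data.frame(variant_id = bg_id, gene = NA_character_,
                       func_region = "intronic",
                       exonic_consequence = "unknown",
                       gnomad_af = round(bg_maf, 4), cadd_phred = NA_real_,
                       gerp_rs = NA_real_, clinvar_class = NA_character_,
                       intervar_class = NA_character_,
                       acmg_class = NA_character_,
                       alphamissense_class = NA_character_,
                       stringsAsFactors = FALSE)
  annotations <- rbind(ann_df[, names(bg_ann)], bg_ann)

  truth_df <- rbind_df(lapply(truth$items, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))

  cohort_vs <- attach_annotations(combine_variant_sets(fam_sets), annotations)
  structure(list(pedigree = pedigree, families = families, groups = groups,
                 family_variants = fam_sets, variants = cohort_vs,
                 annotations = annotations, sv_truth = sv_truth,
                 sv_calls = sv_calls, cnv_segments = cnv_segments,
                 truth = truth_df, reference = reference, config = config,
                 seed = seed),
            class = "ndd_cohort")
}

#' @export
print.ndd_cohort <- function(x, ...) {
  cat(sprintf(paste0("<ndd_cohort> %d families, %d probands, %d sequenced ",
                     "individuals\n  %d short-variant sites, %d true SVs, ",
                     "%d planted events\n"),
              nrow(x$families), sum(x$pedigree$role == "proband"),
              sum(x$pedigree$sequenced), nrow(x$variants$variants),
              nrow(x$sv_truth), nrow(x$truth)))
  invisible(x)
}

#' Write planted-event truth records to TSV
#' @param truth truth data.frame from an \code{ndd_cohort}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  cols <- c("family_id", "proband_id", "class", "gene", "variant_ids",
            "variant_type", "expected_label", "expected_category",
            "expected_yield", "noise_type")
  if (is.null(truth) || nrow(truth) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  write_tsv(truth[, cols], path)
}

#' Write a cohort to disk in the pipeline's input dialects
#'
#' Emits exactly what the readers in this package consume: reference FASTA
#' + gene TSV, a cohort PED, one short-variant VCF per family, one SV VCF
#' per caller, a CNV segment TSV, the annotation TSV, proband groups and
#' the truth table.
#'
#' @param cohort an \code{ndd_cohort}.
#' @param dir output directory.
#' @return Named list of paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_reference(cohort$reference, dir)
  paths$ped <- file.path(dir, "cohort.ped")
  write_pedigree(cohort$pedigree, paths$ped)
  vdir <- file.path(dir, "vcf")
  dir.create(vdir, showWarnings = FALSE)
  clen <- stats::setNames(Biostrings::width(cohort$reference$sequences),
                          names(cohort$reference$sequences))
  paths$vcf <- character()
  for (f in names(cohort$family_variants)) {
    p <- file.path(vdir, paste0(f, ".vcf"))
    write_multisample_vcf(cohort$family_variants[[f]], p, clen)
    paths$vcf[f] <- p
  }
  paths$sv_vcf <- character()
  for (cl in unique(cohort$sv_calls$caller)) {
    p <- file.path(dir, paste0("sv_", cl, ".vcf"))
    write_sv_vcf(cohort$sv_calls[cohort$sv_calls$caller == cl, ], p, cl, clen)
    paths$sv_vcf[cl] <- p
  }
  paths$cnv <- file.path(dir, "cnv_segments.tsv")
  seg <- cohort$cnv_segments
  names(seg)[names(seg) == "log2_ratio"] <- "log2"
  write_tsv(seg[, c("sample_id", "contig", "start", "end", "log2",
                    "p_value", "weight")], paths$cnv)
  paths$annotations <- file.path(dir, "annotations.tsv")
  write_tsv(cohort$annotations, paths$annotations)
  paths$groups <- file.path(dir, "groups.tsv")
  write_tsv(cohort$groups, paths$groups)
  paths$truth <- file.path(dir, "truth.tsv")
  write_truth_table(cohort$truth, paths$truth)
  paths
}
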