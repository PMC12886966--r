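# Shared, lazily-built fixtures. The default-sized cohort reproduces the
# study conditions and backs the recovery checks; the small cohort keeps
# unit tests fast.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

default_reference <- function()
  memo("default_reference", function() generate_reference(sim_config(), seed = 1))

default_cohort <- function()
  memo("default_cohort", function()
    generate_cohort(sim_config(), default_reference()))

default_pipeline <- function()
  memo("default_pipeline", function() run_pipeline(default_cohort()))

small_sim_config <- function(...)
  sim_config(n_families = 12, n_quad_families = 2, n_single_parent = 2,
             n_no_parent = 1, n_common_snps = 80,
             events = c(de_novo = 4, x_linked = 3, hom_recessive = 2,
                        composite_recessive = 2, compound_sv_snv = 2,
                        inherited_candidate = 3, benign_noise = 8),
             n_sv_noise = 4, n_ins = 1, n_mei = 1, n_secondary = 2,
             autosomes = c(chr1 = 80000L, chr2 = 80000L, chr3 = 80000L),
             x_length = 60000L, n_genes_autosome = 36, n_genes_x = 12,
             seed = 3L, ...)

small_reference <- function()
  memo("small_reference", function() generate_reference(small_sim_config()))

small_cohort <- function()
  memo("small_cohort", function()
    generate_cohort(small_sim_config(), small_reference()))

pipeline_config <- function(reference)
  run_config(x_contig = reference$x_contig,
             par_intervals = reference$par_intervals)

# Build a variant_set directly from a compact spec: a data.frame of sites
# plus named genotype/depth/ploidy matrices. Annotation columns present in
# `sites` are carried along.
make_variant_set <- function(sites, gt, dp = NULL, ploidy = NULL) {
  samples <- colnames(gt)
  n <- nrow(sites)
  if (is.null(dp)) dp <- matrix(30L, n, length(samples),
                                dimnames = list(NULL, samples))
  if (is.null(ploidy)) ploidy <- matrix(2L, n, length(samples),
                                        dimnames = list(NULL, samples))
  if (is.null(sites$variant_id))
    sites$variant_id <- nddtrio:::variant_key(sites$contig, sites$pos,
                                              sites$ref, sites$alt)
  if (is.null(sites$filter)) sites$filter <- "PASS"
  core <- c("variant_id", "contig", "pos", "ref", "alt", "filter")
  vs <- nddtrio:::new_variant_set(sites[, core], gt, dp, ploidy)
  extra <- setdiff(names(sites), core)
  for (cn in extra) vs$variants[[cn]] <- sites[[cn]]
  vs
}

# Minimal trio pedigree
make_trio_ped <- function(family = "FAM1", proband_sex = "M",
                          father_seq = TRUE, mother_seq = TRUE) {
  data.frame(
    family_id = family,
    sample_id = paste0(family, c("_F", "_M", "_P")),
    father_id = c(NA, NA, paste0(family, "_F")),
    mother_id = c(NA, NA, paste0(family, "_M")),
    role = c("father", "mother", "proband"),
    sex = c("M", "F", proband_sex),
    affected = c(FALSE, FALSE, TRUE),
    sequenced = c(father_seq, mother_seq, TRUE),
    stringsAsFactors = FALSE)
}

# One-row gene table with configurable flags
make_gene <- function(symbol = "G1", contig = "chr1",
                      exon_start = list(c(100L, 600L)),
                      exon_end = list(c(300L, 900L)),
                      pli = NA_real_, phaplo = NA_real_, ptriplo = NA_real_,
                      ndd_list = TRUE, established = TRUE,
                      acmg_sf = FALSE, mode = "AD") {
  g <- data.frame(symbol = symbol, contig = contig, strand = "+",
                  pli = pli, phaplo = phaplo, ptriplo = ptriplo,
                  ndd_list = ndd_list, established_ndd_gene = established,
                  acmg_sf_gene = acmg_sf, inheritance_mode = mode,
                  stringsAsFactors = FALSE)
  g$exon_start <- exon_start
  g$exon_end <- exon_end
  g
}

# Fully annotated single-site trio variant_set for filter tests
annotated_site <- function(gt_p = 1L, gt_f = 0L, gt_m = 0L,
                           dp_p = 30L, dp_f = 30L, dp_m = 30L,
                           filter = "PASS", gene = "G1",
                           func_region = "exonic",
                           exonic_consequence = "nonsynonymous",
                           gnomad_af = NA_real_, cadd_phred = 30,
                           clinvar_class = NA_character_,
                           intervar_class = NA_character_,
                           acmg_class = "P", contig = "chr1", pos = 150L,
                           ploidy = c(2L, 2L, 2L)) {
  sites <- data.frame(contig = contig, pos = pos, ref = "A", alt = "T",
                      filter = filter, gene = gene,
                      func_region = func_region,
                      exonic_consequence = exonic_consequence,
                      gnomad_af = gnomad_af, cadd_phred = cadd_phred,
                      gerp_rs = NA_real_, clinvar_class = clinvar_class,
                      intervar_class = intervar_class,
                      acmg_class = acmg_class,
                      alphamissense_class = NA_character_,
                      stringsAsFactors = FALSE)
  samples <- c("FAM1_F", "FAM1_M", "FAM1_P")
  gt <- matrix(c(gt_f, gt_m, gt_p), 1, 3, dimnames = list(NULL, samples))
  dp <- matrix(c(dp_f, dp_m, dp_p), 1, 3, dimnames = list(NULL, samples))
  pl <- matrix(ploidy, 1, 3, dimnames = list(NULL, samples))
  make_variant_set(sites, gt, dp, pl)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal VCF text builder
vcf_text <- function(rows, samples = c("S1", "S2", "S3")) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows)
}

# Independent single-pass conjunction oracle over randomized records
# (used by the cascade-equivalence checks).
oracle_keep <- function(v, gt_p, dp_p, het, hom, listed, cfg) {
  benign <- c("Benign", "Likely benign", "Benign/Likely benign")
  v$filter == "PASS" & !is.na(gt_p) & gt_p > 0L & dp_p >= cfg$dp_min &
    (is.na(v$gnomad_af) | v$gnomad_af < cfg$gnomad_af_max) &
    het < cfg$internal_het_max & hom < cfg$internal_hom_max &
    (!is.na(v$func_region) & v$func_region %in% c("exonic", "splicing")) &
    (is.na(v$exonic_consequence) | v$exonic_consequence != "synonymous") &
    !(v$clinvar_class %in% benign) & !(v$intervar_class %in% benign) &
    (is.na(v$cadd_phred) | v$cadd_phred > cfg$cadd_min) &
    (!is.na(v$gene) & v$gene %in% listed)
}

random_record_set <- function(n, seed) {
  set.seed(seed)
  genes <- c("G1", "G2", "G3", NA_character_)
  sites <- data.frame(
    contig = "chr1", pos = seq_len(n) * 10L, ref = "A", alt = "C",
    filter = sample(c("PASS", "LowQual"), n, TRUE, prob = c(0.8, 0.2)),
    gene = sample(genes, n, TRUE),
    func_region = sample(c("exonic", "splicing", "intronic", "intergenic"),
                         n, TRUE),
    exonic_consequence = sample(c("nonsynonymous", "synonymous", "stopgain",
                                  NA_character_), n, TRUE),
    gnomad_af = ifelse(runif(n) < 0.3, NA_real_,
                       round(runif(n, 0, 0.01), 5)),
    cadd_phred = ifelse(runif(n) < 0.3, NA_real_, round(runif(n, 0, 40), 2)),
    gerp_rs = NA_real_,
    clinvar_class = sample(c(NA_character_, "Benign", "Likely benign",
                             "Pathogenic",
                             "Conflicting interpretations of pathogenicity"),
                           n, TRUE),
    intervar_class = sample(c(NA_character_, "Likely benign"), n, TRUE,
                            prob = c(0.85, 0.15)),
    acmg_class = sample(c("P", "LP", "VUS", NA_character_), n, TRUE),
    alphamissense_class = NA_character_,
    stringsAsFactors = FALSE)
  samples <- make_trio_ped()$sample_id
  gt <- matrix(sample(c(0L, 1L, 2L, NA_integer_), n * 3, TRUE,
                      prob = c(0.35, 0.4, 0.2, 0.05)),
               n, 3, dimnames = list(NULL, samples))
  dp <- matrix(sample(5:40, n * 3, TRUE), n, 3,
               dimnames = list(NULL, samples))
  make_variant_set(sites, gt, dp)
}
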