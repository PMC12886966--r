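# Short-variant cascade: filter boundaries, inheritance classification,
# composite-recessive detection, oracle equivalence.
# (oracle_keep / random_record_set live in helper-fixtures.R)

trio_ped <- make_trio_ped()

test_that("site QC keeps PASS calls at depth and drops the rest", {
  cfg <- run_config()
  expect_true(site_qc_filter(annotated_site(dp_p = 12L), "FAM1_P", cfg))
  expect_true(site_qc_filter(annotated_site(dp_p = 10L), "FAM1_P", cfg))
  expect_false(site_qc_filter(annotated_site(dp_p = 9L), "FAM1_P", cfg))
  expect_false(site_qc_filter(annotated_site(filter = "LowQual"),
                              "FAM1_P", cfg))
})

test_that("frequency filter applies strict population and cohort bounds", {
  cfg <- run_config()
  mk <- function(af) annotated_site(gnomad_af = af)
  # af 0.004 with 1 internal het carrier -> kept
  expect_true(frequency_filter(mk(0.004), mk(0.004), cfg))
  expect_false(frequency_filter(mk(0.006), mk(0.006), cfg))
  expect_false(frequency_filter(mk(0.005), mk(0.005), cfg))  # strict <
  expect_true(frequency_filter(mk(NA_real_), mk(NA_real_), cfg))

  # internal het carriers: "less than 5" excludes exactly 5
  cohort5 <- annotated_site()
  big_gt <- matrix(1L, 1, 6, dimnames = list(NULL, paste0("X", 1:6)))
  cohort5 <- make_variant_set(cohort5$variants, big_gt)
  expect_false(frequency_filter(annotated_site(), cohort5, cfg))
  cohort4 <- make_variant_set(annotated_site()$variants,
                              matrix(c(1L, 1L, 1L, 1L, 0L), 1, 5,
                                     dimnames = list(NULL, paste0("X", 1:5))))
  expect_true(frequency_filter(annotated_site(), cohort4, cfg))

  # internal hom carriers: "less than 3" excludes exactly 3
  cohort_hom <- make_variant_set(annotated_site()$variants,
                                 matrix(c(2L, 2L, 2L), 1, 3,
                                        dimnames = list(NULL, paste0("X", 1:3))))
  expect_false(frequency_filter(annotated_site(), cohort_hom, cfg))
})

test_that("consequence filter mirrors the published clauses", {
  cfg <- run_config()
  expect_true(consequence_filter(annotated_site(), cfg))
  expect_false(consequence_filter(annotated_site(func_region = "intronic"),
                                  cfg))
  expect_true(consequence_filter(annotated_site(func_region = "splicing"),
                                 cfg))
  expect_false(consequence_filter(
    annotated_site(exonic_consequence = "synonymous"), cfg))
  for (lab in c("Benign", "Likely benign", "Benign/Likely benign")) {
    expect_false(consequence_filter(annotated_site(clinvar_class = lab), cfg))
    expect_false(consequence_filter(annotated_site(intervar_class = lab), cfg))
  }
  # Conflicting is NOT benign; unknown labels are non-benign
  expect_true(consequence_filter(annotated_site(
    clinvar_class = "Conflicting interpretations of pathogenicity"), cfg))
  expect_true(consequence_filter(annotated_site(cadd_phred = NA_real_), cfg))
  expect_false(consequence_filter(annotated_site(cadd_phred = 20), cfg))
  expect_true(consequence_filter(annotated_site(cadd_phred = 20.01), cfg))
})

test_that("gene-list filter requires a listed gene symbol", {
  genes <- rbind(make_gene("G1", ndd_list = TRUE),
                 make_gene("G2", ndd_list = FALSE))
  expect_true(gene_list_filter(annotated_site(gene = "G1"), genes))
  expect_false(gene_list_filter(annotated_site(gene = "G2"), genes))
  expect_false(gene_list_filter(annotated_site(gene = "G3"), genes))
  expect_false(gene_list_filter(annotated_site(gene = NA_character_), genes))
})

test_that("inheritance classification reproduces the pattern definitions", {
  cfg <- run_config()
  lab <- function(vs, ped = trio_ped)
    classify_inheritance(vs, 1L, ped, "FAM1_P", cfg)
  expect_equal(lab(annotated_site(gt_p = 1L, gt_m = 1L, gt_f = 0L)),
               "inherited_maternal")
  expect_equal(lab(annotated_site(gt_p = 1L, gt_m = 0L, gt_f = 1L)),
               "inherited_paternal")
  expect_equal(lab(annotated_site(gt_p = 1L, gt_m = 0L, gt_f = 0L)),
               "de_novo")
  expect_equal(lab(annotated_site(gt_p = 2L, gt_m = 1L, gt_f = 1L)),
               "homozygous_recessive")
  expect_equal(lab(annotated_site(gt_p = 1L, gt_m = 1L, gt_f = 1L)),
               "unknown")
  # X-linked: hemizygous male proband, het mother, hemizygous-ref father
  xsite <- annotated_site(gt_p = 1L, gt_m = 1L, gt_f = 0L, contig = "chrX",
                          ploidy = c(1L, 2L, 1L))
  expect_equal(lab(xsite), "x_linked")
  # in the PAR the autosomal rules apply instead
  cfg_par <- run_config(par_intervals = data.frame(
    contig = "chrX", start = 0L, end = 1000L))
  expect_equal(classify_inheritance(xsite, 1L, trio_ped, "FAM1_P", cfg_par),
               "inherited_maternal")
  # putative de novo: one parent unsequenced, available parent reference
  ped_single <- make_trio_ped(father_seq = FALSE)
  expect_equal(lab(annotated_site(gt_p = 1L, gt_m = 0L, gt_f = 0L),
                   ped_single),
               "putative_de_novo")
  expect_equal(lab(annotated_site(gt_p = 1L, gt_m = 1L, gt_f = 0L),
                   ped_single),
               "inherited_maternal")
  # low-depth parent demotes de novo to unknown
  expect_equal(lab(annotated_site(gt_p = 1L, gt_m = 0L, gt_f = 0L,
                                  dp_f = 5L)),
               "unknown")
})

test_that("composite recessive requires one variant from each parent", {
  base <- data.frame(
    proband_id = "FAM1_P", family_id = "FAM1",
    variant_id = c("v1", "v2", "v3"), gene = c("G1", "G1", "G2"),
    inheritance = c("inherited_maternal", "inherited_paternal",
                    "inherited_maternal"),
    stringsAsFactors = FALSE)
  comp <- detect_composite_recessive(base, trio_ped)
  expect_equal(nrow(comp), 1L)
  expect_equal(comp$gene, "G1")

  cis_only <- base
  cis_only$inheritance <- "inherited_maternal"
  expect_equal(nrow(detect_composite_recessive(cis_only, trio_ped)), 0L)

  # a single sequenced parent makes parental origin unresolvable
  expect_equal(nrow(detect_composite_recessive(
    base, make_trio_ped(father_seq = FALSE))), 0L)
})

test_that("the cascade equals the predicate-conjunction oracle on 500 random records", {
  cfg <- run_config()
  genes <- rbind(make_gene("G1"), make_gene("G2"))  # G3 unlisted
  vs <- random_record_set(500, seed = 99)
  res <- run_short_cascade(vs, trio_ped, vs, genes, cfg)
  expected <- oracle_keep(vs$variants, vs$gt[, "FAM1_P"], vs$dp[, "FAM1_P"],
                          het = rowSums(vs$gt == 1L, na.rm = TRUE),
                          hom = rowSums(vs$gt == 2L, na.rm = TRUE),
                          listed = c("G1", "G2"), cfg)
  expect_setequal(res$variant_id, vs$variants$variant_id[expected])
})

test_that("annotation filters are order-independent pure conjunctions", {
  cfg <- run_config()
  genes <- rbind(make_gene("G1"), make_gene("G2"))
  vs <- random_record_set(200, seed = 7)
  f1 <- frequency_filter(vs, vs, cfg)
  f2 <- consequence_filter(vs, cfg)
  f3 <- gene_list_filter(vs, genes)
  qc <- site_qc_filter(vs, "FAM1_P", cfg)
  expect_identical(qc & f1 & f2 & f3, f3 & f2 & f1 & qc)
  # monotonicity: each stage keeps a subset
  expect_true(all(which(qc & f1) %in% which(qc)))
  expect_true(all(which(qc & f1 & f2) %in% which(qc & f1)))
})

test_that("planted events are recovered exactly on the small cohort", {
  coh <- small_cohort()
  cfg <- pipeline_config(coh$reference)
  res <- run_pipeline(coh, cfg)
  filtered <- res$filtered_shorts
  tr <- coh$truth[coh$truth$variant_type == "short" &
                    coh$truth$class != "secondary_finding", ]
  for (i in seq_len(nrow(tr))) {
    ids <- strsplit(tr$variant_ids[i], ",")[[1]]
    sub <- filtered[filtered$proband_id == tr$proband_id[i] &
                      filtered$variant_id %in% ids, ]
    if (tr$expected_category[i] == "none") {
      expect_equal(nrow(sub), 0L,
                   info = paste("noise survived:", tr$noise_type[i]))
    } else {
      expect_equal(nrow(sub), length(ids), info = tr$class[i])
      expect_true(all(sub$inheritance == tr$expected_label[i]),
                  info = tr$class[i])
    }
  }
})
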