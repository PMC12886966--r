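# Proband-level integration: compound hets, categorization, yield
# status, secondary findings, de novo database matching.

test_that("cross-class compound hets require opposite parental origins", {
  ped <- make_trio_ped()
  shorts <- data.frame(
    proband_id = "FAM1_P", family_id = "FAM1",
    variant_id = c("chr1:150:A:T", "chr1:700:G:C"),
    gene = c("G1", "G2"),
    inheritance = c("inherited_paternal", "inherited_maternal"),
    inheritance_raw = c("inherited_paternal", "inherited_maternal"),
    stringsAsFactors = FALSE)
  svs <- data.frame(
    family_id = "FAM1", proband_id = "FAM1_P", sv_type = "DEL",
    contig = "chr1", start = 80L, end = 320L, length = 240L,
    carriers = "FAM1_M,FAM1_P", supporting_callers = "manta,lumpy",
    population_af = NA_real_, segregation = "inherited_maternal",
    hemizygous = FALSE, genes = "G1", stringsAsFactors = FALSE)
  hits <- detect_cross_class_compound_het(shorts, svs, ped)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$gene, "G1")
  expect_equal(hits$sv_origin, "maternal")
  expect_equal(hits$short_origin, "paternal")

  # both from the mother: no compound
  both_mat <- shorts; both_mat$inheritance_raw <- "inherited_maternal"
  expect_equal(nrow(detect_cross_class_compound_het(both_mat, svs, ped)), 0L)
  # different genes: no compound
  svs2 <- svs; svs2$genes <- "G3"
  expect_equal(nrow(detect_cross_class_compound_het(shorts, svs2, ped)), 0L)
})

test_that("compound-het detection equals a brute-force pair scan on the cohort", {
  res <- default_pipeline()
  coh <- default_cohort()
  sh <- res$filtered_shorts
  sv <- res$filtered_svs
  brute <- list()
  orig <- c(inherited_maternal = "maternal", inherited_paternal = "paternal")
  for (p in unique(sh$proband_id)) {
    a <- sh[sh$proband_id == p & sh$inheritance_raw %in% names(orig), ]
    b <- sv[sv$proband_id == p & sv$segregation %in% names(orig), ]
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      if (!(a$gene[i] %in% strsplit(b$genes[j], ",")[[1]])) next
      if (orig[a$inheritance_raw[i]] == orig[b$segregation[j]]) next
      brute[[length(brute) + 1L]] <- paste(p, a$gene[i], a$variant_id[i])
    }
  }
  got <- paste(res$compound_het$proband_id, res$compound_het$gene,
               res$compound_het$short_variant_id)
  expect_setequal(got, unlist(brute))
  # every planted compound event is found
  planted <- coh$truth[coh$truth$class == "compound_sv_snv", ]
  expect_true(all(planted$proband_id %in% res$compound_het$proband_id))
  expect_true(all(planted$gene %in% res$compound_het$gene))
})

test_that("categorization follows gene status, ACMG class and inheritance", {
  est_ad <- list(established_ndd_gene = TRUE, ndd_list = TRUE,
                 inheritance_mode = "AD")
  est_ar <- list(established_ndd_gene = TRUE, ndd_list = TRUE,
                 inheritance_mode = "AR")
  listed <- list(established_ndd_gene = FALSE, ndd_list = TRUE,
                 inheritance_mode = "unknown")
  unlisted <- list(established_ndd_gene = FALSE, ndd_list = FALSE,
                   inheritance_mode = "unknown")
  expect_equal(categorize_variant(est_ad, "P", "de_novo"), "candidate")
  expect_equal(categorize_variant(est_ar, "P", "composite_recessive"),
               "candidate")
  expect_equal(categorize_variant(est_ar, "P", "inherited_maternal"),
               "none")  # incompatible with recessive mode
  expect_equal(categorize_variant(listed, "VUS", "x_linked"), "suggestive")
  expect_equal(categorize_variant(est_ad, "LB", "de_novo"), "none")
  expect_equal(categorize_variant(unlisted, "P", "de_novo"), "none")
})

test_that("only candidate P/LP/hot-warm VUS variants drive the yield", {
  mk <- function(acmg, category) {
    data.frame(proband_id = "P1", contributes_to_yield =
                 category == "candidate" & acmg %in%
                 c("P", "LP", "VUS_hot", "VUS_warm"))
  }
  expect_equal(proband_status(mk("LP", "candidate")), "positive")
  expect_equal(proband_status(mk("VUS_warm", "candidate")), "positive")
  expect_equal(proband_status(mk("VUS", "candidate")), "negative")
  expect_equal(proband_status(mk("LP", "suggestive")), "negative")
  expect_equal(proband_status(mk("LP", "candidate")[0, ]), "negative")
})

test_that("yield flags and statuses are mutually consistent on the cohort", {
  res <- default_pipeline()
  pr <- res$prioritized
  expect_true(all(pr$category[pr$contributes_to_yield] == "candidate"))
  expect_true(all(pr$acmg_class[pr$contributes_to_yield] %in%
                    c("P", "LP", "VUS_hot", "VUS_warm")))
  # recompute positives independently from the flat table
  pos <- unique(pr$proband_id[pr$contributes_to_yield])
  expect_setequal(res$statuses$proband_id[res$statuses$status == "positive"],
                  pos)
})

test_that("secondary findings respect the zygosity x inheritance-mode rule", {
  genes <- rbind(
    make_gene("SFAD", ndd_list = FALSE, established = FALSE,
              acmg_sf = TRUE, mode = "AD"),
    make_gene("SFAR", contig = "chr2", ndd_list = FALSE, established = FALSE,
              acmg_sf = TRUE, mode = "AR"),
    make_gene("SFXL", contig = "chrX", ndd_list = FALSE, established = FALSE,
              acmg_sf = TRUE, mode = "XL"))
  sites <- data.frame(
    contig = c("chr1", "chr2", "chrX"), pos = c(150L, 150L, 150L),
    ref = "A", alt = "T", filter = "PASS",
    gene = c("SFAD", "SFAR", "SFXL"),
    func_region = "exonic", exonic_consequence = "nonsynonymous",
    gnomad_af = NA_real_, cadd_phred = 30, gerp_rs = NA_real_,
    clinvar_class = c("Pathogenic", "Pathogenic", NA),
    intervar_class = c(NA, NA, "Likely pathogenic"),
    acmg_class = "P", alphamissense_class = NA_character_,
    stringsAsFactors = FALSE)
  samples <- c("MOM", "DAD", "BOY")
  gt <- matrix(c(1L, 0L, 0L,    # SFAD: het in mother -> reported
                 1L, 0L, 0L,    # SFAR: het only -> not reported
                 0L, 0L, 1L),   # SFXL: hemizygous boy -> reported
               3, 3, byrow = TRUE, dimnames = list(NULL, samples))
  pl <- matrix(c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L, 1L), 3, 3, byrow = TRUE,
               dimnames = list(NULL, samples))
  vs <- make_variant_set(sites, gt, ploidy = pl)
  sf <- screen_secondary_findings(vs, genes)
  expect_equal(nrow(sf), 2L)
  expect_setequal(sf$gene, c("SFAD", "SFXL"))
  expect_equal(sf$sample_id[sf$gene == "SFAD"], "MOM")
  expect_equal(sf$trigger_source[sf$gene == "SFAD"], "ClinVar")
  expect_equal(sf$zygosity[sf$gene == "SFXL"], "hemizygous")
  expect_equal(sf$trigger_source[sf$gene == "SFXL"], "InterVar")

  # homozygous P in the AR gene is reported
  gt2 <- gt; gt2[2, "DAD"] <- 2L
  sf2 <- screen_secondary_findings(make_variant_set(sites, gt2, ploidy = pl),
                                   genes)
  expect_true(any(sf2$gene == "SFAR" & sf2$zygosity == "homozygous"))
})

test_that("planted secondary findings are recovered on the cohort", {
  coh <- default_cohort()
  res <- default_pipeline()
  planted <- coh$truth[coh$truth$class == "secondary_finding", ]
  expect_gt(nrow(planted), 0L)
  expect_true(all(planted$variant_ids %in% res$secondary$variant_id))
})

test_that("de novo database matching picks the highest applicable level", {
  genes <- make_gene("G1", exon_start = list(c(100L, 600L)),
                     exon_end = list(c(300L, 900L)))
  db <- data.frame(gene = c("G1", "G1", "G9"), contig = "chr1",
                   pos = c(150L, 650L, 50L), ref = c("A", "G", "C"),
                   alt = c("T", "C", "G"), stringsAsFactors = FALSE)
  q <- data.frame(variant_id = c("a", "b", "c", "d"), contig = "chr1",
                  pos = c(150L, 250L, 700L, 150L), ref = c("A", "C", "T", "A"),
                  alt = c("T", "G", "A", "T"),
                  gene = c("G1", "G1", "G1", "G5"),
                  stringsAsFactors = FALSE)
  out <- match_denovo_db(q, db, genes)
  # a: identical key -> exact; b: same exon as db pos 150 -> exon;
  # c: db hit in the other exon at 650 -> exon too; d: gene absent -> none
  expect_equal(out$denovo_db_match, c("exact", "exon", "exon", "none"))
  # same gene but different exon -> gene-level match
  db2 <- db[db$pos == 150L, , drop = FALSE]
  out2 <- match_denovo_db(q[3, ], db2, genes)
  expect_equal(out2$denovo_db_match, "gene")
})
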