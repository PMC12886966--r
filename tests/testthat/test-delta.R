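# Delta-log-likelihood scoring: window construction, scorer contract,
# strand averaging, ClinVar harmonization/downsampling/contextualization.

ref_seq_chr <- function(ref, contig)
  as.character(ref$sequences[[contig]])

test_that("every window pair has length exactly 8000 over randomized variants", {
  ref <- small_reference()
  set.seed(17)
  n <- 600
  L <- length(ref$sequences[["chr1"]])
  pos <- sample(9000:(L - 9000), n, replace = TRUE)
  cs <- ref_seq_chr(ref, "chr1")
  for (i in seq_len(n)) {
    kind <- sample(c("snv", "del", "ins"), 1)
    p <- pos[i]
    b <- substr(cs, p, p)
    if (kind == "snv") {
      wp <- build_window_pair(ref, "chr1", p, b,
                              sample(setdiff(c("A", "C", "G", "T"), b), 1))
    } else if (kind == "del") {
      d <- sample(1:30, 1)
      wp <- build_window_pair(ref, "chr1", p, substr(cs, p, p + d), b)
    } else {
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:30, 1), TRUE),
                   collapse = "")
      wp <- build_window_pair(ref, "chr1", p, b, paste0(b, ins))
    }
    if (nchar(wp$ref_window) != 8000L || nchar(wp$var_window) != 8000L)
      fail(sprintf("window length drift at %d (%s)", p, kind))
  }
  succeed()
})

test_that("SNV windows differ only at the center anchor", {
  ref <- small_reference()
  cs <- ref_seq_chr(ref, "chr2")
  p <- 30000L
  b <- substr(cs, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  wp <- build_window_pair(ref, "chr2", p, b, alt)
  expect_equal(wp$anchor_offset, 4000L)
  expect_equal(wp$window_shift, 0L)
  diff_at <- which(strsplit(wp$ref_window, "")[[1]] !=
                     strsplit(wp$var_window, "")[[1]])
  expect_equal(diff_at, 4001L)
  expect_equal(substr(wp$var_window, 4001, 4001), alt)
  # ref window spans positions [p-4000, p+3999]
  expect_equal(wp$ref_window, substr(cs, p - 4000, p + 3999))
})

test_that("deletion and insertion windows match hand-built strings", {
  ref <- small_reference()
  cs <- ref_seq_chr(ref, "chr1")
  p <- 40000L
  # 5-bp deletion: bases p+1..p+5 removed, window extended 5 bp downstream
  del_ref <- substr(cs, p, p + 5)
  wp <- build_window_pair(ref, "chr1", p, del_ref, substr(cs, p, p))
  hand <- paste0(substr(cs, p - 4000, p), substr(cs, p + 6, p + 3999 + 5))
  expect_equal(wp$var_window, hand)
  expect_equal(nchar(wp$var_window), 8000L)
  # 3-bp insertion after p; the last 3 window bases are trimmed
  wp2 <- build_window_pair(ref, "chr1", p, substr(cs, p, p),
                           paste0(substr(cs, p, p), "ACG"))
  hand2 <- paste0(substr(cs, p - 4000, p), "ACG", substr(cs, p + 1, p + 3996))
  expect_equal(wp2$var_window, hand2)
  # symmetric extension splits the deletion make-up between both sides
  cfg_sym <- run_config(deletion_extension = "symmetric")
  wp3 <- build_window_pair(ref, "chr1", p, del_ref, substr(cs, p, p),
                           config = cfg_sym)
  hand3 <- paste0(substr(cs, p - 4002, p), substr(cs, p + 6, p + 3999 + 3))
  expect_equal(wp3$var_window, hand3)
})

test_that("windows shift inward at contig edges and record the shift", {
  ref <- small_reference()
  cs <- ref_seq_chr(ref, "chr1")
  p <- 500L
  wp <- build_window_pair(ref, "chr1", p, substr(cs, p, p), "A")
  expect_equal(nchar(wp$ref_window), 8000L)
  expect_equal(wp$window_shift, 4001L - p)
  expect_equal(wp$anchor_offset, p - 1L)
})

test_that("degenerate and malformed variants behave per contract", {
  ref <- small_reference()
  cs <- ref_seq_chr(ref, "chr1")
  b <- substr(cs, 30000, 30000)
  sc <- function(s) -0.5 * nchar(s)  # any deterministic scorer
  d <- delta_score(ref, "chr1", 30000L, b, b, sc)
  expect_identical(d$delta, 0)
  expect_error(build_window_pair(ref, "chr1", 30000L, "AC", "GT"),
               class = "coord_error")
  expect_error(build_window_pair(ref, "nope", 30000L, "A", "T"),
               class = "coord_error")
  # wrong reference allele is caught
  wrong <- setdiff(c("A", "C", "G", "T"), b)[1]
  expect_error(build_window_pair(ref, "chr1", 30000L, wrong, b),
               class = "coord_error")
  # insertion as long as the window is rejected
  too_long <- paste(rep("A", 8000), collapse = "")
  expect_error(build_window_pair(ref, "chr1", 30000L, b,
                                 paste0(b, too_long)),
               class = "coord_error")
})

test_that("the markov scorer is deterministic and accepts N", {
  ref <- small_reference()
  sc <- memo("small_scorer", function() markov_scorer(ref))
  s <- substr(ref_seq_chr(ref, "chr1"), 1000, 1999)
  expect_identical(score_sequence(sc, s), score_sequence(sc, s))
  with_n <- paste0(substr(s, 1, 500), "NNNNN", substr(s, 506, 1000))
  expect_true(is.finite(score_sequence(sc, with_n)))
  expect_true(score_sequence(sc, s) < 0)
  expect_identical(score_sequence(sc, "N"), log(0.25))
})

test_that("strand averaging makes delta invariant to pre-reverse-complementing", {
  ref <- small_reference()
  sc <- memo("small_scorer", function() markov_scorer(ref))
  cs <- ref_seq_chr(ref, "chr3")
  p <- 35000L
  b <- substr(cs, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  wp <- build_window_pair(ref, "chr3", p, b, alt)
  fwd <- function(s) score_sequence(sc, s)
  rc <- nddtrio:::revcomp
  delta_plain <- (fwd(wp$var_window) + fwd(rc(wp$var_window))) / 2 -
    (fwd(wp$ref_window) + fwd(rc(wp$ref_window))) / 2
  delta_swapped <- (fwd(rc(wp$var_window)) + fwd(rc(rc(wp$var_window)))) / 2 -
    (fwd(rc(wp$ref_window)) + fwd(rc(rc(wp$ref_window)))) / 2
  expect_equal(delta_plain, delta_swapped, tolerance = 1e-12)
  d <- delta_score(ref, "chr3", p, b, alt, sc)
  expect_equal(d$delta, d$ll_var - d$ll_ref)
  expect_equal(d$ll_ref, (d$ll_ref_fwd + d$ll_ref_rc) / 2)
})

test_that("k-mer-disrupting variants score well below neutral substitutions", {
  ref <- small_reference()
  sc <- memo("small_scorer", function() markov_scorer(ref))
  pv <- plant_scoring_variants(ref, 120, seed = 9)
  ds <- delta_score_table(pv, ref, sc)
  pv$delta <- ds$delta
  dis <- pv$delta[pv$class == "disruptive"]
  neu <- pv$delta[pv$class == "neutral"]
  expect_lt(mean(dis), mean(neu))
  expect_true(all(dis < 0))
  p <- wilcox.test(dis, neu, alternative = "less")$p.value
  expect_lt(p, 1e-3)
})

test_that("ClinVar labels harmonize exactly and unknowns are rejected", {
  expect_equal(harmonize_clinvar(c("Pathogenic", "Likely pathogenic",
                                   "Pathogenic/Likely pathogenic")),
               rep("P_LP", 3))
  expect_equal(harmonize_clinvar(c("Benign", "Likely benign",
                                   "Benign/Likely benign")),
               rep("B_LB", 3))
  expect_equal(harmonize_clinvar(
    c("Uncertain significance",
      "Conflicting interpretation of pathogenicity")),
    rep("VUS", 2))
  err <- tryCatch(harmonize_clinvar("drug response"), error = identity)
  expect_s3_class(err, "clinvar_error")
  expect_match(conditionMessage(err), "drug response")
})

test_that("per-gene downsampling caps at 450 and always keeps P/LP", {
  set.seed(1)
  recs <- data.frame(
    gene = rep(c("A", "B"), c(1000, 400)),
    harmonized_category = c(rep("P_LP", 100), rep("B_LB", 450),
                            rep("VUS", 450), rep("VUS", 400)),
    id = seq_len(1400), stringsAsFactors = FALSE)
  out <- downsample_gene_set(recs, cap = 450, seed = 5)
  expect_equal(sum(out$gene == "A"), 450L)
  expect_equal(sum(out$gene == "A" & out$harmonized_category == "P_LP"), 100L)
  expect_equal(sum(out$gene == "B"), 400L)  # under the cap: untouched
  out2 <- downsample_gene_set(recs, cap = 450, seed = 5)
  expect_identical(out$id, out2$id)        # seeded determinism
  out3 <- downsample_gene_set(recs, cap = 450, seed = 6)
  expect_false(identical(out$id, out3$id))
  # P/LP alone above the cap: keep all P/LP, drop the rest, warn
  many_p <- data.frame(gene = "C",
                       harmonized_category = c(rep("P_LP", 500),
                                               rep("VUS", 100)),
                       stringsAsFactors = FALSE)
  expect_warning(out4 <- downsample_gene_set(many_p, cap = 450, seed = 1),
                 "P/LP")
  expect_equal(nrow(out4), 500L)
  expect_true(all(out4$harmonized_category == "P_LP"))
})

test_that("contextualization reports percentiles and the median P/LP rule", {
  gd <- data.frame(
    harmonized_category = rep(c("P_LP", "VUS", "B_LB"), each = 5),
    delta = c(-10, -9, -8, -7, -6,  -3, -2.5, -2, -1.5, -1,
              -0.5, -0.4, -0.3, -0.2, -0.1))
  ctx <- contextualize(-12, gd)
  expect_equal(unname(ctx$percentiles["P_LP"]), 0)
  expect_true(ctx$pathogenic_like)
  ctx2 <- contextualize(-0.05, gd)
  expect_equal(unname(ctx2$percentiles["VUS"]), 100)
  expect_false(ctx2$pathogenic_like)
  # exactly at the P/LP median counts as pathogenic-like
  ctx3 <- contextualize(-8, gd)
  expect_true(ctx3$pathogenic_like)
  # no P/LP records: flag undefined
  ctx4 <- contextualize(-5, gd[gd$harmonized_category != "P_LP", ])
  expect_true(is.na(ctx4$pathogenic_like))
})
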