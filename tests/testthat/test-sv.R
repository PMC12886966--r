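# SV pipeline: segment filters, 50-kb merging, multi-caller consensus,
# family merging/segregation, frequency/exon filters, dosage tiers.

seg_row <- function(log2 = -1, p = 1e-8, w = 40, start = 1000L,
                    end = 5000L, sample = "S1", contig = "chr1") {
  data.frame(sample_id = sample, contig = contig, start = start, end = end,
             log2_ratio = log2, p_value = p, weight = w,
             cnv_type = ifelse(log2 > 0, "DUP", "DEL"),
             stringsAsFactors = FALSE)
}

test_that("CNV segment filter applies the log2/p/weight thresholds", {
  cfg <- run_config()
  expect_equal(nrow(filter_cnv_segments(seg_row(0.5, 1e-7, 30), cfg)), 1L)
  expect_equal(nrow(filter_cnv_segments(seg_row(-0.39), cfg)), 0L)
  expect_equal(nrow(filter_cnv_segments(seg_row(0.36), cfg)), 1L)
  expect_equal(nrow(filter_cnv_segments(seg_row(0.35), cfg)), 0L)
  expect_equal(nrow(filter_cnv_segments(seg_row(-1, p = 1e-4), cfg)), 0L)
  expect_equal(nrow(filter_cnv_segments(seg_row(-1, w = 20), cfg)), 0L)
})

test_that("same-type segments closer than 50 kb merge; others do not", {
  two_dels <- rbind(seg_row(start = 1000L, end = 5000L),
                    seg_row(start = 45000L, end = 50000L))  # 40-kb gap
  m <- merge_adjacent_cnvs(two_dels)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 1000L)
  expect_equal(m$end, 50000L)
  far <- rbind(seg_row(start = 1000L, end = 5000L),
               seg_row(start = 65000L, end = 70000L))       # 60-kb gap
  expect_equal(nrow(merge_adjacent_cnvs(far)), 2L)
  mixed <- rbind(seg_row(start = 1000L, end = 5000L, log2 = -1),
                 seg_row(start = 6000L, end = 9000L, log2 = 0.6))
  expect_equal(nrow(merge_adjacent_cnvs(mixed)), 2L)
})

test_that("CNV merging is idempotent and order-independent", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    segs <- do.call(rbind, lapply(seq_len(n), function(i) {
      s <- sample.int(200000L, 1)
      seg_row(log2 = sample(c(-1, 0.6), 1), start = s,
              end = s + sample.int(20000L, 1))
    }))
    m1 <- merge_adjacent_cnvs(segs)
    shuffled <- segs[sample.int(nrow(segs)), ]
    m2 <- merge_adjacent_cnvs(shuffled)
    expect_equal(m1[, c("start", "end", "cnv_type")],
                 m2[, c("start", "end", "cnv_type")])
    again <- m1
    again$log2_ratio <- ifelse(again$cnv_type == "DUP", 0.6, -1)
    again$p_value <- 1e-8; again$weight <- 40
    m3 <- merge_adjacent_cnvs(again)
    expect_equal(m3[, c("start", "end")], m1[, c("start", "end")])
  }
})

sv_call <- function(caller, start = 10000L, end = 20000L, type = "DEL",
                    sample = "S1", af = NA_real_, len = NULL) {
  data.frame(sample_id = sample, caller = caller, sv_type = type,
             contig = "chr1", start = start, end = end,
             length = len %||% (end - start), genotype = 1L,
             population_af = af, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("consensus requires two distinct callers of the same type", {
  cfg <- run_config()
  two <- rbind(sv_call("manta"), sv_call("lumpy"))
  cons <- consensus_sv(two, cfg)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$n_callers, 2L)
  expect_equal(cons$supporting_callers, "lumpy,manta")

  expect_equal(nrow(consensus_sv(sv_call("manta"), cfg)), 0L)
  type_clash <- rbind(sv_call("manta", type = "DEL"),
                      sv_call("lumpy", type = "DUP"))
  expect_equal(nrow(consensus_sv(type_clash, cfg)), 0L)
  # same caller twice is one caller
  expect_equal(nrow(consensus_sv(rbind(sv_call("manta"), sv_call("manta")),
                                 cfg)), 0L)
})

test_that("consensus tolerates breakpoint jitter within 50% reciprocal overlap", {
  cfg <- run_config()
  jittered <- rbind(sv_call("manta", 10000L, 20000L),
                    sv_call("cnvnator", 10020L, 19980L),
                    sv_call("breakdancer", 9980L, 20020L))
  cons <- consensus_sv(jittered, cfg)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$n_callers, 3L)
  # manta-like breakpoints are used when present
  expect_equal(cons$start, 10000L)
  expect_equal(cons$end, 20000L)
  no_manta <- rbind(sv_call("lumpy", 10000L, 20000L),
                    sv_call("cnvnator", 10020L, 19980L))
  expect_equal(consensus_sv(no_manta, cfg)$start,
               as.integer(round(median(c(10000L, 10020L)))))
  # below 50% reciprocal overlap no cluster forms
  apart <- rbind(sv_call("manta", 10000L, 20000L),
                 sv_call("lumpy", 16000L, 26000L))
  expect_equal(nrow(consensus_sv(apart, cfg)), 0L)
})

test_that("the size cap and INS/MEI pass-through rules hold", {
  cfg <- run_config()
  big <- rbind(sv_call("manta", 0L, 600000L), sv_call("lumpy", 0L, 600000L))
  expect_equal(nrow(consensus_sv(big, cfg)), 0L)
  ins <- sv_call("manta", 5000L, 5001L, type = "INS", len = 300L)
  mei <- sv_call("melt", 8000L, 8001L, type = "MEI", len = 6000L)
  stray_ins <- sv_call("lumpy", 5000L, 5001L, type = "INS", len = 300L)
  cons <- consensus_sv(rbind(ins, mei, stray_ins), cfg)
  expect_equal(nrow(cons), 2L)
  expect_setequal(cons$sv_type, c("INS", "MEI"))
})

test_that("family merging derives segregation from the carrier map", {
  cfg <- run_config()
  ped <- make_trio_ped()
  mk <- function(samples, offsets = 0L) {
    do.call(rbind, lapply(seq_along(samples), function(i)
      data.frame(sample_id = samples[i], sv_type = "DEL", contig = "chr1",
                 start = 10000L + offsets[pmin(i, length(offsets))],
                 end = 20000L + offsets[pmin(i, length(offsets))],
                 length = 10000L, supporting_callers = "manta,lumpy",
                 n_callers = 2L, population_af = NA_real_,
                 stringsAsFactors = FALSE)))
  }
  fam <- merge_family_svs(mk(c("FAM1_P", "FAM1_M")), ped, cfg)
  expect_equal(nrow(fam), 1L)
  expect_equal(fam$segregation, "inherited_maternal")
  expect_equal(fam$carriers, "FAM1_M,FAM1_P")

  fam2 <- merge_family_svs(mk("FAM1_P"), ped, cfg)
  expect_equal(fam2$segregation, "de_novo")

  ped_single <- make_trio_ped(father_seq = FALSE)
  fam3 <- merge_family_svs(mk("FAM1_P"), ped_single, cfg)
  expect_equal(fam3$segregation, "putative_de_novo")

  # calls offset by 1.5 kb stay separate records
  fam4 <- merge_family_svs(mk(c("FAM1_P", "FAM1_M"), c(0L, 1500L)), ped, cfg)
  expect_equal(nrow(fam4), 2L)
  expect_setequal(fam4$segregation, c("de_novo", "not_in_proband"))
})

fam_sv <- function(sv_type = "DEL", start = 80L, end = 320L,
                   af = NA_real_, family = "FAM1", proband = "FAM1_P",
                   carriers = "FAM1_M,FAM1_P", seg = "inherited_maternal",
                   hemi = FALSE) {
  data.frame(family_id = family, proband_id = proband, sv_type = sv_type,
             contig = "chr1", start = start, end = end,
             length = max(end - start, 300L), carriers = carriers,
             supporting_callers = "manta,lumpy", population_af = af,
             segregation = seg, hemizygous = hemi, stringsAsFactors = FALSE)
}

test_that("SV filtering enforces exon overlap, rarity and cohort recurrence", {
  cfg <- run_config()
  genes <- make_gene("G1", exon_start = list(c(100L, 600L)),
                     exon_end = list(c(300L, 900L)), phaplo = 0.99)
  kept <- filter_family_svs(fam_sv(af = 0.001), genes, 100, cfg)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$genes, "G1")
  # no exon overlap
  expect_equal(nrow(filter_family_svs(fam_sv(start = 400L, end = 550L),
                                      genes, 100, cfg)), 0L)
  # common SV
  expect_equal(nrow(filter_family_svs(fam_sv(af = 0.02), genes, 100, cfg)),
               0L)
  expect_equal(nrow(filter_family_svs(fam_sv(af = 0.005), genes, 100, cfg)),
               1L)
  # INS distance rule is strict
  ins_near <- fam_sv("INS", start = 85L, end = 86L)   # 14 bp from exon
  expect_equal(nrow(filter_family_svs(ins_near, genes, 100, cfg)), 1L)
  ins_far <- fam_sv("INS", start = 75L, end = 76L)    # 24 bp from exon
  expect_equal(nrow(filter_family_svs(ins_far, genes, 100, cfg)), 0L)
  # recurrence: the same locus in 12 of 100 families is dropped
  rec <- do.call(rbind, lapply(1:12, function(i)
    fam_sv(family = sprintf("F%02d", i), proband = sprintf("F%02d_P", i),
           carriers = sprintf("F%02d_P", i), seg = "de_novo")))
  expect_equal(nrow(filter_family_svs(rec, genes, 100, cfg)), 0L)
  expect_equal(nrow(filter_family_svs(rec[1:9, ], genes, 100, cfg)), 9L)
})

test_that("dosage prioritization matches type-specific thresholds", {
  cfg <- run_config()
  genes <- rbind(
    make_gene("HI", phaplo = 0.99, ptriplo = 0.3, pli = 0.95),
    make_gene("LO", phaplo = 0.54, ptriplo = 0.67, pli = 0.9))
  tier_of <- function(...) {
    sv <- fam_sv(...)
    sv$genes <- sv$genes %||% NULL
    out <- prioritize_dosage(filter_family_svs(sv, genes, 100, cfg),
                             genes, cfg)
    out$tier
  }
  expect_equal(tier_of(seg = "de_novo", carriers = "FAM1_P"), "high")
  expect_equal(tier_of(seg = "inherited_maternal"), "review")
  # boundary: pHaplo threshold is >=, 0.54 fails; pTriplo 0.68 needed
  genes_lo <- make_gene("LO", phaplo = 0.54, ptriplo = 0.67, pli = 0.9)
  sv <- fam_sv(seg = "de_novo", carriers = "FAM1_P")
  out <- prioritize_dosage(filter_family_svs(sv, genes_lo, 100, cfg),
                           genes_lo, cfg)
  expect_equal(out$tier, "review")
  # de novo INS over a gene with pLI above 0.9
  ins <- fam_sv("INS", start = 95L, end = 96L, seg = "de_novo",
                carriers = "FAM1_P")
  genes_pli <- make_gene("G1", pli = 0.95)
  out2 <- prioritize_dosage(filter_family_svs(ins, genes_pli, 100, cfg),
                            genes_pli, cfg)
  expect_equal(out2$tier, "high")
  # hemizygous inherited DEL on a high-pHaplo gene is also prioritized
  hemi <- fam_sv(seg = "inherited_maternal", hemi = TRUE)
  genes_hi <- make_gene("G1", phaplo = 0.8)
  out3 <- prioritize_dosage(filter_family_svs(hemi, genes_hi, 100, cfg),
                            genes_hi, cfg)
  expect_equal(out3$tier, "high")
})

test_that("family merging is idempotent and order-independent", {
  cfg <- run_config()
  ped <- make_trio_ped()
  calls <- do.call(rbind, lapply(list(
    c("FAM1_P", 10000, 20000), c("FAM1_M", 10100, 19900),
    c("FAM1_F", 50000, 60000)), function(x)
      data.frame(sample_id = x[1], sv_type = "DEL", contig = "chr1",
                 start = as.integer(x[2]), end = as.integer(x[3]),
                 length = as.integer(x[3]) - as.integer(x[2]),
                 supporting_callers = "manta,lumpy", n_callers = 2L,
                 population_af = NA_real_, stringsAsFactors = FALSE)))
  m1 <- merge_family_svs(calls, ped, cfg)
  m2 <- merge_family_svs(calls[c(3, 1, 2), ], ped, cfg)
  expect_equal(m1[order(m1$start), c("start", "end", "carriers",
                                     "segregation")],
               m2[order(m2$start), c("start", "end", "carriers",
                                     "segregation")])
})

test_that("consensus recall on the planted cohort is complete at 2+ callers", {
  coh <- small_cohort()
  cfg <- pipeline_config(coh$reference)
  cons <- consensus_sv(coh$sv_calls, cfg)
  planted <- coh$sv_truth[coh$sv_truth$truth_class == "compound_sv_snv", ]
  for (i in seq_len(nrow(planted))) {
    x <- planted[i, ]
    for (carrier in strsplit(x$carriers, ",")[[1]]) {
      hit <- cons$sample_id == carrier & cons$contig == x$contig &
        abs(cons$start - x$start) < 500 & abs(cons$end - x$end) < 500
      expect_equal(sum(hit), 1L)
      expect_gte(cons$n_callers[hit], 2L)
    }
  }
  # single-caller noise never reaches consensus
  noise <- coh$sv_truth[coh$sv_truth$truth_class == "sv_noise_single_caller", ]
  for (i in seq_len(nrow(noise)))
    expect_equal(sum(cons$contig == noise$contig[i] &
                       abs(cons$start - noise$start[i]) < 500 &
                       cons$sv_type == "DEL" & cons$n_callers >= 2), 0L)
})
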