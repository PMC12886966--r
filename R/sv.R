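# Structural-variant prioritization: CNV segment filtering, same-type
# merging, multi-caller consensus, family-level merging with segregation,
# frequency/exon filtering, and dosage-sensitivity prioritization.

#' Filter read-depth CNV segments
#'
#' Keeps segments with (log2 ratio > 0.35 or < -0.4) and p-value < 1e-5
#' and weight > 20 (thresholds configurable); the published filter for
#' separating germline copy-number signal from background noise.
#'
#' @param segments CNV segment data.frame
#'   (\code{\link{read_cnv_segments}}).
#' @param config \code{\link{run_config}}.
#' @return The surviving rows.
#' @export
filter_cnv_segments <- function(segments, config = run_config()) {
  keep <- (segments$log2_ratio > config$cnv_log2_dup |
             segments$log2_ratio < config$cnv_log2_del) &
    segments$p_value < config$cnv_p_max &
    segments$weight > config$cnv_weight_min
  segments[keep, , drop = FALSE]
}

#' Merge nearby same-type CNV segments
#'
#' Coalesces same-sample, same-contig, same-type segments separated by
#' less than \code{gap} bp (default 50 kb) into min-start/max-end merged
#' calls. Different types never merge; the operation is idempotent and
#' input-order independent.
#'
#' @param segments CNV segment data.frame.
#' @param gap merge gap in bp (gaps strictly smaller merge).
#' @return data.frame(sample_id, contig, start, end, cnv_type,
#'   n_segments).
#' @export
merge_adjacent_cnvs <- function(segments, gap = 50000) {
  out <- list()
  if (nrow(segments) > 0L) {
    key <- paste(segments$sample_id, segments$contig, segments$cnv_type,
                 sep = "\r")
    for (k in unique(key)) {
      sub <- segments[key == k, , drop = FALSE]
      r <- IRanges::reduce(to_iranges(sub$start, sub$end),
                           min.gapwidth = gap, with.revmap = TRUE)
      out[[k]] <- data.frame(
        sample_id = sub$sample_id[1], contig = sub$contig[1],
        start = from_iranges_start(r), end = from_iranges_end(r),
        cnv_type = sub$cnv_type[1],
        n_segments = lengths(S4Vectors::mcols(r)$revmap),
        stringsAsFactors = FALSE)
    }
  }
  res <- rbind_df(out) %||%
    empty_df(list(sample_id = character(), contig = character(),
                  start = integer(), end = integer(), cnv_type = character(),
                  n_segments = integer()))
  res <- res[order(res$sample_id, res$contig, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  ifelse(ov <= 0, 0, pmin(ov / (e1 - s1), ov / (e2 - s2)))
}

# Single-linkage clustering of intervals by a pairwise predicate, via
# union-find over candidate overlapping pairs.
cluster_pairs <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs) > 0L) for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, 1L)
}

consensus_coordinates <- function(sub) {
  # manta-like breakpoints when available (split-read precision),
  # else the per-breakpoint median of supporters
  if ("manta" %in% sub$caller) {
    m <- sub[sub$caller == "manta", ][1, ]
    c(start = m$start, end = m$end)
  } else {
    c(start = as.integer(round(stats::median(sub$start))),
      end = as.integer(round(stats::median(sub$end))))
  }
}

#' Build per-sample multi-caller SV consensus
#'
#' Deletions/duplications smaller than \code{config$sv_max_size} are
#' clustered across callers per sample and type by at least 50%
#' reciprocal overlap (single linkage); clusters supported by at least
#' two distinct callers are emitted with manta-preferred consensus
#' coordinates. Insertions pass through from the manta-like caller and
#' mobile element insertions from the melt-like caller, unchanged.
#'
#' @param calls per-caller SV call data.frame
#'   (\code{\link{read_sv_vcf}} rows, any number of callers/samples).
#' @param config \code{\link{run_config}}.
#' @return data.frame(sample_id, sv_type, contig, start, end, length,
#'   supporting_callers, n_callers, population_af).
#' @export
consensus_sv <- function(calls, config = run_config()) {
  proto <- list(sample_id = character(), sv_type = character(),
                contig = character(), start = integer(), end = integer(),
                length = integer(), supporting_callers = character(),
                n_callers = integer(), population_af = numeric())
  if (nrow(calls) == 0L) return(empty_df(proto))
  out <- list()
  cnv <- calls[calls$sv_type %in% c("DEL", "DUP") &
                 calls$length < config$sv_max_size, , drop = FALSE]
  key <- paste(cnv$sample_id, cnv$contig, cnv$sv_type, sep = "\r")
  for (k in unique(key)) {
    sub <- cnv[key == k, , drop = FALSE]
    ir <- to_iranges(sub$start, sub$end)
    hits <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    sel <- qh < sh
    qh <- qh[sel]; sh <- sh[sel]
    ro <- reciprocal_overlap(sub$start[qh], sub$end[qh],
                             sub$start[sh], sub$end[sh])
    good <- ro >= config$reciprocal_overlap
    comp <- cluster_pairs(nrow(sub), cbind(qh[good], sh[good]))
    for (cid in unique(comp)) {
      cl <- sub[comp == cid, , drop = FALSE]
      callers <- sort(unique(cl$caller))
      if (length(callers) < config$consensus_min_callers) next
      co <- consensus_coordinates(cl)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = cl$sample_id[1], sv_type = cl$sv_type[1],
        contig = cl$contig[1], start = unname(co["start"]),
        end = unname(co["end"]), length = unname(co["end"] - co["start"]),
        supporting_callers = paste(callers, collapse = ","),
        n_callers = length(callers),
        population_af = suppressWarnings(
          if (all(is.na(cl$population_af))) NA_real_
          else max(cl$population_af, na.rm = TRUE)),
        stringsAsFactors = FALSE)
    }
  }
  passthrough <- calls[(calls$sv_type == "INS" & calls$caller == "manta") |
                         (calls$sv_type == "MEI" & calls$caller == "melt"), ,
                       drop = FALSE]
  if (nrow(passthrough) > 0L)
    out[[length(out) + 1L]] <- data.frame(
      sample_id = passthrough$sample_id, sv_type = passthrough$sv_type,
      contig = passthrough$contig, start = passthrough$start,
      end = passthrough$end, length = passthrough$length,
      supporting_callers = passthrough$caller, n_callers = 1L,
      population_af = passthrough$population_af, stringsAsFactors = FALSE)
  res <- rbind_df(out) %||% empty_df(proto)
  res <- res[order(res$sample_id, res$contig, res$start, res$sv_type), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# Segregation of a family-level SV from the carrier set, mirroring the
# short-variant inheritance definitions on presence/absence genotypes.
sv_segregation <- function(carriers, ctx) {
  p_in <- ctx$proband %in% carriers
  if (!p_in) return("not_in_proband")
  mo_in <- ctx$mother_seq && ctx$mother %in% carriers
  fa_in <- ctx$father_seq && ctx$father %in% carriers
  if (mo_in && fa_in) return("unknown")
  if (mo_in) return("inherited_maternal")
  if (fa_in) return("inherited_paternal")
  if (ctx$father_seq && ctx$mother_seq) return("de_novo")
  if (xor(ctx$father_seq, ctx$mother_seq)) return("putative_de_novo")
  "unknown"
}

#' Merge per-member consensus SVs to family level
#'
#' Same-type calls from members of one family whose breakpoints both lie
#' within \code{config$family_merge_bp} (default 1000 bp) are merged into
#' a single record carrying per-member presence genotypes; segregation
#' (inherited maternal/paternal, de novo, putative de novo, unknown) is
#' derived from the carrier map per proband, and X-contig calls in male
#' probands are flagged hemizygous.
#'
#' @param consensus per-sample consensus data.frame
#'   (\code{\link{consensus_sv}}); samples from one or more families.
#' @param pedigree pedigree data.frame.
#' @param config \code{\link{run_config}}.
#' @return data.frame(family_id, proband_id, sv_type, contig, start, end,
#'   length, carriers, supporting_callers, population_af, segregation,
#'   hemizygous), one row per (family-level SV, proband).
#' @export
merge_family_svs <- function(consensus, pedigree, config = run_config()) {
  proto <- list(family_id = character(), proband_id = character(),
                sv_type = character(), contig = character(),
                start = integer(), end = integer(), length = integer(),
                carriers = character(), supporting_callers = character(),
                population_af = numeric(), segregation = character(),
                hemizygous = logical())
  if (nrow(consensus) == 0L) return(empty_df(proto))
  fam_of <- stats::setNames(pedigree$family_id, pedigree$sample_id)
  consensus$family_id <- unname(fam_of[consensus$sample_id])
  out <- list()
  key <- paste(consensus$family_id, consensus$contig, consensus$sv_type,
               sep = "\r")
  for (k in unique(key)) {
    sub <- consensus[key == k, , drop = FALSE]
    close <- function(i, j)
      abs(sub$start[i] - sub$start[j]) <= config$family_merge_bp &
      abs(sub$end[i] - sub$end[j]) <= config$family_merge_bp
    pairs <- which(outer(seq_len(nrow(sub)), seq_len(nrow(sub)),
                         function(i, j) i < j & close(i, j)), arr.ind = TRUE)
    comp <- cluster_pairs(nrow(sub), pairs)
    fam <- sub$family_id[1]
    members <- pedigree[pedigree$family_id == fam, ]
    probands <- members$sample_id[members$role == "proband" &
                                    members$sequenced]
    for (cid in unique(comp)) {
      cl <- sub[comp == cid, , drop = FALSE]
      carriers <- sort(unique(cl$sample_id))
      start <- as.integer(round(stats::median(cl$start)))
      end <- as.integer(round(stats::median(cl$end)))
      af <- suppressWarnings(if (all(is.na(cl$population_af))) NA_real_
                             else max(cl$population_af, na.rm = TRUE))
      for (p in probands) {
        ctx <- family_context(pedigree, p)
        seg <- sv_segregation(carriers, ctx)
        hemi <- cl$contig[1] == config$x_contig && p %in% carriers &&
          members$sex[members$sample_id == p] == "M" &&
          !in_par(cl$contig[1], start + 1L, config$par_intervals)
        out[[length(out) + 1L]] <- data.frame(
          family_id = fam, proband_id = p, sv_type = cl$sv_type[1],
          contig = cl$contig[1], start = start, end = end,
          length = if (cl$sv_type[1] %in% c("INS", "MEI"))
            max(cl$length) else end - start,
          carriers = paste(carriers, collapse = ","),
          supporting_callers = paste(sort(unique(unlist(
            strsplit(cl$supporting_callers, ",")))), collapse = ","),
          population_af = af, segregation = seg, hemizygous = hemi,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- rbind_df(out) %||% empty_df(proto)
  res <- res[order(res$family_id, res$contig, res$start, res$proband_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# Distance (bp) from an interval/point to the nearest exon of listed genes
exon_hits <- function(svs, genes, listed_only = TRUE) {
  ex <- gene_exons(genes[!listed_only | genes$ndd_list, , drop = FALSE])
  function(contig, start, end, near = 0L) {
    sub <- ex[ex$contig == contig, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(list(overlap = FALSE, dist = Inf, genes = character()))
    ov <- sub$start < end & sub$end > start
    dist <- ifelse(ov, 0L, pmax(sub$start - end, start - sub$end))
    list(overlap = any(ov), dist = min(dist),
         genes = unique(sub$symbol[ov | dist < near]))
  }
}

#' Frequency, exon-overlap and cohort-recurrence SV filters
#'
#' Keeps deletions/duplications with at least 1 bp of exon overlap in a
#' listed gene, and insertions/MEIs whose breakpoint lies closer than 20
#' bp to such an exon; requires population frequency < 0.01 (missing
#' frequency = rare); drops SVs present in the proband of more than 10%
#' of enrolled families (or more than \code{config$family_count_rule}
#' families when set). Overlapped listed genes are recorded per SV.
#'
#' @param family_svs family-level SV data.frame
#'   (\code{\link{merge_family_svs}}), covering the whole cohort so
#'   recurrence can be assessed.
#' @param genes gene table.
#' @param n_families number of enrolled families in the cohort.
#' @param config \code{\link{run_config}}.
#' @return The surviving rows, with a \code{genes} column added.
#' @export
filter_family_svs <- function(family_svs, genes, n_families,
                              config = run_config()) {
  if (nrow(family_svs) == 0L) {
    family_svs$genes <- character()
    return(family_svs)
  }
  hit <- exon_hits(family_svs, genes)
  in_proband <- mapply(function(p, carr)
    p %in% strsplit(carr, ",")[[1]],
    family_svs$proband_id, family_svs$carriers)
  keep <- logical(nrow(family_svs))
  gene_col <- character(nrow(family_svs))
  for (i in seq_len(nrow(family_svs))) {
    x <- family_svs[i, ]
    h <- hit(x$contig, x$start, x$end,
             near = if (x$sv_type %in% c("INS", "MEI"))
               config$ins_exon_dist else 0L)
    ok_exon <- if (x$sv_type %in% c("DEL", "DUP")) h$overlap
               else h$dist < config$ins_exon_dist
    ok_af <- is.na(x$population_af) || x$population_af < config$sv_af_max
    keep[i] <- ok_exon && ok_af && in_proband[i]
    gene_col[i] <- paste(h$genes, collapse = ",")
  }
  family_svs$genes <- gene_col
  res <- family_svs[keep, , drop = FALSE]
  if (nrow(res) == 0L) return(res)
  # cohort recurrence: cluster retained loci across families with the
  # family-merge distance rule and count distinct families per locus
  key <- paste(res$contig, res$sv_type, sep = "\r")
  drop <- logical(nrow(res))
  limit <- if (!is.na(config$family_count_rule)) config$family_count_rule
           else config$max_family_frac * n_families
  for (k in unique(key)) {
    idx <- which(key == k)
    sub <- res[idx, , drop = FALSE]
    close <- function(i, j)
      abs(sub$start[i] - sub$start[j]) <= config$family_merge_bp &
      abs(sub$end[i] - sub$end[j]) <= config$family_merge_bp
    pairs <- which(outer(seq_len(nrow(sub)), seq_len(nrow(sub)),
                         function(i, j) i < j & close(i, j)), arr.ind = TRUE)
    comp <- cluster_pairs(nrow(sub), pairs)
    for (cid in unique(comp)) {
      fams <- unique(sub$family_id[comp == cid])
      if (length(fams) > limit) drop[idx[comp == cid]] <- TRUE
    }
  }
  res <- res[!drop, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Prioritize filtered SVs by dosage sensitivity
#'
#' Tier "high": de novo or hemizygous SVs whose overlapped listed genes
#' meet the matching dosage threshold (pHaplo >= 0.55 for deletions,
#' pTriplo >= 0.68 for duplications, pLI > 0.9 for insertions and MEIs)
#' on at least one gene. Everything else that survived filtering stays in
#' tier "review" (lower-dosage-sensitivity calls were still evaluated in
#' the published workflow).
#'
#' @param filtered_svs output of \code{\link{filter_family_svs}}.
#' @param genes gene table.
#' @param config \code{\link{run_config}}.
#' @return The input with a \code{tier} column.
#' @export
prioritize_dosage <- function(filtered_svs, genes, config = run_config()) {
  if (nrow(filtered_svs) == 0L) {
    filtered_svs$tier <- character()
    return(filtered_svs)
  }
  score_of <- function(symbols, col) {
    v <- genes[[col]][match(symbols, genes$symbol)]
    v[!is.na(v)]
  }
  tier <- character(nrow(filtered_svs))
  for (i in seq_len(nrow(filtered_svs))) {
    x <- filtered_svs[i, ]
    eligible <- x$segregation == "de_novo" || isTRUE(x$hemizygous)
    gs <- strsplit(x$genes, ",")[[1]]
    meets <- switch(x$sv_type,
      DEL = any(score_of(gs, "phaplo") >= config$phaplo_min),
      DUP = any(score_of(gs, "ptriplo") >= config$ptriplo_min),
      any(score_of(gs, "pli") > config$pli_min))
    tier[i] <- if (eligible && isTRUE(meets)) "high" else "review"
  }
  filtered_svs$tier <- tier
  filtered_svs
}
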