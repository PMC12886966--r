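# Variant-window delta-log-likelihood protocol.
#
# For each short variant an 8000-bp window centered on the variant
# position is extracted from the reference, a matched variant window is
# built (SNV substitution at the center; deletions remove the segment
# after the anchor and extend downstream to keep the length; insertions
# add bases after the anchor and trim the window end), both windows and
# their reverse complements are scored with a pluggable sequence scorer,
# strand scores are averaged, and delta = ll(variant) - ll(reference).
# Negative deltas mean the variant makes the sequence less probable
# under the model.

BASE_CODE <- {
  lk <- rep(NA_integer_, 128)
  lk[utf8ToInt("A")] <- 1L; lk[utf8ToInt("C")] <- 2L
  lk[utf8ToInt("G")] <- 3L; lk[utf8ToInt("T")] <- 4L
  lk
}

encode_bases <- function(seq) BASE_CODE[utf8ToInt(toupper(seq))]

revcomp <- function(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

# Scorer contract: an object for which score_sequence() returns the total
# log-likelihood of a sequence over {A,C,G,T,N}; deterministic; defined
# for any length >= 1. Plain functions seq -> loglik also satisfy it.
score_seq <- function(scorer, seq) {
  if (is.function(scorer)) scorer(seq) else score_sequence(scorer, seq)
}

#' Score a sequence with a sequence scorer
#' @param scorer a scorer object (e.g. \code{\link{markov_scorer}}).
#' @param seq nucleotide string over A/C/G/T/N.
#' @return Total log-likelihood (numeric scalar).
#' @export
score_sequence <- function(scorer, seq) UseMethod("score_sequence", scorer)

#' Fit a k-mer Markov sequence scorer on a reference
#'
#' An order-\code{order} Markov chain with add-one smoothing over all
#' (order+1)-mers of the reference contigs. Positions whose context runs
#' off the sequence start, or whose (order+1)-mer contains N, score as
#' uniform (log 1/4). Deterministic by construction; serves as the
#' default mock scorer behind the scorer contract (a trained genomic
#' language model plugs in through the same contract).
#'
#' @param reference \code{DNAStringSet} or \code{ndd_reference}.
#' @param order Markov order (default 5, i.e. 6-mer statistics).
#' @return An object of class \code{markov_scorer}.
#' @export
markov_scorer <- function(reference, order = 5L) {
  if (inherits(reference, "ndd_reference")) reference <- reference$sequences
  k <- order + 1L
  n_ctx <- 4L^order
  counts <- numeric(n_ctx * 4L)
  pow <- 4L^((k - 1L):0L)
  for (i in seq_along(reference)) {
    b <- encode_bases(as.character(reference[[i]])) - 1L
    L <- length(b)
    if (L < k) next
    idx <- numeric(L - k + 1L)
    ok <- rep(TRUE, L - k + 1L)
    for (j in seq_len(k)) {
      bj <- b[j:(L - k + j)]
      ok <- ok & !is.na(bj)
      idx <- idx + ifelse(is.na(bj), 0, bj) * pow[j]
    }
    tab <- tabulate(idx[ok] + 1L, nbins = n_ctx * 4L)
    counts <- counts + tab
  }
  kmat <- matrix(counts, nrow = n_ctx, ncol = 4L, byrow = TRUE)
  ctx_tot <- rowSums(kmat)
  logp <- log(kmat + 1) - log(ctx_tot + 4)
  structure(list(order = as.integer(order), logp = logp),
            class = "markov_scorer")
}

#' @export
print.markov_scorer <- function(x, ...) {
  cat(sprintf("<markov_scorer> order %d (%d contexts)\n", x$order,
              nrow(x$logp)))
  invisible(x)
}

#' @export
score_sequence.markov_scorer <- function(scorer, seq) {
  b <- encode_bases(seq)
  L <- length(b)
  if (L < 1L) ndd_stop("cannot score an empty sequence", "scorer_error")
  ord <- scorer$order
  unif <- log(0.25)
  if (L <= ord) return(L * unif)
  head_ll <- ord * unif
  b0 <- b - 1L
  pow <- 4L^((ord - 1L):0L)
  n <- L - ord
  ctx <- numeric(n)
  ok <- rep(TRUE, n)
  for (j in seq_len(ord)) {
    bj <- b0[j:(n + j - 1L)]
    ok <- ok & !is.na(bj)
    ctx <- ctx + ifelse(is.na(bj), 0, bj) * pow[j]
  }
  nxt <- b[(ord + 1L):L]
  ok <- ok & !is.na(nxt)
  ll <- rep(unif, n)
  ll[ok] <- scorer$logp[cbind(ctx[ok] + 1L, nxt[ok])]
  head_ll + sum(ll)
}

get_sequences <- function(reference) {
  if (inherits(reference, "ndd_reference")) reference$sequences else reference
}

#' Build the reference/variant window pair for a variant
#'
#' @param reference \code{DNAStringSet} or \code{ndd_reference}.
#' @param contig,pos,ref,alt the variant (1-based position, VCF-style
#'   left-anchored alleles: SNVs are 1/1 bp, deletions R+seq/R,
#'   insertions R/R+seq).
#' @param window window length in bp (default 8000).
#' @param config \code{\link{run_config}} (deletion extension side).
#' @return list(ref_window, var_window, window_shift, anchor_offset)
#'   with both windows of length exactly \code{window}.
#' @export
build_window_pair <- function(reference, contig, pos, ref, alt,
                              window = 8000L, config = run_config()) {
  seqs <- get_sequences(reference)
  if (!(contig %in% names(seqs)))
    ndd_stop(paste("unknown contig:", contig), "coord_error")
  cseq <- seqs[[contig]]
  clen <- length(cseq)
  if (clen < window) ndd_stop("contig shorter than the window", "coord_error")
  W <- as.integer(window)
  half <- W %/% 2L
  sub <- function(s, e) toupper(as.character(Biostrings::subseq(cseq, s, e)))
  start1 <- pos - half             # 1-based window start; anchor offset half
  shift <- 0L
  if (start1 < 1L) shift <- 1L - start1
  if (start1 + shift + W - 1L > clen) shift <- clen - W + 1L - start1
  start1 <- start1 + shift
  end1 <- start1 + W - 1L
  a <- pos - start1 + 1L           # anchor index within the window
  ref_window <- sub(start1, end1)
  nref <- nchar(ref); nalt <- nchar(alt)
  if (substr(ref_window, a, a + nref - 1L) != toupper(ref))
    ndd_stop(sprintf("reference allele mismatch at %s:%d", contig, pos),
             "coord_error")
  if (nref == nalt && nref == 1L) {
    var_window <- ref_window
    substr(var_window, a, a) <- toupper(alt)
  } else if (nref > 1L && nalt == 1L) {
    d <- nref - 1L                 # deletion of d bases after the anchor
    if (config$deletion_extension == "symmetric") {
      dl <- d %/% 2L; dr <- d - dl
      if (start1 - dl < 1L || end1 + dr > clen)
        ndd_stop("deletion window extension overruns the contig",
                 "coord_error")
      var_window <- paste0(sub(start1 - dl, start1 - 1L),
                           substr(ref_window, 1L, a),
                           sub(pos + d + 1L, end1 + dr))
    } else {
      if (end1 + d > clen)
        ndd_stop("deletion window extension overruns the contig",
                 "coord_error")
      var_window <- paste0(substr(ref_window, 1L, a),
                           sub(pos + d + 1L, end1 + d))
    }
  } else if (nalt > 1L && nref == 1L) {
    d <- nalt - 1L                 # insertion of d bases after the anchor
    if (d >= W)
      ndd_stop("insertion length must be smaller than the window",
               "coord_error")
    var_window <- paste0(substr(ref_window, 1L, a),
                         substr(toupper(alt), 2L, nalt),
                         substr(ref_window, a + 1L, W - d))
  } else {
    ndd_stop("unsupported allele pair (not SNV, simple del or simple ins)",
             "coord_error")
  }
  if (nchar(var_window) != W)
    ndd_stop("internal error: variant window length drift", "coord_error")
  list(ref_window = ref_window, var_window = var_window,
       window_shift = as.integer(shift), anchor_offset = a - 1L)
}

#' Delta log-likelihood score of a variant
#'
#' Scores the reference and variant windows and their reverse
#' complements, averages the two strands for each, and reports
#' delta = ll_var - ll_ref.
#'
#' @inheritParams build_window_pair
#' @param scorer a scorer object or function (see
#'   \code{\link{markov_scorer}}).
#' @return One-row data.frame: variant_id, ll_ref_fwd, ll_ref_rc,
#'   ll_var_fwd, ll_var_rc, ll_ref, ll_var, delta, window_shift.
#' @export
delta_score <- function(reference, contig, pos, ref, alt, scorer,
                        window = 8000L, config = run_config()) {
  wp <- build_window_pair(reference, contig, pos, ref, alt, window, config)
  vid <- variant_key(contig, pos, toupper(ref), toupper(alt))
  sc <- function(s) tryCatch(score_seq(scorer, s), error = function(e)
    ndd_stop(sprintf("scorer failed for %s: %s", vid, conditionMessage(e)),
             "scorer_error"))
  ll_ref_fwd <- sc(wp$ref_window)
  ll_ref_rc <- sc(revcomp(wp$ref_window))
  ll_var_fwd <- sc(wp$var_window)
  ll_var_rc <- sc(revcomp(wp$var_window))
  ll_ref <- (ll_ref_fwd + ll_ref_rc) / 2
  ll_var <- (ll_var_fwd + ll_var_rc) / 2
  data.frame(variant_id = vid, ll_ref_fwd = ll_ref_fwd, ll_ref_rc = ll_ref_rc,
             ll_var_fwd = ll_var_fwd, ll_var_rc = ll_var_rc,
             ll_ref = ll_ref, ll_var = ll_var, delta = ll_var - ll_ref,
             window_shift = wp$window_shift, stringsAsFactors = FALSE)
}

#' Delta scores for a table of variants
#'
#' @param variants data.frame with contig, pos, ref, alt columns.
#' @inheritParams delta_score
#' @return data.frame with one \code{\link{delta_score}} row per variant.
#' @export
delta_score_table <- function(variants, reference, scorer, window = 8000L,
                              config = run_config()) {
  rows <- lapply(seq_len(nrow(variants)), function(i)
    delta_score(reference, variants$contig[i], variants$pos[i],
                variants$ref[i], variants$alt[i], scorer, window, config))
  rbind_df(rows) %||%
    empty_df(list(variant_id = character(), ll_ref_fwd = numeric(),
                  ll_ref_rc = numeric(), ll_var_fwd = numeric(),
                  ll_var_rc = numeric(), ll_ref = numeric(),
                  ll_var = numeric(), delta = numeric(),
                  window_shift = integer()))
}

CLINVAR_MAP <- c(
  "Pathogenic" = "P_LP",
  "Likely pathogenic" = "P_LP",
  "Pathogenic/Likely pathogenic" = "P_LP",
  "Benign" = "B_LB",
  "Likely benign" = "B_LB",
  "Benign/Likely benign" = "B_LB",
  "Uncertain significance" = "VUS",
  "Conflicting interpretation of pathogenicity" = "VUS")

#' Harmonize raw ClinVar clinical-significance labels
#'
#' Maps the standard label set onto three categories: P_LP, B_LB, VUS
#' (conflicting interpretations count as uncertain). Unknown labels are
#' rejected with an error naming them.
#'
#' @param raw character vector of raw labels.
#' @return Character vector of harmonized categories.
#' @export
harmonize_clinvar <- function(raw) {
  out <- CLINVAR_MAP[raw]
  if (anyNA(out))
    ndd_stop(paste("unrecognized ClinVar label(s):",
                   paste(unique(raw[is.na(out)]), collapse = "; ")),
             "clinvar_error")
  unname(out)
}

#' Downsample ClinVar records per gene to a cap
#'
#' All P_LP records are always kept; when a gene holds more than
#' \code{cap} records, B_LB and VUS records are randomly subsampled
#' (seeded) so the gene totals exactly \code{cap}. Genes at or under the
#' cap are untouched. If P_LP alone exceeds the cap, all P_LP are kept,
#' the rest dropped, with a warning.
#'
#' @param records data.frame with gene and harmonized_category columns.
#' @param cap per-gene record cap (default 450).
#' @param seed integer RNG seed.
#' @return The downsampled data.frame.
#' @export
downsample_gene_set <- function(records, cap = 450L, seed = 1L) {
  set.seed(as.integer(seed))
  keep <- logical(nrow(records))
  for (g in sort(unique(records$gene))) {
    idx <- which(records$gene == g)
    if (length(idx) <= cap) { keep[idx] <- TRUE; next }
    plp <- idx[records$harmonized_category[idx] == "P_LP"]
    rest <- setdiff(idx, plp)
    keep[plp] <- TRUE
    room <- cap - length(plp)
    if (room < 0L) {
      warning(sprintf("gene %s: %d P/LP records exceed the cap of %d; %s",
                      g, length(plp), cap,
                      "keeping all P/LP and dropping the rest"))
      room <- 0L
    }
    if (room > 0L && length(rest) > 0L)
      keep[rest[sample.int(length(rest), min(room, length(rest)))]] <- TRUE
  }
  records[keep, , drop = FALSE]
}

#' Contextualize a variant's delta score against a gene's ClinVar deltas
#'
#' Reports the empirical percentile of \code{delta} within each
#' harmonized category's delta distribution for the gene, plus a
#' pathogenic-like flag: TRUE iff the delta is at or below the median of
#' the gene's P_LP deltas. The median rule is this package's numeric
#' operationalization of "comparable to P/LP"; when the gene has no
#' scored P_LP record the flag is NA (undefined) and reported as such.
#'
#' @param delta the variant's delta score.
#' @param gene_deltas data.frame with harmonized_category and delta
#'   columns for the gene's ClinVar records.
#' @return list(percentiles = named numeric (percent within each present
#'   category), pathogenic_like = logical or NA).
#' @export
contextualize <- function(delta, gene_deltas) {
  cats <- c("P_LP", "B_LB", "VUS")
  pct <- stats::setNames(rep(NA_real_, length(cats)), cats)
  for (cat in cats) {
    d <- gene_deltas$delta[gene_deltas$harmonized_category == cat]
    if (length(d) > 0L) pct[cat] <- 100 * mean(d <= delta)
  }
  plp <- gene_deltas$delta[gene_deltas$harmonized_category == "P_LP"]
  flag <- if (length(plp) == 0L) NA else delta <= stats::median(plp)
  list(percentiles = pct, pathogenic_like = flag)
}
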