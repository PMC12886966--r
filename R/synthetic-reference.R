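# Synthetic reference genome + gene model generator.
#
# Sequences are drawn from an order-2 Markov chain with strongly biased
# transitions (two favored bases per dinucleotide context). This gives the
# reference a non-trivial k-mer composition, so that a k-mer model fitted
# on it assigns clearly different likelihoods to substitutions that respect
# versus disrupt the favored k-mer spectrum - the property the delta-score
# separation analysis relies on.

BASES <- c("A", "C", "G", "T")

#' Synthetic cohort simulation configuration
#'
#' Defaults emulate the published study cohort: 100 families, 10 of them
#' multiplex quads with two affected probands (110 probands in total), 10
#' trio probands with a single sequenced parent and 2 with none (298
#' sequenced individuals), 71% male probands. Planted event counts follow
#' the study's filtered-variant segregation table where reported (37 de
#' novo, 33 X-linked, 5 homozygous recessive, 6 cross-class compound
#' SV+SNV probands); composite-recessive, inherited-candidate and
#' benign-noise counts are desk-scale choices. Single-copy CNVs target
#' log2 ratios of -1.0 (deletion) and +0.585 (duplication), comfortably
#' beyond the segment filters at the default noise level.
#'
#' @param ... named overrides.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_families = 100,
    n_quad_families = 10,        # two affected probands each
    n_single_parent = 10,        # trio families with one sequenced parent
    n_no_parent = 1,             # quad families with no sequenced parent
    p_male = 0.71,
    group_fractions = c(ASD = 40 / 110, ID = 27 / 110, `ASD-ID` = 43 / 110),
    n_common_snps = 300,
    maf_range = c(0.05, 0.5),
    events = c(de_novo = 37, x_linked = 33, hom_recessive = 5,
               composite_recessive = 6, compound_sv_snv = 6,
               inherited_candidate = 20, benign_noise = 30),
    n_sv_noise = 10,
    n_ins = 2,
    n_mei = 2,
    n_secondary = 3,
    caller_sensitivity = c(manta = 1, cnvnator = 1, breakdancer = 1,
                           lumpy = 1, melt = 1),
    jitter_sd = 20,
    cnv_log2_del = -1.0,
    cnv_log2_dup = 0.585,
    cnv_log2_sd = 0.05,
    genotype_error_rate = 0,
    mean_depth = 35,
    autosomes = c(chr1 = 300000L, chr2 = 300000L, chr3 = 300000L),
    x_contig = "chrX",
    x_length = 200000L,
    n_genes_autosome = 140,
    n_genes_x = 40,
    par_x = c(0L, 5000L),        # pseudoautosomal head of the X contig
    seed = 1L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0L)
    ndd_stop(paste("unknown sim_config field(s):",
                   paste(unknown, collapse = ", ")), "config_error")
  cfg[names(override)] <- override
  if (is.null(cfg$seed) || is.na(cfg$seed))
    ndd_stop("sim_config requires a seed", "config_error")
  probs <- c(cfg$p_male, cfg$group_fractions, cfg$caller_sensitivity)
  if (any(probs < 0 | probs > 1))
    ndd_stop("probabilities must lie in [0,1]", "config_error")
  structure(cfg, class = "sim_config")
}

# Biased order-2 transition matrix: per 16 contexts, two favored bases at
# 0.49, the others at 0.01.
make_transition_matrix <- function() {
  trans <- matrix(0.01, nrow = 16, ncol = 4,
                  dimnames = list(NULL, BASES))
  for (ctx in 1:16) {
    fav <- ((ctx - 1L + c(0L, 2L)) %% 4L) + 1L  # deterministic favored pair
    trans[ctx, fav] <- 0.49
  }
  trans
}

markov_context <- function(b2, b1) (b2 - 1L) * 4L + b1  # bases as 1..4

generate_markov_sequence <- function(len, trans) {
  cum <- t(apply(trans, 1, cumsum))
  u <- stats::runif(len)
  b <- integer(len)
  b[1] <- sample.int(4L, 1L)
  b[2] <- sample.int(4L, 1L)
  for (i in 3:len) {
    ctx <- markov_context(b[i - 2L], b[i - 1L])
    cc <- cum[ctx, ]
    b[i] <- 1L + (u[i] > cc[1L]) + (u[i] > cc[2L]) + (u[i] > cc[3L])
  }
  b
}

# Lay out n genes along a contig; returns per-gene exon interval lists
# (half-open 0-based). Errors if the contig cannot host the quota.
layout_genes <- function(contig, contig_len, n, margin = 12000L) {
  pos <- margin
  genes <- vector("list", n)
  for (g in seq_len(n)) {
    n_ex <- sample(2:5, 1L)
    ex_len <- sample(150:300, n_ex, replace = TRUE)
    introns <- if (n_ex > 1L) sample(200:500, n_ex - 1L, replace = TRUE) else integer()
    starts <- integer(n_ex)
    ends <- integer(n_ex)
    p <- pos
    for (k in seq_len(n_ex)) {
      starts[k] <- p
      ends[k] <- p + ex_len[k]
      p <- ends[k] + if (k < n_ex) introns[k] else 0L
    }
    if (p > contig_len - margin)
      ndd_stop(sprintf("contig %s too short for %d genes", contig, n),
               "config_error")
    genes[[g]] <- list(start = starts, end = ends)
    pos <- p + sample(500:1500, 1L)
  }
  genes
}

#' Generate the synthetic reference and gene table
#'
#' Produces three autosome-like contigs and one X-like contig (all far
#' longer than two scoring windows), a multi-exon gene model with dosage
#' scores spanning both sides of the prioritization thresholds, gene-list
#' and ACMG secondary-findings flags, and per-gene inheritance modes. The
#' order-2 transition matrix used to draw the sequence is kept on the
#' object so variants that respect or disrupt the generating k-mer
#' distribution can be planted later.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer; overrides \code{config$seed} when given.
#' @return An object of class \code{ndd_reference}: list(sequences
#'   (DNAStringSet), genes, transition, x_contig, par_intervals).
#' @export
generate_reference <- function(config = sim_config(), seed = NULL) {
  seed <- as.integer(seed %||% config$seed)
  contig_lengths <- c(config$autosomes,
                      stats::setNames(as.integer(config$x_length),
                                      config$x_contig))
  if (any(contig_lengths < 2L * 8000L + 1L))
    ndd_stop("contigs must be at least 16001 bp for delta-score windows",
             "config_error")
  set.seed(seed)
  trans <- make_transition_matrix()
  seqs <- lapply(contig_lengths, function(L)
    paste(BASES[generate_markov_sequence(L, trans)], collapse = ""))
  sequences <- Biostrings::DNAStringSet(unlist(seqs))
  names(sequences) <- names(contig_lengths)

  # ---- gene layout ----------------------------------------------------
  auto_names <- names(config$autosomes)
  per_auto <- diff(round(seq(0, config$n_genes_autosome,
                             length.out = length(auto_names) + 1L)))
  gene_rows <- list()
  gi <- 0L
  for (ci in seq_along(auto_names)) {
    lay <- layout_genes(auto_names[ci], config$autosomes[ci], per_auto[ci])
    for (g in lay) {
      gi <- gi + 1L
      gene_rows[[gi]] <- data.frame(symbol = sprintf("GENE%03d", gi),
                                    contig = auto_names[ci],
                                    stringsAsFactors = FALSE)
      gene_rows[[gi]]$exon_start <- list(g$start)
      gene_rows[[gi]]$exon_end <- list(g$end)
    }
  }
  layx <- layout_genes(config$x_contig, config$x_length, config$n_genes_x,
                       margin = max(12000L, config$par_x[2]))
  for (g in layx) {
    gi <- gi + 1L
    gene_rows[[gi]] <- data.frame(symbol = sprintf("GENE%03d", gi),
                                  contig = config$x_contig,
                                  stringsAsFactors = FALSE)
    gene_rows[[gi]]$exon_start <- list(g$start)
    gene_rows[[gi]]$exon_end <- list(g$end)
  }
  genes <- do.call(rbind, gene_rows)
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)

  # ---- gene classes ---------------------------------------------------
  n_auto <- config$n_genes_autosome
  is_x <- genes$contig == config$x_contig
  auto_idx <- sample(which(!is_x))  # shuffle class assignment over position
  x_idx <- sample(which(is_x))
  cls <- rep(NA_character_, nrow(genes))
  take <- function(idx, n) { out <- idx[seq_len(n)]; out }
  # autosomal quotas: ~43% established AD, ~17% established AR, ~32%
  # listed-only, a few ACMG-SF genes outside the NDD list, rest unlisted
  n_ad <- min(round(0.43 * n_auto), n_auto); rest <- auto_idx
  cls[take(rest, n_ad)] <- "est_AD"; rest <- rest[-seq_len(n_ad)]
  n_ar <- min(round(0.17 * n_auto), length(rest))
  cls[take(rest, n_ar)] <- "est_AR"; rest <- rest[-seq_len(n_ar)]
  n_sg <- min(round(0.32 * n_auto), length(rest))
  cls[take(rest, n_sg)] <- "listed_only"; rest <- rest[-seq_len(n_sg)]
  n_sf <- min(max(2L, round(0.035 * n_auto)), length(rest))
  cls[take(rest, n_sf)] <- "acmg_sf"; rest <- rest[-seq_len(n_sf)]
  cls[rest] <- "unlisted"
  # X: ~90% established XL, rest listed-only
  n_xl <- min(round(0.9 * length(x_idx)), length(x_idx))
  cls[take(x_idx, n_xl)] <- "est_XL"
  if (n_xl < length(x_idx)) cls[x_idx[-seq_len(n_xl)]] <- "listed_only"
  genes$sim_class <- cls

  genes$ndd_list <- cls %in% c("est_AD", "est_AR", "est_XL", "listed_only")
  genes$established_ndd_gene <- cls %in% c("est_AD", "est_AR", "est_XL")
  genes$acmg_sf_gene <- cls == "acmg_sf"
  genes$inheritance_mode <- ifelse(cls == "est_AD", "AD",
                            ifelse(cls == "est_AR", "AR",
                            ifelse(cls == "est_XL", "XL",
                            ifelse(cls == "acmg_sf",
                                   sample(c("AD", "AR"), nrow(genes),
                                          replace = TRUE), "unknown"))))
  # dosage-sensitivity scores straddling the prioritization thresholds
  genes$phaplo <- round(stats::runif(nrow(genes)), 3)
  genes$ptriplo <- round(stats::runif(nrow(genes)), 3)
  genes$pli <- round(stats::runif(nrow(genes)), 3)

  cols <- c("symbol", "contig", "strand", "pli", "phaplo", "ptriplo",
            "ndd_list", "established_ndd_gene", "acmg_sf_gene",
            "inheritance_mode", "sim_class", "exon_start", "exon_end")
  genes <- genes[, cols]
  par_intervals <- data.frame(contig = config$x_contig,
                              start = as.integer(config$par_x[1]),
                              end = as.integer(config$par_x[2]),
                              stringsAsFactors = FALSE)
  structure(list(sequences = sequences, genes = genes, transition = trans,
                 x_contig = config$x_contig, par_intervals = par_intervals,
                 seed = seed),
            class = "ndd_reference")
}

#' @export
print.ndd_reference <- function(x, ...) {
  cat(sprintf("<ndd_reference> %d contig(s), %d gene(s)\n",
              length(x$sequences), nrow(x$genes)))
  invisible(x)
}

#' Write reference FASTA and gene table to a directory
#' @param reference an \code{ndd_reference}.
#' @param dir output directory (created if absent).
#' @return Named list of written paths.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(reference$sequences, fa, width = 80L)
  gt <- file.path(dir, "genes.tsv")
  write_gene_table(reference$genes, gt)
  list(fasta = fa, genes = gt)
}

# Base at 1-based position of a contig
ref_base <- function(reference, contig, pos) {
  substr(as.character(reference$sequences[[contig]]), pos, pos)
}

#' Plant neutral and k-mer-disrupting substitutions
#'
#' Draws SNV positions on the autosome-like contigs and assigns two ALT
#' choices per position using the generating transition matrix: a
#' "neutral" substitution (the alternative favored base in that
#' dinucleotide context) and a "disruptive" one (a minimum-probability
#' base, creating k-mers the reference rarely or never contains). Used to
#' study the delta-score separation between pathogenic-like and neutral
#' variants under a scorer fitted on the reference.
#'
#' @param reference an \code{ndd_reference}.
#' @param n number of positions per class.
#' @param seed integer RNG seed.
#' @return data.frame(contig, pos, ref, alt, class).
#' @export
plant_scoring_variants <- function(reference, n, seed = 1L) {
  set.seed(as.integer(seed))
  autos <- setdiff(names(reference$sequences), reference$x_contig)
  lens <- Biostrings::width(reference$sequences[autos])
  contig <- sample(autos, n, replace = TRUE, prob = lens / sum(lens))
  pos <- integer(n)
  for (i in seq_len(n)) {
    L <- length(reference$sequences[[contig[i]]])
    pos[i] <- sample(8101:(L - 8100L), 1L)
  }
  seqs <- vapply(seq_len(n), function(i)
    substr(as.character(reference$sequences[[contig[i]]]),
           pos[i] - 2L, pos[i]), "")
  b2 <- match(substr(seqs, 1, 1), BASES)
  b1 <- match(substr(seqs, 2, 2), BASES)
  refb <- substr(seqs, 3, 3)
  ctx <- markov_context(b2, b1)
  neutral <- character(n); disruptive <- character(n)
  for (i in seq_len(n)) {
    p <- reference$transition[ctx[i], ]
    ri <- match(refb[i], BASES)
    pn <- p; pn[ri] <- -Inf   # never pick the reference base
    neutral[i] <- BASES[which.max(pn)]
    pd <- p; pd[ri] <- Inf
    disruptive[i] <- BASES[which.min(pd)]
  }
  rbind(
    data.frame(contig = contig, pos = pos, ref = refb, alt = neutral,
               class = "neutral", stringsAsFactors = FALSE),
    data.frame(contig = contig, pos = pos, ref = refb, alt = disruptive,
               class = "disruptive", stringsAsFactors = FALSE)
  )
}
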