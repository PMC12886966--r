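# Multi-sample short-variant VCF reading/writing.
#
# The in-memory container is a `variant_set`: a site table plus aligned
# genotype matrices. All downstream modules consume this, never raw VCF.
#   variants: data.frame(variant_id, contig, pos (1-based), ref, alt, filter)
#   gt:     integer matrix sites x samples, ALT allele count (NA = missing)
#   dp:     integer matrix, read depth
#   ploidy: integer matrix, number of called alleles (1 = hemizygous)

new_variant_set <- function(variants, gt, dp, ploidy) {
  stopifnot(nrow(variants) == nrow(gt), all(dim(gt) == dim(dp)),
            all(dim(gt) == dim(ploidy)))
  rownames(variants) <- NULL
  rownames(gt) <- rownames(dp) <- rownames(ploidy) <- variants$variant_id
  structure(list(variants = variants, gt = gt, dp = dp, ploidy = ploidy,
                 samples = colnames(gt)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d site(s) x %d sample(s)\n",
              nrow(x$variants), length(x$samples)))
  invisible(x)
}

empty_variant_set <- function(samples = character()) {
  v <- empty_df(list(variant_id = character(), contig = character(),
                     pos = integer(), ref = character(), alt = character(),
                     filter = character()))
  m <- matrix(integer(), nrow = 0, ncol = length(samples),
              dimnames = list(NULL, samples))
  new_variant_set(v, m, m, m)
}

parse_gt_strings <- function(gt_chr, half_call = "missing") {
  # gt_chr: character vector like "0/1", "1|0", "1", "./.", ".", "0/."
  alleles <- strsplit(gsub("\\|", "/", gt_chr), "/", fixed = FALSE)
  ploidy <- lengths(alleles)
  count <- integer(length(gt_chr))
  missing <- logical(length(gt_chr))
  for (i in seq_along(alleles)) {
    a <- alleles[[i]]
    if (all(a == ".") || is.na(gt_chr[i])) {
      missing[i] <- TRUE
    } else if (any(a == ".")) {
      # half-called genotype
      if (half_call == "missing") missing[i] <- TRUE
      else count[i] <- sum(a != "0" & a != ".")
    } else {
      count[i] <- sum(a != "0")
    }
  }
  count[missing] <- NA_integer_
  ploidy[is.na(gt_chr)] <- 2L
  list(count = count, ploidy = as.integer(ploidy))
}

#' Read a multi-sample short-variant VCF
#'
#' Parses a VCF 4.2 file into a \code{variant_set}. Records must carry GT
#' per sample; DP is read when present (0 otherwise). Multiallelic records
#' are excluded and counted (the published filter kept single-genotype
#' records only) or decomposed into per-ALT records when
#' \code{config$multiallelic == "decompose"}.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param pedigree optional pedigree data frame (\code{\link{read_pedigree}});
#'   samples in the VCF absent from it are reported in the
#'   \code{unknown_samples} attribute.
#' @param config an \code{\link{run_config}} object.
#' @return A \code{variant_set}; attribute \code{n_multiallelic_skipped}
#'   counts excluded records.
#' @export
read_multisample_vcf <- function(path, pedigree = NULL, config = run_config()) {
  if (!file.exists(path)) ndd_stop(paste("no such VCF:", path), "io_error")
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) ndd_stop(
                    paste0("malformed VCF '", path, "': ", conditionMessage(e)),
                    "parse_error"))
  samples <- colnames(vcf@gt)[-1]
  if (nrow(vcf@fix) == 0L) {
    out <- empty_variant_set(samples)
    attr(out, "n_multiallelic_skipped") <- 0L
    return(out)
  }
  if (is.null(vcf@gt) || !grepl("GT", vcf@gt[1, "FORMAT"]))
    ndd_stop("VCF FORMAT lacks GT", "format_error")

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_skipped <- 0L
  gt_chr <- vcfR::extract.gt(vcf, element = "GT")
  dp_chr <- tryCatch(vcfR::extract.gt(vcf, element = "DP"),
                     error = function(e) NULL)
  if (is.null(dim(gt_chr))) gt_chr <- matrix(gt_chr, ncol = length(samples),
                                             dimnames = list(NULL, samples))

  expand <- list()
  if (config$multiallelic == "decompose") {
    for (i in which(multi)) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      for (k in seq_along(alts)) expand[[length(expand) + 1L]] <-
          list(row = i, alt = alts[k], allele = k)
    }
    keep <- which(!multi)
  } else {
    n_skipped <- sum(multi)
    keep <- which(!multi)
  }

  build_rows <- function(rows, alt_override = NULL, allele = 1L) {
    if (length(rows) == 0L) return(NULL)
    v <- data.frame(
      contig = fix$CHROM[rows], pos = as.integer(fix$POS[rows]),
      ref = toupper(fix$REF[rows]),
      alt = toupper(if (is.null(alt_override)) fix$ALT[rows] else alt_override),
      filter = ifelse(is.na(fix$FILTER[rows]), ".", fix$FILTER[rows]),
      stringsAsFactors = FALSE)
    v$variant_id <- variant_key(v$contig, v$pos, v$ref, v$alt)
    gm <- matrix(NA_integer_, nrow = length(rows), ncol = length(samples),
                 dimnames = list(NULL, samples))
    pm <- matrix(2L, nrow = length(rows), ncol = length(samples),
                 dimnames = list(NULL, samples))
    for (j in seq_along(samples)) {
      parsed <- parse_gt_strings(gt_chr[rows, j], config$half_call)
      if (!is.null(alt_override)) {
        # recount against the chosen ALT allele index
        raw <- gsub("\\|", "/", gt_chr[rows, j])
        parts <- strsplit(raw, "/")
        parsed$count <- vapply(seq_along(parts), function(ii) {
          a <- parts[[ii]]
          if (any(a == ".") || is.na(raw[ii])) return(NA_integer_)
          sum(a == as.character(allele))
        }, integer(1))
      }
      gm[, j] <- parsed$count
      pm[, j] <- parsed$ploidy
    }
    dm <- matrix(0L, nrow = length(rows), ncol = length(samples),
                 dimnames = list(NULL, samples))
    if (!is.null(dp_chr)) {
      dd <- suppressWarnings(matrix(as.integer(dp_chr[rows, , drop = FALSE]),
                                    nrow = length(rows)))
      dd[is.na(dd)] <- 0L
      dm[] <- dd
    }
    list(v = v, gt = gm, dp = dm, ploidy = pm)
  }

  parts <- list(build_rows(keep))
  for (e in expand) {
    b <- build_rows(e$row, alt_override = e$alt, allele = e$allele)
    parts[[length(parts) + 1L]] <- b
  }
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 0L) {
    out <- empty_variant_set(samples)
  } else {
    v <- rbind_df(lapply(parts, `[[`, "v"))
    gm <- do.call(rbind, lapply(parts, `[[`, "gt"))
    dm <- do.call(rbind, lapply(parts, `[[`, "dp"))
    pm <- do.call(rbind, lapply(parts, `[[`, "ploidy"))
    o <- order(v$contig, v$pos, v$alt)
    out <- new_variant_set(v[o, c("variant_id", "contig", "pos", "ref", "alt",
                                  "filter")],
                           gm[o, , drop = FALSE], dm[o, , drop = FALSE],
                           pm[o, , drop = FALSE])
  }
  attr(out, "n_multiallelic_skipped") <- n_skipped
  if (!is.null(pedigree)) {
    attr(out, "unknown_samples") <- setdiff(samples, pedigree$sample_id)
  }
  out
}

gt_to_string <- function(count, ploidy) {
  out <- character(length(count))
  for (i in seq_along(count)) {
    p <- ploidy[i]
    if (is.na(count[i])) {
      out[i] <- paste(rep(".", p), collapse = "/")
    } else if (p == 1L) {
      out[i] <- as.character(count[i])
    } else {
      n_alt <- count[i]
      out[i] <- paste(c(rep("0", p - n_alt), rep("1", n_alt)), collapse = "/")
    }
  }
  out
}

#' Write a variant_set as a plain-text VCF 4.2 file
#'
#' Inverse of \code{\link{read_multisample_vcf}} for single-ALT records;
#' writing and re-reading yields identical domain objects.
#'
#' @param vs a \code{variant_set}.
#' @param path output path (plain text).
#' @param contig_lengths optional named integer vector for contig header lines.
#' @return \code{path}, invisibly.
#' @export
write_multisample_vcf <- function(vs, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=nddtrio",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs$samples)
  lines <- c(hdr, paste(cols, collapse = "\t"))
  v <- vs$variants
  if (nrow(v) > 0L) {
    body <- character(nrow(v))
    gt_cols <- matrix("", nrow = nrow(v), ncol = length(vs$samples))
    for (j in seq_along(vs$samples)) {
      gt_cols[, j] <- paste0(gt_to_string(vs$gt[, j], vs$ploidy[, j]), ":",
                             vs$dp[, j])
    }
    for (i in seq_len(nrow(v))) {
      body[i] <- paste(c(v$contig[i], v$pos[i], ".", v$ref[i], v$alt[i], ".",
                         v$filter[i], ".", "GT:DP", gt_cols[i, ]),
                       collapse = "\t")
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

# Combine per-family variant_sets into a cohort-wide set (union of sites,
# all samples; genotypes absent from a family's VCF are hom-ref only if the
# site was assayed there, otherwise NA).
#' Combine variant_sets over samples
#'
#' Builds a cohort-level \code{variant_set} from per-family sets: the site
#' list is the union, samples are concatenated, and a site absent from a
#' family's VCF is treated as homozygous reference for that family's samples
#' (the convention of joint-called cohort VCFs, where uncalled sites are
#' reference).
#'
#' @param sets list of \code{variant_set} objects with disjoint samples.
#' @return A cohort \code{variant_set}.
#' @export
combine_variant_sets <- function(sets) {
  sets <- Filter(function(s) length(s$samples) > 0L, sets)
  if (length(sets) == 0L) return(empty_variant_set())
  all_v <- rbind_df(lapply(sets, function(s) s$variants))
  all_v <- all_v[!duplicated(all_v$variant_id), , drop = FALSE]
  o <- order(all_v$contig, all_v$pos, all_v$alt)
  all_v <- all_v[o, , drop = FALSE]
  samples <- unlist(lapply(sets, `[[`, "samples"))
  if (anyDuplicated(samples))
    ndd_stop("duplicate sample ids across variant sets", "pedigree_error")
  n <- nrow(all_v)
  gt <- matrix(0L, n, length(samples), dimnames = list(all_v$variant_id, samples))
  dp <- matrix(0L, n, length(samples), dimnames = dimnames(gt))
  pl <- matrix(2L, n, length(samples), dimnames = dimnames(gt))
  for (s in sets) {
    idx <- match(s$variants$variant_id, all_v$variant_id)
    gt[idx, s$samples] <- s$gt
    dp[idx, s$samples] <- s$dp
    pl[idx, s$samples] <- s$ploidy
    # sites not present in this family's VCF: keep hom-ref, depth at dp of 0
  }
  new_variant_set(all_v, gt, dp, pl)
}
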