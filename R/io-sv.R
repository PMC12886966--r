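# SV VCF reading/writing (per-caller call sets).
#
# Dialect: VCF 4.2 with symbolic ALT alleles and SVTYPE/END/SVLEN INFO
# keys; one record per (sample, call) with the carrier named in the
# SAMPLE INFO field and the population allele frequency in AF — the shape
# per-sample SV callers emit before any family merging.

#' Read a per-caller SV VCF into a call table
#'
#' @param path VCF with SVTYPE/END/SVLEN (and optional SAMPLE, AF) INFO
#'   keys.
#' @param caller caller label attached to every call; defaults to the
#'   \code{##source} header when present.
#' @param sample_id fallback sample id when records lack a SAMPLE key.
#' @return data.frame(sample_id, caller, sv_type, contig, start, end,
#'   length, genotype, population_af); coordinates half-open 0-based.
#' @export
read_sv_vcf <- function(path, caller = NULL, sample_id = NULL) {
  if (!file.exists(path)) ndd_stop(paste("no such VCF:", path), "io_error")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(caller)) {
    src <- grep("^##source=", vcf@meta, value = TRUE)
    caller <- if (length(src) > 0L) sub("^##source=", "", src[1]) else
      NA_character_
  }
  proto <- list(sample_id = character(), caller = character(),
                sv_type = character(), contig = character(),
                start = integer(), end = integer(), length = integer(),
                genotype = integer(), population_af = numeric())
  if (nrow(vcf@fix) == 0L) return(empty_df(proto))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="),
                                             info))) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  svtype <- info_get(fix$INFO, "SVTYPE")
  if (anyNA(svtype)) ndd_stop("SV VCF record lacks SVTYPE", "format_error")
  end1 <- as.integer(info_get(fix$INFO, "END"))
  svlen <- abs(as.integer(info_get(fix$INFO, "SVLEN")))
  smp <- info_get(fix$INFO, "SAMPLE")
  if (anyNA(smp)) {
    if (is.null(sample_id))
      ndd_stop("SV VCF lacks SAMPLE INFO key and no sample_id given",
               "format_error")
    smp[is.na(smp)] <- sample_id
  }
  af <- suppressWarnings(as.numeric(info_get(fix$INFO, "AF")))
  start0 <- as.integer(fix$POS)       # POS = base before the event
  end0 <- ifelse(svtype %in% c("INS", "MEI"), start0 + 1L, end1)
  len <- ifelse(svtype %in% c("INS", "MEI"), svlen, end0 - start0)
  data.frame(sample_id = smp, caller = caller, sv_type = svtype,
             contig = fix$CHROM, start = start0, end = as.integer(end0),
             length = as.integer(len), genotype = 1L, population_af = af,
             stringsAsFactors = FALSE)
}

#' Write a call table as a per-caller SV VCF
#'
#' Inverse of \code{\link{read_sv_vcf}}.
#'
#' @param calls call data.frame (see \code{\link{read_sv_vcf}}).
#' @param path output path.
#' @param caller caller label written to the \code{##source} header.
#' @param contig_lengths optional named vector for contig header lines.
#' @return \code{path}, invisibly.
#' @export
write_sv_vcf <- function(calls, path, caller = "custom",
                         contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=", caller),
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
           '##INFO=<ID=SAMPLE,Number=1,Type=String,Description="Carrier sample">',
           '##INFO=<ID=AF,Number=1,Type=Float,Description="Population allele frequency">',
           '##ALT=<ID=DEL,Description="Deletion">',
           '##ALT=<ID=DUP,Description="Duplication">',
           '##ALT=<ID=INS,Description="Insertion">',
           '##ALT=<ID=MEI,Description="Mobile element insertion">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t"))
  body <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    x <- calls[i, ]
    svlen <- if (x$sv_type == "DEL") -x$length else x$length
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;SAMPLE=%s", x$sv_type,
                    x$end, svlen, x$sample_id)
    if (!is.na(x$population_af))
      info <- paste0(info, sprintf(";AF=%g", x$population_af))
    body[i] <- paste(c(x$contig, x$start, paste0("sv", i), "N",
                       paste0("<", x$sv_type, ">"), ".", "PASS", info),
                     collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
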