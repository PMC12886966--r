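# PED pedigrees, gene tables, CNV segment tables, annotation tables, FASTA.

#' Read a PED pedigree file
#'
#' Standard 6-column PED (family, individual, father, mother, sex,
#' phenotype). Roles are inferred: an affected individual with parent
#' columns set (or listed as a child) is a proband; individuals referenced
#' as father/mother take those roles; unaffected children are siblings.
#'
#' @param path PED file, whitespace-delimited, optional header line
#'   starting with '#'.
#' @return A data.frame with columns family_id, sample_id, father_id,
#'   mother_id, role, sex ("M"/"F"), affected, sequenced (TRUE; flip with
#'   \code{\link{mark_sequenced}} once genotype availability is known).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) ndd_stop(paste("no such PED:", path), "io_error")
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#",
                           col.names = c("family_id", "sample_id", "father_id",
                                         "mother_id", "sex", "phenotype"))
  if (nrow(raw) == 0L)
    return(empty_df(list(family_id = character(), sample_id = character(),
                         father_id = character(), mother_id = character(),
                         role = character(), sex = character(),
                         affected = logical(), sequenced = logical())))
  raw$family_id <- as.character(raw$family_id)
  raw$sample_id <- as.character(raw$sample_id)
  raw$father_id <- as.character(raw$father_id)
  raw$mother_id <- as.character(raw$mother_id)
  if (anyDuplicated(raw$sample_id))
    ndd_stop("duplicate sample id in PED", "pedigree_error")
  raw$father_id[raw$father_id %in% c("0", ".")] <- NA_character_
  raw$mother_id[raw$mother_id %in% c("0", ".")] <- NA_character_
  bad_f <- !is.na(raw$father_id) & !(raw$father_id %in% raw$sample_id)
  bad_m <- !is.na(raw$mother_id) & !(raw$mother_id %in% raw$sample_id)
  if (any(bad_f | bad_m))
    ndd_stop(paste("PED child references unknown parent id:",
                   paste(stats::na.omit(c(raw$father_id[bad_f],
                                          raw$mother_id[bad_m])),
                         collapse = ", ")),
             "pedigree_error")
  sex <- ifelse(raw$sex %in% c("1", "M"), "M",
                ifelse(raw$sex %in% c("2", "F"), "F", NA_character_))
  affected <- raw$phenotype %in% c("2", "2.0")
  role <- rep(NA_character_, nrow(raw))
  role[raw$sample_id %in% raw$father_id] <- "father"
  role[raw$sample_id %in% raw$mother_id] <- "mother"
  is_child <- is.na(role) # not referenced as a parent
  role[is_child & affected] <- "proband"
  role[is_child & !affected] <- "sibling"
  ped <- data.frame(family_id = raw$family_id, sample_id = raw$sample_id,
                    father_id = raw$father_id, mother_id = raw$mother_id,
                    role = role, sex = sex, affected = affected,
                    sequenced = TRUE, stringsAsFactors = FALSE)
  for (fam in unique(ped$family_id)) {
    sub <- ped[ped$family_id == fam, ]
    if (!any(sub$role == "proband"))
      ndd_stop(paste("family without affected proband:", fam), "pedigree_error")
    if (sum(sub$role == "father") > 1L || sum(sub$role == "mother") > 1L)
      ndd_stop(paste("family with more than one father or mother:", fam),
               "pedigree_error")
  }
  ped
}

#' Write a pedigree data.frame as a PED file
#' @param ped pedigree data.frame (see \code{\link{read_pedigree}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(ped$family_id, ped$sample_id,
                    ifelse(is.na(ped$father_id), "0", ped$father_id),
                    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    ifelse(ped$sex == "M", 1L, 2L),
                    ifelse(ped$affected, 2L, 1L))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Flag pedigree members without genotype data
#'
#' @param ped pedigree data.frame.
#' @param sequenced_samples character vector of sample ids with genotypes.
#' @return The pedigree with the \code{sequenced} column updated.
#' @export
mark_sequenced <- function(ped, sequenced_samples) {
  ped$sequenced <- ped$sample_id %in% sequenced_samples
  ped
}

#' Read a gene annotation table
#'
#' TSV with columns: symbol, contig, strand, exon_starts, exon_ends
#' (comma-separated, BED-style half-open 0-based), pli, phaplo, ptriplo,
#' ndd_list, established_ndd_gene, acmg_sf_gene, inheritance_mode. Exon
#' intervals are normalized (sorted, overlapping rows unioned); missing
#' dosage scores stay missing.
#'
#' @param path TSV file.
#' @return A data.frame with list columns \code{exon_start}/\code{exon_end}.
#' @export
read_gene_table <- function(path) {
  tab <- read_tsv(path)
  proto <- list(symbol = character(), contig = character(), strand = character(),
                pli = numeric(), phaplo = numeric(), ptriplo = numeric(),
                ndd_list = logical(), established_ndd_gene = logical(),
                acmg_sf_gene = logical(), inheritance_mode = character())
  if (nrow(tab) == 0L) {
    out <- empty_df(proto)
    out$exon_start <- list()
    out$exon_end <- list()
    return(out)
  }
  parse_ints <- function(x) lapply(strsplit(as.character(x), ","),
                                   function(v) as.integer(v[nzchar(v)]))
  starts <- parse_ints(tab$exon_starts)
  ends <- parse_ints(tab$exon_ends)
  exon_start <- vector("list", nrow(tab))
  exon_end <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    s <- starts[[i]]; e <- ends[[i]]
    if (any(s < 0)) ndd_stop("negative exon coordinate", "coord_error")
    check_interval(s, e, "exon")
    r <- IRanges::reduce(to_iranges(s, e))
    exon_start[[i]] <- from_iranges_start(r)
    exon_end[[i]] <- from_iranges_end(r)
  }
  data.frame(symbol = as.character(tab$symbol),
             contig = as.character(tab$contig),
             strand = as.character(tab$strand %||% "+"),
             pli = as.numeric(tab$pli), phaplo = as.numeric(tab$phaplo),
             ptriplo = as.numeric(tab$ptriplo),
             ndd_list = as.logical(tab$ndd_list),
             established_ndd_gene = as.logical(tab$established_ndd_gene),
             acmg_sf_gene = as.logical(tab$acmg_sf_gene),
             inheritance_mode = as.character(tab$inheritance_mode),
             stringsAsFactors = FALSE) -> out
  out$exon_start <- exon_start
  out$exon_end <- exon_end
  out
}

#' Write a gene table to TSV
#' @param genes gene table as returned by \code{\link{read_gene_table}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  flat <- genes[, setdiff(names(genes), c("exon_start", "exon_end"))]
  flat$exon_starts <- vapply(genes$exon_start, paste, "", collapse = ",")
  flat$exon_ends <- vapply(genes$exon_end, paste, "", collapse = ",")
  write_tsv(flat, path)
}

# Flatten a gene table to one row per exon (half-open 0-based).
gene_exons <- function(genes) {
  n <- lengths(genes$exon_start)
  data.frame(symbol = rep(genes$symbol, n),
             contig = rep(genes$contig, n),
             start = unlist(genes$exon_start, use.names = FALSE) %||% integer(),
             end = unlist(genes$exon_end, use.names = FALSE) %||% integer(),
             stringsAsFactors = FALSE)
}

#' Read CNV segments (CNVkit-style .cns dialect)
#'
#' Accepts a TSV with columns chromosome/contig, start, end, log2,
#' p-value (named p_value, p_ttest or p), weight, and sample_id (or a
#' single-sample file plus the \code{sample_id} argument). Coordinates are
#' half-open 0-based. The copy-number state is derived from the sign of
#' the log2 ratio: DUP when log2 > 0, DEL otherwise.
#'
#' @param path TSV file.
#' @param sample_id sample name used when the table has no sample column.
#' @return data.frame(sample_id, contig, start, end, log2_ratio, p_value,
#'   weight, cnv_type).
#' @export
read_cnv_segments <- function(path, sample_id = NULL) {
  tab <- read_tsv(path)
  names(tab)[names(tab) == "chromosome"] <- "contig"
  pcol <- intersect(c("p_value", "p_ttest", "p"), names(tab))[1]
  if (is.na(pcol)) ndd_stop("CNV table lacks a p-value column", "schema_error")
  names(tab)[names(tab) == pcol] <- "p_value"
  if (!("sample_id" %in% names(tab))) {
    if (is.null(sample_id))
      ndd_stop("CNV table lacks sample_id column and no sample_id given",
               "schema_error")
    tab$sample_id <- sample_id
  }
  required <- c("contig", "start", "end", "log2", "p_value", "weight")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0L)
    ndd_stop(paste("CNV table lacks column(s):", paste(miss, collapse = ", ")),
             "schema_error")
  if (nrow(tab) == 0L)
    return(empty_df(list(sample_id = character(), contig = character(),
                         start = integer(), end = integer(),
                         log2_ratio = numeric(), p_value = numeric(),
                         weight = numeric(), cnv_type = character())))
  out <- data.frame(sample_id = as.character(tab$sample_id),
                    contig = as.character(tab$contig),
                    start = as.integer(tab$start), end = as.integer(tab$end),
                    log2_ratio = as.numeric(tab$log2),
                    p_value = as.numeric(tab$p_value),
                    weight = as.numeric(tab$weight),
                    stringsAsFactors = FALSE)
  check_interval(out$start, out$end, "CNV segment")
  out$cnv_type <- ifelse(out$log2_ratio > 0, "DUP", "DEL")
  out
}

#' Read the variant annotation table
#'
#' One row per variant key with the annotation columns the cascade
#' consumes (gene, functional region, exonic consequence, gnomAD AF,
#' CADD_phred, GERP++_RS, ClinVar/InterVar labels, ACMG class,
#' AlphaMissense class). Missing values stay NA.
#'
#' @param path TSV with a variant_id column (contig:pos:ref:alt).
#' @return data.frame keyed by variant_id.
#' @export
read_annotation_table <- function(path) {
  tab <- read_tsv(path)
  for (cn in c("gene", "func_region", "exonic_consequence", "clinvar_class",
               "intervar_class", "acmg_class", "alphamissense_class"))
    if (cn %in% names(tab)) tab[[cn]] <- as.character(tab[[cn]])
  need <- c("variant_id", "gene", "func_region", "exonic_consequence",
            "gnomad_af", "cadd_phred", "gerp_rs", "clinvar_class",
            "intervar_class", "acmg_class", "alphamissense_class")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    ndd_stop(paste("annotation table lacks:", paste(miss, collapse = ", ")),
             "schema_error")
  bad_af <- !is.na(tab$gnomad_af) & (tab$gnomad_af < 0 | tab$gnomad_af > 1)
  if (any(bad_af)) ndd_stop("gnomad_af outside [0,1]", "schema_error")
  tab
}

#' Attach annotations to a variant_set
#'
#' Left-joins annotation columns onto the site table by variant key.
#' Sites without a row in the table get all-NA annotations.
#'
#' @param vs a \code{variant_set}.
#' @param annotations data.frame from \code{\link{read_annotation_table}}.
#' @return The \code{variant_set} with annotation columns on
#'   \code{vs$variants}.
#' @export
attach_annotations <- function(vs, annotations) {
  idx <- match(vs$variants$variant_id, annotations$variant_id)
  cols <- setdiff(names(annotations), "variant_id")
  for (cn in cols) vs$variants[[cn]] <- annotations[[cn]][idx]
  vs
}

#' Load a reference FASTA
#' @param path FASTA file.
#' @return A named \code{Biostrings::DNAStringSet} (names truncated at the
#'   first whitespace).
#' @export
load_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Fetch an uppercase reference window
#'
#' Extracts \code{[start, end)} (half-open 0-based) from a loaded
#' reference. Windows overhanging a contig boundary are shifted inward so
#' that the requested length is preserved; the applied shift (bp, signed)
#' is returned in the \code{shift} attribute rather than padding silently.
#'
#' @param reference \code{DNAStringSet} from \code{\link{load_reference}}.
#' @param contig contig name.
#' @param start,end half-open 0-based coordinates.
#' @return Uppercase sequence string of length \code{end - start} with
#'   attribute \code{shift}.
#' @export
fetch_reference_window <- function(reference, contig, start, end) {
  if (!(contig %in% names(reference)))
    ndd_stop(paste("unknown contig:", contig), "coord_error")
  check_interval(start, end, "window")
  len <- end - start
  clen <- length(reference[[contig]])
  if (len > clen)
    ndd_stop("window longer than contig", "coord_error")
  shift <- 0L
  if (start < 0L) { shift <- -start; }
  if (end + shift > clen) { shift <- clen - end }
  start <- start + shift
  end <- end + shift
  seqc <- toupper(as.character(Biostrings::subseq(reference[[contig]],
                                                  start + 1L, end)))
  attr(seqc, "shift") <- as.integer(shift)
  seqc
}
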