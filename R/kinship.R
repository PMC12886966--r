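# KING-robust kinship estimation and pedigree verification.
#
# The estimator is the robust between-family formula on biallelic
# genotype counts: with N_Aa,Aa the number of sites where both samples
# are heterozygous, N_AA,aa the number of opposite-homozygote sites and
# N_Aa(i) the heterozygote count of sample i over the shared sites,
#
#   phi = (N_Aa,Aa - 2 * N_AA,aa) / (N_Aa(i) + N_Aa(j)).
#
# Expected values: monozygotic/self 0.5, parent-offspring and full
# siblings ~0.25, unrelated ~0.

#' Estimate pairwise kinship (KING-robust)
#'
#' @param genotypes_i,genotypes_j integer vectors of ALT allele counts
#'   (0/1/2) over the same autosomal biallelic sites; NA = missing call.
#'   Sites missing in either sample are excluded.
#' @return A one-row data.frame: n_sites, n_het_het, n_opp_hom, n_het_i,
#'   n_het_j, phi (NA with \code{defined = FALSE} when neither sample has
#'   a heterozygous site).
#' @examples
#' g <- c(0L, 1L, 1L, 2L, 0L)
#' estimate_kinship(g, g)$phi  # 0.5, the self/MZ-twin value
#' @export
estimate_kinship <- function(genotypes_i, genotypes_j) {
  if (length(genotypes_i) != length(genotypes_j))
    ndd_stop("genotype vectors differ in length", "kinship_error")
  ok <- !is.na(genotypes_i) & !is.na(genotypes_j)
  gi <- genotypes_i[ok]; gj <- genotypes_j[ok]
  n_het_het <- sum(gi == 1L & gj == 1L)
  n_opp_hom <- sum(abs(gi - gj) == 2L)
  n_het_i <- sum(gi == 1L)
  n_het_j <- sum(gj == 1L)
  denom <- n_het_i + n_het_j
  phi <- if (denom > 0L) (n_het_het - 2 * n_opp_hom) / denom else NA_real_
  data.frame(n_sites = length(gi), n_het_het = n_het_het,
             n_opp_hom = n_opp_hom, n_het_i = n_het_i, n_het_j = n_het_j,
             phi = phi, defined = denom > 0L)
}

# Extract the autosomal, biallelic, PASS, depth-qualified genotype matrix
# used for kinship ("quality-filtered short variants").
kinship_genotypes <- function(vs, config = run_config()) {
  v <- vs$variants
  keep <- v$filter == "PASS" & v$contig != config$x_contig
  gt <- vs$gt[keep, , drop = FALSE]
  dp <- vs$dp[keep, , drop = FALSE]
  gt[dp < config$dp_min] <- NA_integer_
  gt
}

expected_phi_bin <- function(relation, config) {
  fd <- config$kinship_first_degree
  switch(relation,
         parent_child = c(fd[1], fd[2]),
         siblings = c(fd[1], fd[2]),
         parent_pair = c(-Inf, config$kinship_unrelated_max),
         c(-Inf, Inf))
}

#' Verify declared pedigree relationships from genotypes
#'
#' Estimates kinship for every declared parent-child and sibling pair and
#' for each family's mother-father pair, then flags pairs whose
#' coefficient falls outside the conventional bin for the declared
#' relationship (first degree [0.177, 0.354); unrelated below 0.0442).
#' Members without genotype data are skipped with a warning.
#'
#' @param vs cohort \code{variant_set} holding all sequenced members.
#' @param pedigree pedigree data.frame (\code{\link{read_pedigree}}).
#' @param config \code{\link{run_config}} with kinship bins and QC
#'   thresholds.
#' @return data.frame(family_id, sample_i, sample_j, relation, phi,
#'   consistent).
#' @export
verify_pedigree <- function(vs, pedigree, config = run_config()) {
  gt <- kinship_genotypes(vs, config)
  have <- colnames(gt)
  rows <- list()
  add_pair <- function(fam, a, b, relation) {
    if (!(a %in% have) || !(b %in% have)) {
      warning(sprintf("pair %s-%s skipped: missing genotypes", a, b))
      return()
    }
    est <- estimate_kinship(gt[, a], gt[, b])
    bin <- expected_phi_bin(relation, config)
    rows[[length(rows) + 1L]] <<- data.frame(
      family_id = fam, sample_i = a, sample_j = b, relation = relation,
      phi = est$phi,
      consistent = !is.na(est$phi) & est$phi >= bin[1] & est$phi < bin[2],
      stringsAsFactors = FALSE)
  }
  for (fam in unique(pedigree$family_id)) {
    sub <- pedigree[pedigree$family_id == fam, ]
    children <- sub[!is.na(sub$father_id) | !is.na(sub$mother_id), ]
    for (i in seq_len(nrow(children))) {
      ch <- children$sample_id[i]
      if (!is.na(children$father_id[i]))
        add_pair(fam, children$father_id[i], ch, "parent_child")
      if (!is.na(children$mother_id[i]))
        add_pair(fam, children$mother_id[i], ch, "parent_child")
    }
    if (nrow(children) > 1L) {
      for (i in seq_len(nrow(children) - 1L))
        for (j in (i + 1L):nrow(children))
          add_pair(fam, children$sample_id[i], children$sample_id[j],
                   "siblings")
    }
    fa <- sub$sample_id[sub$role == "father"]
    mo <- sub$sample_id[sub$role == "mother"]
    if (length(fa) == 1L && length(mo) == 1L)
      add_pair(fam, fa, mo, "parent_pair")
  }
  rbind_df(rows) %||%
    empty_df(list(family_id = character(), sample_i = character(),
                  sample_j = character(), relation = character(),
                  phi = numeric(), consistent = logical()))
}

#' Simulate trio genotype matrices at independent biallelic SNPs
#'
#' Founders are drawn in Hardy-Weinberg equilibrium at per-site MAFs
#' uniform over \code{maf_range}; one offspring per trio is produced by
#' Mendelian transmission. Used for kinship calibration.
#'
#' @param n_trios number of trios.
#' @param n_sites number of autosomal biallelic sites.
#' @param maf_range length-2 numeric, uniform MAF bounds.
#' @param seed integer RNG seed.
#' @return list(gt = sites x (3*n_trios) integer matrix with columns
#'   <trio>_F/_M/_P, trios = data.frame of column names per trio).
#' @export
simulate_trio_genotypes <- function(n_trios, n_sites,
                                    maf_range = c(0.1, 0.5), seed = 1L) {
  set.seed(as.integer(seed))
  maf <- stats::runif(n_sites, maf_range[1], maf_range[2])
  cols <- as.vector(t(outer(sprintf("T%03d", seq_len(n_trios)),
                            c("_F", "_M", "_P"), paste0)))
  gt <- matrix(NA_integer_, n_sites, 3L * n_trios,
               dimnames = list(NULL, cols))
  for (k in seq_len(n_trios)) {
    fa <- stats::rbinom(n_sites, 2L, maf)
    mo <- stats::rbinom(n_sites, 2L, maf)
    ch <- stats::rbinom(n_sites, 1L, fa / 2) + stats::rbinom(n_sites, 1L, mo / 2)
    gt[, 3L * (k - 1L) + 1:3] <- cbind(fa, mo, ch)
  }
  trios <- data.frame(father = cols[seq(1, length(cols), 3)],
                      mother = cols[seq(2, length(cols), 3)],
                      child = cols[seq(3, length(cols), 3)],
                      stringsAsFactors = FALSE)
  list(gt = gt, trios = trios)
}

#' Kinship calibration on simulated trios
#'
#' Convenience wrapper: simulates \code{n_trios} trios, estimates
#' KING-robust kinship for all parent-offspring and mother-father pairs,
#' and returns the per-pair estimates plus class means.
#'
#' @inheritParams simulate_trio_genotypes
#' @return list(pairs = data.frame(relation, phi), means = named numeric
#'   with parent_offspring and parent_pair entries).
#' @export
kinship_calibration <- function(n_trios = 100, n_sites = 20000,
                                maf_range = c(0.1, 0.5), seed = 1L) {
  sim <- simulate_trio_genotypes(n_trios, n_sites, maf_range, seed)
  rows <- list()
  for (k in seq_len(nrow(sim$trios))) {
    tr <- sim$trios[k, ]
    for (par in c(tr$father, tr$mother))
      rows[[length(rows) + 1L]] <- data.frame(
        relation = "parent_offspring",
        phi = estimate_kinship(sim$gt[, par], sim$gt[, tr$child])$phi)
    rows[[length(rows) + 1L]] <- data.frame(
      relation = "parent_pair",
      phi = estimate_kinship(sim$gt[, tr$father], sim$gt[, tr$mother])$phi)
  }
  pairs <- rbind_df(rows)
  means <- tapply(pairs$phi, pairs$relation, mean)
  list(pairs = pairs,
       means = c(parent_offspring = unname(means[["parent_offspring"]]),
                 parent_pair = unname(means[["parent_pair"]])))
}
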