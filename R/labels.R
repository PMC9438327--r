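#' Phylogenetic nucleotide conservation labels
#'
#' Turns per-site GERP-style scores into the binary-with-missing PNC label:
#' `w = 1` when the neutral tree size exceeds `n_min` and the ratio of
#' rejected substitutions to tree size exceeds `rate_conserved` (i.e.
#' substitution rate below 1 - `rate_conserved`); `w = 0` when the site is
#' absent from the alignment (encoded as `N` missing or zero); `NA`
#' (intermediate) otherwise. Intermediate sites are excluded from training
#' so the forest contrasts clearly conserved sites against unaligned ones.
#'
#' @param N Neutral tree size (expected substitutions under a neutral
#'   model); `NA` or 0 encodes a site absent from the alignment.
#' @param RS Rejected substitutions at the site.
#' @param n_min Tree-size threshold (default 5).
#' @param rate_conserved Conservation-ratio threshold (default 0.95,
#'   strict).
#' @return Integer vector of labels in \{1, 0, `NA`\}.
#' @export
pnc_label <- function(N, RS, n_min = 5, rate_conserved = 0.95) {
  stopifnot(length(N) == length(RS))
  absent <- is.na(N) | N == 0
  if (any(N[!absent] < 0)) stop("malformed scores: negative tree size")
  if (any(RS[!absent] > N[!absent]))
    stop("malformed scores: RS exceeds neutral tree size")
  out <- rep(NA_integer_, length(N))
  out[absent] <- 0L
  conserved <- !absent & N > n_min & RS / N > rate_conserved
  out[conserved] <- 1L
  out
}

#' Label genomic sites against a conservation-score table
#'
#' Sites missing from the table are unaligned (`w = 0`).
#'
#' @param chrom,pos Site coordinates.
#' @param scores Data frame with `chrom`, `pos`, `N`, `RS` (see
#'   [read_conservation_scores()]).
#' @param ... Passed to [pnc_label()].
#' @return Integer label vector aligned with the sites.
#' @export
label_sites <- function(chrom, pos, scores, ...) {
  hit <- match(paste(chrom, pos), paste(scores$chrom, scores$pos))
  N <- ifelse(is.na(hit), NA_real_, scores$N[hit])
  RS <- ifelse(is.na(hit), NA_real_, scores$RS[hit])
  # absent row = unaligned site
  N[is.na(hit)] <- 0
  RS[is.na(hit)] <- 0
  pnc_label(N, RS, ...)
}

#' Filter a SNP panel
#'
#' Keeps bi-allelic records with minor allele count at least `min_mac` and
#' missingness at most `max_missing` (both bounds inclusive), and computes
#' the minor allele frequency from non-missing calls. The operation is
#' idempotent.
#'
#' @param snps List with `sites` (data frame `chrom`, `pos`, `ref`, `alt`)
#'   and `dosage` (sites x individuals matrix), as from [read_snp_vcf()].
#' @param min_mac Minimum minor allele count (default 3).
#' @param max_missing Maximum fraction of missing calls (default 0.5).
#' @return The filtered panel; `sites` gains `maf` and `missingness`
#'   columns.
#' @export
filter_snps <- function(snps, min_mac = 3L, max_missing = 0.5) {
  sites <- snps$sites
  dosage <- snps$dosage
  n_ind <- ncol(dosage)
  miss <- rowSums(is.na(dosage)) / n_ind
  an <- 2L * rowSums(!is.na(dosage))
  ac <- rowSums(dosage, na.rm = TRUE)
  mac <- pmin(ac, an - ac)
  maf <- ifelse(an > 0L, mac / an, NA_real_)
  biallelic <- !grepl(",", sites$alt) & nchar(sites$alt) == 1L &
    nchar(sites$ref) == 1L
  keep <- biallelic & mac >= min_mac & miss <= max_missing
  sites$maf <- maf
  sites$missingness <- miss
  list(sites = sites[keep, , drop = FALSE],
       dosage = dosage[keep, , drop = FALSE])
}

#' Partition mutations into training and prediction sets
#'
#' Monomorphic mutations with an observed label (`w` of 0 or 1) form the
#' training set; SNP mutations form the prediction set (labels not
#' required). Any position occurring in both is assigned to the prediction
#' set only, so the sets are disjoint by position.
#'
#' @param mutations Mutation table from [enumerate_mutations()] (monomorphic
#'   and SNP rows together).
#' @param labels Integer label vector aligned with `mutations` (see
#'   [label_sites()]).
#' @return List with logical index vectors `training` and `prediction`.
#' @export
partition_sites <- function(mutations, labels) {
  stopifnot(nrow(mutations) == length(labels))
  key <- paste(mutations$chrom, mutations$pos)
  snp_pos <- unique(key[mutations$is_snp])
  prediction <- mutations$is_snp
  training <- !mutations$is_snp & !(key %in% snp_pos) & !is.na(labels)
  list(training = training, prediction = prediction)
}

#' Expected deleterious-mutation load per inbred line
#'
#' Assuming the minor allele at each prioritized SNP to be deleterious, an
#' inbred line carries the minor allele at a SNP with probability equal to
#' its minor allele frequency, so the expected number of deleterious
#' mutations per line is the sum of the MAFs of the prioritized SNPs.
#'
#' @param maf Minor allele frequencies of the prioritized SNPs.
#' @return Expected count (scalar).
#' @export
expected_deleterious_load <- function(maf) {
  stopifnot(all(maf >= 0 & maf <= 0.5))
  sum(maf)
}
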