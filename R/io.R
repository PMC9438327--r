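#' Read a genome from a FASTA file
#'
#' Sequences are returned as an upper-case named character vector, one element
#' per contig, which is the in-memory genome representation used throughout
#' the package.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return Named character vector of contig sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  # keep only the first whitespace-delimited token of each FASTA header
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write gene features as GFF3
#'
#' @param features Data frame with columns `chrom`, `source`, `type`, `start`,
#'   `end`, `strand`, `attributes` (GFF3 column 9 strings).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                   features$chrom, features$source %||% "picnc",
                   features$type, features$start, features$end,
                   features$strand,
                   ifelse(features$type == "CDS", "0", "."),
                   features$attributes)
  writeLines(lines, con)
  invisible(path)
}

#' Read transposon (or chromatin) intervals from BED
#'
#' BED half-open coordinates are converted to the 1-based inclusive
#' convention used internally. The feature label (BED name column) is kept
#' as the interval family.
#'
#' @param path Path to a BED file with at least 4 columns.
#' @return Data frame with columns `chrom`, `start`, `end`, `family`.
#' @export
read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             family = as.character(gr$name),
             stringsAsFactors = FALSE)
}

#' Read per-site conservation scores
#'
#' @param path TSV with columns `chrom`, `pos`, `N` (neutral tree size) and
#'   `RS` (rejected substitutions). Sites absent from the table are treated
#'   as unaligned (see [pnc_label()]).
#' @return Data frame of scores.
#' @export
read_conservation_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "N", "RS") %in% names(df)))
  df$chrom <- as.character(df$chrom)
  df
}

#' Write per-site conservation scores
#' @param scores Data frame with columns `chrom`, `pos`, `N`, `RS`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a SNP panel from VCF
#'
#' Parses site records and GT fields into the light-weight panel structure
#' used by [filter_snps()] and the kinship builders: a site table plus a
#' sites-by-individuals dosage matrix (minor-allele counts 0/1/2, `NA` for
#' missing calls).
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @return List with elements `sites` (data frame: `chrom`, `pos`, `ref`,
#'   `alt`) and `dosage` (integer matrix, sites x individuals).
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  sites <- data.frame(chrom = as.character(fix[, "CHROM"]),
                      pos = as.integer(fix[, "POS"]),
                      ref = as.character(fix[, "REF"]),
                      alt = as.character(fix[, "ALT"]),
                      stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, nrow = nrow(sites), ncol = ncol(gt),
                   dimnames = list(NULL, colnames(gt)))
  clean <- gsub("\\|", "/", gt)
  dosage[clean == "0/0"] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean == "1/1"] <- 2L
  list(sites = sites, dosage = dosage)
}

#' Write a SNP panel as VCF
#'
#' @param sites Data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param dosage Sites-by-individuals matrix of 0/1/2 dosages (`NA` =
#'   missing call). Column names are used as sample ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, dosage, path) {
  stopifnot(nrow(sites) == nrow(dosage))
  ids <- colnames(dosage) %||% sprintf("ind%03d", seq_len(ncol(dosage)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  gt <- matrix("./.", nrow = nrow(dosage), ncol = ncol(dosage))
  gt[which(dosage == 0L)] <- "0/0"
  gt[which(dosage == 1L)] <- "0/1"
  gt[which(dosage == 2L)] <- "1/1"
  lines <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                 "PASS", ".", "GT", sep = "\t")
  lines <- paste(lines, apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read precomputed SIFT-style scores
#'
#' @param path TSV keyed by `chrom`, `pos`, `alt` with a `sift_score` column.
#' @return Data frame of scores.
#' @export
read_sift_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "alt", "sift_score") %in% names(df)))
  df$chrom <- as.character(df$chrom)
  df
}

#' Write a mutation-by-annotation table
#'
#' Columns are written in their fixed construction order (site metadata
#' first, then annotation columns as produced by [annotate_mutations()]).
#'
#' @param annotations Data frame from [annotate_mutations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
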