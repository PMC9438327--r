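#' Gene models
#'
#' Gene models are plain lists: `gene_id`, `chrom`, `strand` and a list of
#' transcripts. Each transcript carries its ordered (transcription order)
#' CDS intervals, the coding-strand CDS sequence, the downstream (3' UTR)
#' sequence used for stop-loss read-through, and the translated protein
#' (terminal stop excluded). Only genes with at least one transcript having
#' CDS, 5' UTR and 3' UTR features are retained, and the CDS of every
#' retained transcript must be a multiple of 3 that translates without an
#' internal stop.
#'
#' @param gff_path Path to a GFF3 file with `gene`, `mRNA`, `CDS`,
#'   `five_prime_UTR` and `three_prime_UTR` features.
#' @param genome Named character vector of contig sequences (see
#'   [read_genome()]).
#' @return List of gene models, named by gene id.
#' @export
read_gene_models <- function(gff_path, genome) {
  gr <- rtracklayer::import(gff_path, format = "GFF3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   type = as.character(gr$type),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   id = as.character(gr$ID %||% NA),
                   parent = vapply(gr$Parent, function(p)
                     if (length(p)) as.character(p[1]) else NA_character_,
                     character(1)),
                   stringsAsFactors = FALSE)
  build_gene_models(df, genome)
}

# Assemble gene models from a flat feature table (columns chrom, type,
# start, end, strand, id, parent). Shared by the GFF reader and the
# synthetic-genome generator.
build_gene_models <- function(features, genome) {
  genes <- features[features$type == "gene", , drop = FALSE]
  mrnas <- features[features$type == "mRNA", , drop = FALSE]
  out <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    tx_rows <- mrnas[mrnas$parent == g$id, , drop = FALSE]
    transcripts <- list()
    for (ti in seq_len(nrow(tx_rows))) {
      tx <- try(build_transcript(tx_rows[ti, ], features, genome),
                silent = TRUE)
      if (inherits(tx, "try-error")) {
        warning("skipping transcript ", tx_rows$id[ti], ": ",
                attr(tx, "condition")$message, call. = FALSE)
        next
      }
      if (!is.null(tx)) transcripts[[tx$transcript_id]] <- tx
    }
    if (!length(transcripts)) {
      warning("skipping gene ", g$id, ": no complete transcript",
              call. = FALSE)
      next
    }
    out[[g$id]] <- list(gene_id = g$id, chrom = g$chrom, strand = g$strand,
                        transcripts = transcripts)
  }
  out
}

build_transcript <- function(mrna, features, genome) {
  kids <- features[!is.na(features$parent) & features$parent == mrna$id, ,
                   drop = FALSE]
  cds <- kids[kids$type == "CDS", , drop = FALSE]
  utr5 <- kids[kids$type == "five_prime_UTR", , drop = FALSE]
  utr3 <- kids[kids$type == "three_prime_UTR", , drop = FALSE]
  if (!nrow(cds) || !nrow(utr5) || !nrow(utr3)) return(NULL)
  minus <- mrna$strand == "-"
  ord <- order(cds$start, decreasing = minus)
  cds <- cds[ord, , drop = FALSE]
  utr3 <- utr3[order(utr3$start, decreasing = minus), , drop = FALSE]
  chrom_seq <- genome[[mrna$chrom]]
  if (is.null(chrom_seq)) stop("contig ", mrna$chrom, " absent from genome")
  piece <- function(s, e) {
    p <- substr(chrom_seq, s, e)
    if (minus) revcomp(p) else p
  }
  cds_seq <- paste(mapply(piece, cds$start, cds$end), collapse = "")
  utr3_seq <- paste(mapply(piece, utr3$start, utr3$end), collapse = "")
  if (nchar(cds_seq) %% 3L != 0L)
    stop("CDS length not a multiple of 3")
  prot <- translate_until_stop(cds_seq)
  if (!attr(prot, "terminated") || nchar(prot) != nchar(cds_seq) / 3L - 1L)
    stop("CDS does not translate to a clean open reading frame")
  list(transcript_id = mrna$id, gene_id = mrna$parent, chrom = mrna$chrom,
       strand = mrna$strand,
       cds_intervals = data.frame(start = cds$start, end = cds$end),
       cds_seq = cds_seq, utr3_seq = utr3_seq,
       protein = as.character(prot))
}

#' Select the representative transcript of a gene
#'
#' The representative transcript is the one with the longest CDS; ties are
#' broken by the lexicographically smallest transcript id, so the choice is
#' deterministic.
#'
#' @param gene A gene model (see [read_gene_models()]).
#' @return The representative transcript id (character scalar).
#' @export
select_representative_transcript <- function(gene) {
  if (!length(gene$transcripts))
    stop("gene ", gene$gene_id, " has no transcript with a complete CDS")
  ids <- vapply(gene$transcripts, `[[`, "", "transcript_id")
  lens <- vapply(gene$transcripts, function(t) nchar(t$cds_seq), 0)
  ids <- sort(ids[lens == max(lens)])
  unname(ids[1L])
}

# Map a transcript's CDS genomic positions to coding coordinates.
# Returns a data.frame: pos (genomic), coding_pos (1-based along the
# coding-strand CDS), codon_index (0-based codon) and codon_pos (0..2).
cds_position_map <- function(transcript) {
  iv <- transcript$cds_intervals
  pos <- unlist(lapply(seq_len(nrow(iv)), function(i) {
    p <- iv$start[i]:iv$end[i]
    if (transcript$strand == "-") rev(p) else p
  }), use.names = FALSE)
  coding <- seq_along(pos)
  data.frame(pos = pos, coding_pos = coding,
             codon_index = (coding - 1L) %/% 3L,
             codon_pos = (coding - 1L) %% 3L)
}
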