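AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Deterministic hashed-composition protein embedder
#'
#' A light-weight stand-in for a trained protein representation model,
#' honouring the embedder contract (a fixed-dimension numeric vector per
#' sequence, deterministic for a given sequence). Counts of amino-acid
#' 1-mers and 2-mers are each mapped by a seeded hash to one of `D`
#' coordinates and accumulated, then divided by the sequence length. The
#' 2-mer terms make the embedding sensitive to residue order, so in-silico
#' mutagenesis produces informative deviations.
#'
#' @param sequence Amino-acid string (terminal `*` is stripped).
#' @param D Embedding dimension (default 256).
#' @param seed Integer offset entering the bucket hash.
#' @return Numeric vector of length `D`.
#' @export
toy_embedder <- function(sequence, D = 256L, seed = 1L) {
  seq <- gsub("*", "", sequence, fixed = TRUE)
  vec <- numeric(D)
  if (nchar(seq) == 0L) {
    warning("empty sequence after stripping stops; returning zero vector")
    return(vec)
  }
  chars <- strsplit(seq, "")[[1]]
  kmers <- c(chars,
             if (length(chars) > 1L)
               paste0(chars[-length(chars)], chars[-1L]))
  counts <- table(kmers)
  for (i in seq_along(counts)) {
    bucket <- (string_hash(names(counts)[i]) + seed) %% D + 1L
    vec[bucket] <- vec[bucket] + counts[[i]]
  }
  vec / nchar(seq)
}

#' Embed a protein sequence
#'
#' Validates the sequence against the 20-residue alphabet (a terminal stop
#' `*` is stripped first) and applies the supplied embedder.
#'
#' @param sequence Amino-acid string.
#' @param embedder Function mapping a sequence to a numeric vector of fixed
#'   dimension; defaults to [toy_embedder()] at dimension 256.
#' @return Numeric representation vector.
#' @export
embed_protein <- function(sequence, embedder = toy_embedder) {
  seq <- gsub("*", "", sequence, fixed = TRUE)
  if (nchar(seq) == 0L) stop("empty protein sequence")
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad))
    stop("invalid residue '", chars[bad[1L]], "' at position ", bad[1L])
  out <- embedder(sequence)
  if (!all(is.finite(out))) stop("embedder returned non-finite values")
  out
}

#' Apply a coding point mutation to a protein
#'
#' Edits the transcript CDS at the mutated base and re-translates.
#' Missense mutations substitute one residue; stop gains truncate the
#' protein before the new stop; stop losses read through the former stop
#' into the downstream transcript sequence (3' UTR) until the next in-frame
#' stop or the transcript end (flagged via the `"terminated"` attribute
#' when no stop is found).
#'
#' @param transcript A transcript (see [read_gene_models()]).
#' @param mut One row of a mutation table from [enumerate_mutations()].
#' @return Mutated protein string with attribute `terminated`.
#' @export
mutate_protein <- function(transcript, mut) {
  map <- cds_position_map(transcript)
  i <- match(mut$pos, map$pos)
  if (is.na(i)) stop("mutation at ", mut$chrom, ":", mut$pos,
                     " lies outside the CDS of ", transcript$transcript_id)
  alt_coding <- if (transcript$strand == "-")
    complement_base(mut$alt) else mut$alt
  edited <- transcript$cds_seq
  substr(edited, map$coding_pos[i], map$coding_pos[i]) <- alt_coding
  full <- paste0(edited, transcript$utr3_seq)
  prot <- translate_until_stop(full)
  out <- as.character(prot)
  attr(out, "terminated") <- attr(prot, "terminated")
  out
}

#' In-silico mutagenesis scores
#'
#' Signed per-dimension deviations (mutant minus reference) of the protein
#' representation, plus their Euclidean norm.
#'
#' @param ref,mut Representation vectors of equal dimension.
#' @return List with `deviations` (numeric vector) and `distance`
#'   (non-negative scalar).
#' @export
mutagenesis_scores <- function(ref, mut) {
  if (length(ref) != length(mut))
    stop("representation dimensions differ: ", length(ref), " vs ",
         length(mut))
  dev <- mut - ref
  list(deviations = dev, distance = sqrt(sum(dev^2)))
}
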