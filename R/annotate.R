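#' Classify a nonsynonymous codon change
#'
#' @param ref_codon,alt_codon Three-letter DNA codons differing at exactly
#'   one position (standard nuclear code).
#' @return One of `"missense"`, `"stop_gain"`, `"stop_loss"`.
#' @export
classify_mutation <- function(ref_codon, alt_codon) {
  ref_codon <- toupper(ref_codon); alt_codon <- toupper(alt_codon)
  if (nchar(ref_codon) != 3L || nchar(alt_codon) != 3L)
    stop("codons must have length 3")
  diff <- sum(strsplit(ref_codon, "")[[1]] != strsplit(alt_codon, "")[[1]])
  if (diff != 1L) stop("codons must differ at exactly one position")
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  if (ref_aa == alt_aa) stop("not nonsynonymous: ", ref_codon, " -> ",
                             alt_codon, " is synonymous")
  if (ref_aa != "*" && alt_aa == "*") return("stop_gain")
  if (ref_aa == "*" && alt_aa != "*") return("stop_loss")
  "missense"
}

# Deterministic site-keyed ordering of alternate alleles: the same
# (chrom, pos, seed) always yields the same draw, independent of the order
# in which sites are visited.
site_alt_order <- function(chrom, pos, seed, n_options) {
  # scramble the polynomial hash multiplicatively (exact 31-bit modular
  # product via 16-bit limbs) so near-identical keys land far apart
  mulmod <- function(a, b, m = 2147483647) {
    ((a %% 65536) * b %% m + (a %/% 65536) * ((65536 * b) %% m)) %% m
  }
  keys <- vapply(seq_len(n_options), function(i)
    mulmod(string_hash(paste(chrom, pos, seed, i, sep = ":")) + 1,
           2654435761 %% 2147483647), 0)
  order(keys)
}

#' Enumerate candidate nonsynonymous point mutations
#'
#' Walks every coding base of each gene's representative transcript. In
#' `"snp"` mode the observed SNPs falling in coding regions are returned,
#' keeping only those whose alternate allele is nonsynonymous. In
#' `"monomorphic"` mode, sites with no SNP record receive `per_site`
#' uniformly drawn alternate bases among the nonsynonymous options at that
#' site (deterministic given `seed`); sites whose three alternates are all
#' synonymous are skipped.
#'
#' @param genome Named character vector of contig sequences.
#' @param genes List of gene models.
#' @param snps Data frame of SNPs with columns `chrom`, `pos`, `ref`, `alt`
#'   (forward strand), or `NULL`.
#' @param mode `"monomorphic"` or `"snp"`.
#' @param per_site Number of alternate alleles drawn per monomorphic site.
#' @param seed Integer seed for the site-keyed draws.
#' @return Data frame of site mutations: `chrom`, `pos`, `ref`, `alt`
#'   (forward strand), `gene_id`, `transcript_id`, `codon_index` (0-based),
#'   `codon_pos` (0-2), `ref_codon`, `alt_codon` (coding strand),
#'   `mutation_type`, `is_snp`.
#' @export
enumerate_mutations <- function(genome, genes, snps = NULL,
                                mode = c("monomorphic", "snp"),
                                per_site = 1L, seed = 1L) {
  mode <- match.arg(mode)
  if (!length(genes)) return(empty_mutation_table())
  snp_key <- if (!is.null(snps) && nrow(snps))
    paste(snps$chrom, snps$pos) else character(0)
  rows <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    gene <- genes[[gi]]
    tx <- gene$transcripts[[select_representative_transcript(gene)]]
    map <- cds_position_map(tx)
    minus <- tx$strand == "-"
    cds_chars <- strsplit(tx$cds_seq, "")[[1]]
    n_codon <- length(cds_chars) %/% 3L
    codons <- substring(tx$cds_seq, 3L * seq_len(n_codon) - 2L,
                        3L * seq_len(n_codon))
    genome_base <- substring(genome[[tx$chrom]], map$pos, map$pos)
    coding_ref <- cds_chars[map$coding_pos]
    expect_fwd <- if (minus) complement_base(coding_ref) else coding_ref
    bad <- which(genome_base != expect_fwd)
    if (length(bad))
      stop("reference mismatch at ", tx$chrom, ":", map$pos[bad[1L]],
           " for transcript ", tx$transcript_id)
    site_key <- paste(tx$chrom, map$pos)
    is_snp_site <- site_key %in% snp_key
    keep <- if (mode == "snp") which(is_snp_site) else which(!is_snp_site)
    if (!length(keep)) next
    gene_rows <- lapply(keep, function(i) {
      ci <- map$codon_index[i]
      cp <- map$codon_pos[i]
      ref_codon <- codons[ci + 1L]
      ref_c <- coding_ref[i]
      if (mode == "snp") {
        hit <- snps[snps$chrom == tx$chrom & snps$pos == map$pos[i], ,
                    drop = FALSE]
        alts_fwd <- hit$alt
        if (any(hit$ref != genome_base[i]))
          stop("SNP ref mismatch at ", tx$chrom, ":", map$pos[i])
      } else {
        alts_fwd <- setdiff(c("A", "C", "G", "T"), genome_base[i])
      }
      alts_coding <- if (minus) complement_base(alts_fwd) else alts_fwd
      alt_codons <- vapply(alts_coding, function(a) {
        x <- ref_codon; substr(x, cp + 1L, cp + 1L) <- a; x
      }, "")
      nonsyn <- translate_codon(alt_codons) != translate_codon(ref_codon)
      if (!any(nonsyn)) return(NULL)
      idx <- which(nonsyn)
      if (mode == "monomorphic" && length(idx) > per_site) {
        ord <- site_alt_order(tx$chrom, map$pos[i], seed, length(idx))
        idx <- idx[ord[seq_len(per_site)]]
      }
      data.frame(chrom = tx$chrom, pos = map$pos[i],
                 ref = genome_base[i], alt = alts_fwd[idx],
                 gene_id = gene$gene_id, transcript_id = tx$transcript_id,
                 codon_index = ci, codon_pos = cp,
                 ref_codon = ref_codon, alt_codon = alt_codons[idx],
                 mutation_type = vapply(alt_codons[idx], classify_mutation,
                                        "", ref_codon = ref_codon),
                 is_snp = mode == "snp",
                 stringsAsFactors = FALSE)
    })
    rows[[gi]] <- do.call(rbind, gene_rows)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_mutation_table())
  rownames(out) <- NULL
  out
}

empty_mutation_table <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene_id = character(),
             transcript_id = character(), codon_index = integer(),
             codon_pos = integer(), ref_codon = character(),
             alt_codon = character(), mutation_type = character(),
             is_snp = logical(), stringsAsFactors = FALSE)
}

#' GC content around a site
#'
#' Counts G or C bases (case-insensitive; N counts as non-GC) in the genomic
#' window from 49 bases upstream to 50 bases downstream of each site. Windows
#' are clipped at contig ends; the effective window length is recorded in the
#' `"window"` attribute.
#'
#' @param genome Named character vector of contig sequences.
#' @param chrom,pos Site coordinates (vectors of equal length).
#' @return Integer vector of G/C counts with a `"window"` attribute.
#' @export
gc_content <- function(genome, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  out <- integer(length(pos))
  win <- integer(length(pos))
  for (i in seq_along(pos)) {
    L <- nchar(genome[[chrom[i]]])
    lo <- max(1L, pos[i] - 49L)
    hi <- min(L, pos[i] + 50L)
    s <- toupper(substr(genome[[chrom[i]]], lo, hi))
    out[i] <- nchar(gsub("[^GC]", "", s))
    win[i] <- hi - lo + 1L
  }
  attr(out, "window") <- win
  out
}

# Encode every k-length window of a contig as a base-4 integer (A=0, C=1,
# G=2, T=3); windows containing ambiguous bases get NA. 4^13 < 2^31 so the
# codes are exact doubles.
encode_kmers <- function(seq, k) {
  codes <- c(A = 0, C = 1, G = 2, T = 3)[strsplit(toupper(seq), "")[[1]]]
  m <- length(codes) - k + 1L
  if (m < 1L) return(numeric(0))
  val <- numeric(m)
  for (j in 0:(k - 1L)) val <- val * 4 + codes[(1L + j):(m + j)]
  val
}

#' Genome-wide k-mer count index
#'
#' Precomputes occurrence counts of every k-mer present in the genome
#' (forward strand, exact match, case-folded; windows containing N are
#' ignored). The index is reused by [kmer_frequency()] across many sites.
#'
#' @param genome Named character vector of contig sequences.
#' @param k Word size (default 13).
#' @return An opaque index object for [kmer_frequency()].
#' @export
kmer_index <- function(genome, k = 13L) {
  all_codes <- unlist(lapply(genome, encode_kmers, k = k), use.names = FALSE)
  all_codes <- all_codes[!is.na(all_codes)]
  u <- sort(unique(all_codes))
  counts <- tabulate(findInterval(all_codes, u), nbins = length(u))
  structure(list(codes = u, counts = counts, k = k), class = "kmer_index")
}

#' Mean genome-wide frequency of the k-mers covering a site
#'
#' For each site, the up-to-k forward-strand windows of length `k` that
#' contain the site are looked up in the genome-wide count index and the
#' mean occurrence count is returned. Windows containing ambiguous bases
#' never match (count 0). Contigs shorter than `k` yield 0 with a warning.
#'
#' @param genome Named character vector of contig sequences.
#' @param chrom,pos Site coordinates (vectors of equal length).
#' @param k Word size (default 13).
#' @param index Optional precomputed [kmer_index()].
#' @return Numeric vector of mean covering-window counts.
#' @export
kmer_frequency <- function(genome, chrom, pos, k = 13L, index = NULL) {
  stopifnot(k >= 1L, length(chrom) == length(pos))
  if (is.null(index)) index <- kmer_index(genome, k)
  stopifnot(index$k == k)
  out <- numeric(length(pos))
  for (i in seq_along(pos)) {
    L <- nchar(genome[[chrom[i]]])
    if (L < k) {
      warning("contig ", chrom[i], " shorter than k = ", k)
      out[i] <- 0
      next
    }
    starts <- max(1L, pos[i] - k + 1L):min(pos[i], L - k + 1L)
    wins <- substring(genome[[chrom[i]]], starts, starts + k - 1L)
    codes <- vapply(wins, function(w) {
      v <- encode_kmers(w, k)
      if (length(v)) v else NA_real_
    }, 0)
    hit <- match(codes, index$codes)
    cnt <- ifelse(is.na(hit), 0, index$counts[hit])
    out[i] <- mean(cnt)
  }
  out
}

TE_FAMILIES <- c("helitron", "TIR", "LINE", "LTR")

#' Transposon-family membership flags
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and `family` (one of helitron, TIR, LINE, LTR).
#' @param chrom,pos Site coordinates (vectors of equal length).
#' @return Logical matrix, sites x 4 families.
#' @export
transposon_flags <- function(intervals, chrom, pos) {
  out <- matrix(FALSE, nrow = length(pos), ncol = length(TE_FAMILIES),
                dimnames = list(NULL, paste0("te_", tolower(TE_FAMILIES))))
  if (is.null(intervals) || !nrow(intervals)) return(out)
  unknown <- setdiff(unique(intervals$family), TE_FAMILIES)
  if (length(unknown))
    stop("unknown transposon family label(s): ",
         paste(unknown, collapse = ", "))
  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  for (f in TE_FAMILIES) {
    fam <- intervals[intervals$family == f, , drop = FALSE]
    if (!nrow(fam)) next
    gr <- GenomicRanges::GRanges(fam$chrom,
                                 IRanges::IRanges(fam$start, fam$end))
    out[, paste0("te_", tolower(f))] <-
      GenomicRanges::countOverlaps(sites, gr) > 0L
  }
  out
}

#' SIFT score features
#'
#' Missing scores are imputed to 1 (tolerated); the class is
#' `"constrained"` when the score is at most 0.05.
#'
#' @param raw_score Numeric vector of SIFT scores in \[0, 1\], `NA` allowed.
#' @return Data frame with `sift_score`, `sift_class` and
#'   `score_was_missing`.
#' @export
sift_features <- function(raw_score) {
  missing <- is.na(raw_score)
  if (any(raw_score[!missing] < 0 | raw_score[!missing] > 1))
    stop("SIFT scores must lie in [0, 1]")
  score <- ifelse(missing, 1, raw_score)
  data.frame(sift_score = score,
             sift_class = ifelse(score <= 0.05, "constrained", "tolerated"),
             score_was_missing = missing,
             stringsAsFactors = FALSE)
}

#' Build the full mutation-by-annotation table
#'
#' Combines genomic-structure annotations (GC content, 13-mer frequency,
#' transposon flags), SIFT features, the reference protein representation
#' and the in-silico mutagenesis scores of every mutation into one predictor
#' table ready for forest training.
#'
#' @param genome Named character vector of contig sequences.
#' @param mutations Mutation table from [enumerate_mutations()].
#' @param genes Gene model list (for protein mutagenesis).
#' @param te Optional transposon interval data frame (see
#'   [transposon_flags()]); omit to drop the four flags.
#' @param sift Optional data frame of precomputed SIFT scores keyed by
#'   `chrom`, `pos`, `alt`; unmatched mutations are treated as missing.
#' @param embedder Protein embedder function (default [toy_embedder()]
#'   closure of dimension `D`).
#' @param D Embedding dimension (default 256).
#' @param k Word size for the k-mer frequency annotation.
#' @param kmer_idx Optional precomputed [kmer_index()].
#' @return Data frame: mutation metadata columns followed by annotation
#'   columns (`mutation_type`, `sift_score`, `sift_class`, `gc_content`,
#'   `kmer_freq`, optional `te_*`, `rep_*`, `dev_*`, `distance`).
#' @export
annotate_mutations <- function(genome, mutations, genes, te = NULL,
                               sift = NULL, embedder = NULL, D = 256L,
                               k = 13L, kmer_idx = NULL) {
  if (is.null(embedder))
    embedder <- function(seq) toy_embedder(seq, D = D)
  meta <- mutations[c("chrom", "pos", "ref", "alt", "gene_id",
                      "transcript_id", "is_snp")]
  ann <- data.frame(mutation_type = mutations$mutation_type,
                    stringsAsFactors = FALSE)
  raw_sift <- rep(NA_real_, nrow(mutations))
  if (!is.null(sift) && nrow(sift)) {
    key <- paste(mutations$chrom, mutations$pos, mutations$alt)
    hit <- match(key, paste(sift$chrom, sift$pos, sift$alt))
    raw_sift[!is.na(hit)] <- sift$sift_score[hit[!is.na(hit)]]
  }
  sf <- sift_features(raw_sift)
  ann$sift_score <- sf$sift_score
  ann$sift_class <- sf$sift_class
  gc <- gc_content(genome, mutations$chrom, mutations$pos)
  ann$gc_content <- as.integer(gc)
  ann$kmer_freq <- kmer_frequency(genome, mutations$chrom, mutations$pos,
                                  k = k, index = kmer_idx)
  if (!is.null(te))
    ann <- cbind(ann, as.data.frame(
      transposon_flags(te, mutations$chrom, mutations$pos) * 1L))
  # reference protein representations, one embedding per transcript
  tx_ids <- unique(mutations$transcript_id)
  tx_lookup <- list()
  for (g in genes) for (t in g$transcripts)
    if (t$transcript_id %in% tx_ids) tx_lookup[[t$transcript_id]] <- t
  absent <- setdiff(tx_ids, names(tx_lookup))
  if (length(absent))
    stop("transcripts missing from gene models: ",
         paste(absent, collapse = ", "))
  ref_reps <- lapply(tx_lookup, function(t) embedder(t$protein))
  Dn <- length(ref_reps[[1L]])
  rep_mat <- t(vapply(mutations$transcript_id,
                      function(id) ref_reps[[id]], numeric(Dn)))
  colnames(rep_mat) <- sprintf("rep_%d", seq_len(Dn))
  dev_mat <- matrix(0, nrow(mutations), Dn,
                    dimnames = list(NULL, sprintf("dev_%d", seq_len(Dn))))
  dist <- numeric(nrow(mutations))
  for (i in seq_len(nrow(mutations))) {
    tx <- tx_lookup[[mutations$transcript_id[i]]]
    mut_prot <- mutate_protein(tx, mutations[i, ])
    mut_rep <- if (nchar(mut_prot) > 0L) embedder(mut_prot) else numeric(Dn)
    ms <- mutagenesis_scores(ref_reps[[tx$transcript_id]], mut_rep)
    dev_mat[i, ] <- ms$deviations
    dist[i] <- ms$distance
  }
  cbind(meta, ann, as.data.frame(rep_mat), as.data.frame(dev_mat),
        distance = dist)
}

#' Names of the annotation (predictor) columns of an annotation table
#'
#' @param annotations Data frame from [annotate_mutations()].
#' @return Character vector of predictor column names.
#' @export
annotation_columns <- function(annotations) {
  meta <- c("chrom", "pos", "ref", "alt", "gene_id", "transcript_id",
            "is_snp")
  setdiff(names(annotations), meta)
}
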