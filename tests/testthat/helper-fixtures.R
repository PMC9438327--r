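# Shared fixtures, built in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

small_config <- function(seed = 42L) {
  sim_config(n_chromosomes = 3L, genes_per_chromosome = 3L,
             codons_range = c(40L, 80L), embed_dim = 8L,
             n_diverse = 60L, n_families = 4L, family_size = 10L,
             n_background_snps = 150L, seed = seed)
}

small_bundle <- function(seed = 42L) {
  key <- paste0("bundle", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulate_picnc_data(small_config(seed))
  .fixtures[[key]]
}

# A tiny hand-made single-gene genome written through the standard formats,
# so tests with hand-computable expectations also exercise the readers.
# Layout on chrT (plus strand): 10 bp 5'UTR, CDS ATG GCT AAA TGG TAA,
# 9 bp 3'UTR.
toy_gene_files <- function() {
  if (!is.null(.fixtures$toy)) return(.fixtures$toy)
  dir <- file.path(tempdir(), "picnc-toy-gene")
  dir.create(dir, showWarnings = FALSE)
  utr5 <- "ACACACACAC"
  cds <- "ATGGCTAAATGGTAA"
  utr3 <- "GTGTGTGTG"
  seq <- paste0(utr5, cds, utr3)
  fasta <- file.path(dir, "toy.fa")
  writeLines(c(">chrT", seq), fasta)
  gff <- file.path(dir, "toy.gff3")
  writeLines(c(
    "##gff-version 3",
    "chrT\ttoy\tgene\t1\t34\t.\t+\t.\tID=gToy",
    "chrT\ttoy\tmRNA\t1\t34\t.\t+\t.\tID=gToy_t1;Parent=gToy",
    "chrT\ttoy\tfive_prime_UTR\t1\t10\t.\t+\t.\tParent=gToy_t1",
    "chrT\ttoy\tCDS\t11\t25\t.\t+\t0\tParent=gToy_t1",
    "chrT\ttoy\tthree_prime_UTR\t26\t34\t.\t+\t.\tParent=gToy_t1"),
    gff)
  .fixtures$toy <- list(fasta = fasta, gff = gff, seq = seq,
                        cds = cds, cds_start = 11L)
  .fixtures$toy
}

toy_gene_models <- function() {
  f <- toy_gene_files()
  if (is.null(.fixtures$toy_genes)) {
    genome <- read_genome(f$fasta)
    .fixtures$toy_genes <- list(genome = genome,
                                genes = read_gene_models(f$gff, genome))
  }
  .fixtures$toy_genes
}

# Independent re-implementation of the 31-bit polynomial string hash used by
# the site-keyed draws and the toy embedder.
oracle_hash <- function(x) {
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2147483647
  h
}

# Brute-force translation oracle from the standard code table.
oracle_translate <- function(codon) {
  tab <- Biostrings::GENETIC_CODE
  names(tab) <- chartr("U", "T", names(tab))
  unname(tab[toupper(codon)])
}

random_genome <- function(n, seed, name = "chrR") {
  set.seed(seed)
  setNames(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = ""), name)
}
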