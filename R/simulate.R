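#' Simulation configuration
#'
#' Desk-scale defaults for the synthetic fixture bundle: a five-chromosome
#' genome of a few tens of kilobases per chromosome, a few thousand labeled
#' coding sites, and hybrid panels of a few hundred individuals — large
#' enough for forest and REML signal, small enough for minutes-scale runs.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param genes_per_chromosome Genes per chromosome.
#' @param codons_range CDS length range in codons (start and stop
#'   included).
#' @param n_introns_range Number of introns per gene.
#' @param intron_len,utr5_len,utr3_len,intergenic Length ranges (bp).
#' @param embed_dim Protein representation dimension used in the bundle.
#' @param sift_missing_rate Fraction of mutations without a SIFT score.
#' @param planted_coef Named coefficients of the planted
#'   annotation-to-conservation logistic model (applied to standardized
#'   annotation columns).
#' @param conserved_bias Intercept of the planted logistic model.
#' @param frac_intermediate Fraction of non-conserved sites emitted as
#'   intermediate (scores violating exactly one labeling threshold).
#' @param snp_fraction Fraction of coding sites that carry a SNP.
#' @param snp_depletion Strength of SNP depletion at conserved sites.
#' @param maf_beta_a,maf_beta_b,maf_coupling Beta parameters of the MAF
#'   distribution; the second shape grows with true conservation
#'   probability by `maf_coupling`, so conserved sites tend to be rarer.
#' @param n_diverse Individuals in the diversity panel.
#' @param n_families,family_size Half-sib family structure of the second
#'   panel.
#' @param n_background_snps Neutral genome-wide (non-coding) SNPs added for
#'   the genome-wide kernel.
#' @param missing_rate Genotype missing-call rate.
#' @param n_causal Causal SNPs per trait.
#' @param heritability Trait heritability.
#' @param seed Master seed; one seed yields a byte-identical bundle.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 5L, genes_per_chromosome = 6L,
                       codons_range = c(60L, 140L),
                       n_introns_range = c(1L, 2L),
                       intron_len = c(60L, 150L), utr5_len = c(40L, 80L),
                       utr3_len = c(60L, 120L), intergenic = c(300L, 800L),
                       embed_dim = 16L, sift_missing_rate = 0.1,
                       planted_coef = c(sift_score = -2, gc_content = 1,
                                        distance = 0.8),
                       conserved_bias = 0, frac_intermediate = 0.3,
                       snp_fraction = 0.15, snp_depletion = 0.7,
                       maf_beta_a = 0.8, maf_beta_b = 1.2,
                       maf_coupling = 6, n_diverse = 200L,
                       n_families = 8L, family_size = 25L,
                       n_background_snps = 600L, missing_rate = 0.02,
                       n_causal = 40L, heritability = 0.5, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$heritability >= 0, cfg$heritability <= 1,
            cfg$snp_fraction >= 0, cfg$snp_fraction <= 1,
            cfg$frac_intermediate >= 0, cfg$frac_intermediate <= 1)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

sense_codons <- function() {
  tab <- codon_table()
  names(tab)[tab != "*"]
}

runif_int <- function(rng) if (rng[1] == rng[2]) rng[1] else
  sample(rng[1]:rng[2], 1L)

# Build one gene: sense-strand layout (5'UTR, CDS exons with introns,
# 3'UTR), then mirror coordinates for minus-strand genes.
simulate_gene <- function(gene_id, chrom, offset, strand, cfg) {
  n_codons <- runif_int(cfg$codons_range)
  body <- sample(setdiff(sense_codons(), "ATG"), n_codons - 2L,
                 replace = TRUE)
  cds <- paste(c("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L)),
               collapse = "")
  cds_len <- nchar(cds)
  n_intr <- runif_int(cfg$n_introns_range)
  cuts <- sort(sample(seq_len(cds_len - 1L), n_intr))
  exon_bounds <- cbind(c(1L, cuts + 1L), c(cuts, cds_len))
  intron_seqs <- vapply(seq_len(n_intr), function(i)
    random_dna(runif_int(cfg$intron_len)), "")
  u5 <- random_dna(runif_int(cfg$utr5_len))
  u3 <- random_dna(runif_int(cfg$utr3_len))
  # relative sense-strand coordinates
  feats <- list()
  cursor <- 1L
  add <- function(type, len) {
    feats[[length(feats) + 1L]] <<- data.frame(type = type, start = cursor,
                                               end = cursor + len - 1L)
    cursor <<- cursor + len
  }
  add("five_prime_UTR", nchar(u5))
  pieces <- character(0)
  for (i in seq_len(nrow(exon_bounds))) {
    exon_seq <- substr(cds, exon_bounds[i, 1L], exon_bounds[i, 2L])
    add("CDS", nchar(exon_seq))
    pieces <- c(pieces, exon_seq)
    if (i < nrow(exon_bounds)) {
      add("intron", nchar(intron_seqs[i]))
      pieces <- c(pieces, intron_seqs[i])
    }
  }
  add("three_prime_UTR", nchar(u3))
  rel <- do.call(rbind, feats)
  sense_seq <- paste0(u5, paste(pieces, collapse = ""), u3)
  L <- nchar(sense_seq)
  if (strand == "-") {
    genomic_seq <- revcomp(sense_seq)
    new_start <- L - rel$end + 1L
    rel$end <- L - rel$start + 1L
    rel$start <- new_start
  } else genomic_seq <- sense_seq
  rel <- rel[rel$type != "intron", , drop = FALSE]
  tx_id <- paste0(gene_id, "_t1")
  rows <- rbind(
    data.frame(type = "gene", start = 1L, end = L, id = gene_id,
               parent = NA_character_, stringsAsFactors = FALSE),
    data.frame(type = "mRNA", start = 1L, end = L, id = tx_id,
               parent = gene_id, stringsAsFactors = FALSE),
    data.frame(type = rel$type, start = rel$start, end = rel$end,
               id = NA_character_, parent = tx_id,
               stringsAsFactors = FALSE))
  rows$start <- rows$start + offset - 1L
  rows$end <- rows$end + offset - 1L
  rows$chrom <- chrom
  rows$strand <- strand
  list(features = rows, seq = genomic_seq)
}

#' Simulate a genome with gene models
#'
#' Generates random chromosome sequences carrying non-overlapping genes on
#' both strands, each with 5' UTR, intron-split CDS (length a multiple of
#' 3, clean open reading frame) and 3' UTR. Deterministic given the
#' configuration seed.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector), `features` (flat
#'   feature table, GFF3-ready) and `genes` (gene model list).
#' @export
simulate_genome <- function(config = sim_config()) {
  with_seed(config$seed, {
    genome <- character(0)
    feats <- list()
    for (ci in seq_len(config$n_chromosomes)) {
      chrom <- paste0("chr", ci)
      cursor <- 1L
      chrom_pieces <- character(0)
      for (gi in seq_len(config$genes_per_chromosome)) {
        gap <- runif_int(config$intergenic)
        chrom_pieces <- c(chrom_pieces, random_dna(gap))
        cursor <- cursor + gap
        gene_id <- sprintf("gene_c%d_%02d", ci, gi)
        g <- simulate_gene(gene_id, chrom, cursor,
                           sample(c("+", "-"), 1L), config)
        chrom_pieces <- c(chrom_pieces, g$seq)
        cursor <- cursor + nchar(g$seq)
        feats[[length(feats) + 1L]] <- g$features
      }
      tail_gap <- runif_int(config$intergenic)
      chrom_pieces <- c(chrom_pieces, random_dna(tail_gap))
      genome[chrom] <- paste(chrom_pieces, collapse = "")
    }
    features <- do.call(rbind, feats)
    features$source <- "picnc_sim"
    features$attributes <- ifelse(
      is.na(features$parent), paste0("ID=", features$id),
      ifelse(is.na(features$id), paste0("Parent=", features$parent),
             paste0("ID=", features$id, ";Parent=", features$parent)))
    genes <- build_gene_models(features, genome)
    list(genome = genome, features = features, genes = genes)
  })
}

#' Simulate transposon intervals
#'
#' A handful of labeled intervals per chromosome and family, for the
#' transposon-flag annotation.
#'
#' @param genome Named character vector of contig sequences.
#' @param seed Integer seed.
#' @param per_family Expected intervals per chromosome and family.
#' @return Data frame `chrom`, `start`, `end`, `family`.
#' @export
simulate_transposons <- function(genome, seed = 1L, per_family = 1L) {
  with_seed(seed + 101L, {
    rows <- list()
    for (chrom in names(genome)) {
      L <- nchar(genome[[chrom]])
      for (f in TE_FAMILIES) {
        k <- stats::rpois(1L, per_family)
        if (!k) next
        start <- sample(seq_len(max(1L, L - 900L)), k)
        len <- sample(200:800, k, replace = TRUE)
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = chrom, start = start,
                     end = pmin(L, start + len - 1L), family = f,
                     stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out[order(out$chrom, out$start), ]
  })
}

#' Simulate SIFT-style scores for a mutation table
#'
#' Draws a latent damage score per mutation (stop gains/losses damaging,
#' missense mixed) and emits a noisy SIFT score (low = damaging), with a
#' configurable fraction of missing scores.
#'
#' @param mutations Mutation table from [enumerate_mutations()].
#' @param config A [sim_config()].
#' @return List with `table` (TSV-ready: `chrom`, `pos`, `alt`,
#'   `sift_score`; missing rows dropped) and `damage` (latent truth).
#' @export
simulate_sift <- function(mutations, config = sim_config()) {
  with_seed(config$seed + 202L, {
    n <- nrow(mutations)
    damage <- ifelse(mutations$mutation_type == "missense",
                     stats::rbeta(n, 0.7, 0.7),
                     stats::rbeta(n, 6, 1.5))
    score <- pmin(1, pmax(0, 1 - damage + stats::rnorm(n, 0, 0.1)))
    missing <- stats::runif(n) < config$sift_missing_rate
    tab <- data.frame(chrom = mutations$chrom, pos = mutations$pos,
                      alt = mutations$alt,
                      sift_score = round(score, 4),
                      stringsAsFactors = FALSE)[!missing, , drop = FALSE]
    list(table = tab, damage = damage)
  })
}

#' Simulate conservation scores with planted structure
#'
#' The true conservation probability of each site is a logistic function of
#' its (standardized) annotations under the planted coefficients. Sites are
#' drawn conserved, absent (unaligned) or intermediate, and (N, RS) score
#' rows are emitted consistent with the drawn label: conserved sites get
#' deep trees and near-zero substitution rates, absent sites get no row,
#' and intermediate sites violate exactly one of the two labeling
#' thresholds.
#'
#' @param annotations Annotated mutation table (one row per site; see
#'   [annotate_mutations()]).
#' @param config A [sim_config()].
#' @return List: `scores` (data frame `chrom`, `pos`, `N`, `RS`) and
#'   `truth` (`chrom`, `pos`, `w`, `p1`).
#' @export
simulate_conservation <- function(annotations, config = sim_config()) {
  with_seed(config$seed + 303L, {
    coef <- config$planted_coef
    eta <- rep(config$conserved_bias, nrow(annotations))
    for (nm in names(coef)) {
      col <- annotations[[nm]]
      if (is.null(col)) stop("planted coefficient for absent column ", nm)
      z <- as.numeric(col)
      sdz <- stats::sd(z)
      if (sdz > 0) z <- (z - mean(z)) / sdz
      eta <- eta + coef[[nm]] * z
    }
    p1 <- stats::plogis(eta)
    n <- length(p1)
    conserved <- stats::runif(n) < p1
    intermediate <- !conserved & stats::runif(n) < config$frac_intermediate
    w <- ifelse(conserved, 1L, ifelse(intermediate, NA_integer_, 0L))
    N <- RS <- rep(NA_real_, n)
    idx <- which(conserved)
    N[idx] <- stats::runif(length(idx), 5.5, 16.2)
    RS[idx] <- N[idx] * stats::runif(length(idx), 0.96, 0.999)
    idx <- which(intermediate)
    shallow <- stats::runif(length(idx)) < 0.5
    N[idx] <- ifelse(shallow, stats::runif(length(idx), 0.5, 4.9),
                     stats::runif(length(idx), 5.5, 16.2))
    RS[idx] <- N[idx] * ifelse(shallow,
                               stats::runif(length(idx), 0.96, 0.999),
                               stats::runif(length(idx), 0.3, 0.94))
    emit <- !is.na(N)
    scores <- data.frame(chrom = annotations$chrom[emit],
                         pos = annotations$pos[emit],
                         N = round(N[emit], 4), RS = round(RS[emit], 4),
                         stringsAsFactors = FALSE)
    truth <- data.frame(chrom = annotations$chrom, pos = annotations$pos,
                        w = w, p1 = p1, stringsAsFactors = FALSE)
    list(scores = scores, truth = truth)
  })
}

sim_genotypes_diverse <- function(n_ind, freq) {
  t(vapply(freq, function(f) stats::rbinom(n_ind, 2L, f),
           integer(n_ind)))
}

# Half-sib hybrid panel: RILs from recurrent x donor parents, crossed to a
# common tester. One donor parent per family.
sim_genotypes_families <- function(n_families, family_size, freq) {
  m <- length(freq)
  recurrent <- stats::rbinom(m, 1L, freq)
  tester <- stats::rbinom(m, 1L, freq)
  dosage <- matrix(0L, m, n_families * family_size)
  fam <- integer(0)
  col <- 1L
  for (f in seq_len(n_families)) {
    donor <- stats::rbinom(m, 1L, freq)
    for (i in seq_len(family_size)) {
      pick <- stats::rbinom(m, 1L, 0.5)
      ril <- ifelse(pick == 1L, donor, recurrent)
      dosage[, col] <- ril + tester
      fam <- c(fam, f)
      col <- col + 1L
    }
  }
  list(dosage = dosage, families = paste0("fam", fam))
}

#' Simulate SNPs and hybrid-panel genotypes
#'
#' Places SNPs at a random subset of the coding sites (depleted at
#' conserved sites), draws minor allele frequencies from a Beta
#' distribution whose mean decreases with true conservation probability,
#' and generates 0/1/2 genotypes for a diversity panel and a half-sib
#' family panel, plus neutral background SNPs for the genome-wide kernel.
#'
#' @param mutations Mutation table (one candidate row per coding site).
#' @param truth Truth table from [simulate_conservation()].
#' @param genome Named character vector (for background SNP placement).
#' @param config A [sim_config()].
#' @return List with `sites` (coding SNPs: coordinates, alleles, `maf`,
#'   `p1`, mutation metadata), `background_sites`, per-panel dosage
#'   matrices (`coding_*`, `background_*`, individuals in columns),
#'   `families` labels, and the generating frequencies.
#' @export
simulate_snps <- function(mutations, truth, genome,
                          config = sim_config()) {
  with_seed(config$seed + 404L, {
    stopifnot(nrow(mutations) == nrow(truth))
    n_sites <- nrow(mutations)
    n_snp <- round(config$snp_fraction * n_sites)
    prob <- 1 - config$snp_depletion * truth$p1
    pick <- sort(sample.int(n_sites, n_snp, prob = prob))
    maf <- 0.5 * stats::rbeta(n_snp, config$maf_beta_a,
                              config$maf_beta_b +
                                config$maf_coupling * truth$p1[pick])
    maf <- pmax(maf, 0.01)
    sites <- mutations[pick, c("chrom", "pos", "ref", "alt", "gene_id")]
    sites$maf <- maf
    sites$p1 <- truth$p1[pick]
    sites$w_true <- truth$w[pick]
    rownames(sites) <- NULL
    # neutral background SNPs on the same chromosomes
    nb <- config$n_background_snps
    bchrom <- sample(names(genome), nb, replace = TRUE)
    bpos <- vapply(bchrom, function(ch)
      sample.int(nchar(genome[[ch]]), 1L), 0L)
    bmaf <- pmax(0.5 * stats::rbeta(nb, config$maf_beta_a,
                                    config$maf_beta_b), 0.01)
    background <- data.frame(chrom = bchrom, pos = bpos, maf = bmaf,
                             stringsAsFactors = FALSE)
    n_div <- config$n_diverse
    div_cod <- sim_genotypes_diverse(n_div, maf)
    div_bg <- sim_genotypes_diverse(n_div, bmaf)
    fam_cod <- sim_genotypes_families(config$n_families,
                                      config$family_size, maf)
    fam_bg_seed <- sim_genotypes_families(config$n_families,
                                          config$family_size, bmaf)
    mask <- function(x) {
      x[stats::runif(length(x)) < config$missing_rate] <- NA_integer_
      x
    }
    div_ids <- sprintf("div%03d", seq_len(n_div))
    fam_ids <- sprintf("fam%03d", seq_len(ncol(fam_cod$dosage)))
    dimnames(div_cod) <- list(NULL, div_ids)
    dimnames(div_bg) <- list(NULL, div_ids)
    dimnames(fam_cod$dosage) <- list(NULL, fam_ids)
    dimnames(fam_bg_seed$dosage) <- list(NULL, fam_ids)
    list(sites = sites, background_sites = background,
         coding_diverse = mask(div_cod), coding_family = mask(fam_cod$dosage),
         background_diverse = div_bg,
         background_family = fam_bg_seed$dosage,
         families = fam_cod$families)
  })
}

#' Simulate phenotypes over hybrid panels
#'
#' Phenotypes are the sum of effects at causal SNPs (drawn preferentially
#' among truly conserved nonsynonymous sites) plus Gaussian noise scaled to
#' the target heritability. The same causal architecture underlies both
#' panels, so cross-panel prediction is meaningful.
#'
#' @param snps Output of [simulate_snps()].
#' @param config A [sim_config()].
#' @return List with per-panel phenotype vectors (`y_diverse`,
#'   `y_family`), causal indices (into the coding SNP table), effects and
#'   the residual standard deviation used.
#' @export
simulate_phenotypes <- function(snps, config = sim_config()) {
  with_seed(config$seed + 505L, {
    m <- nrow(snps$sites)
    conserved <- !is.na(snps$sites$w_true) & snps$sites$w_true == 1L
    prob <- 0.05 + conserved
    n_causal <- min(config$n_causal, m)
    causal <- sort(sample.int(m, n_causal, prob = prob))
    beta <- stats::rnorm(n_causal)
    impute0 <- function(X) { X[is.na(X)] <- 0L; X }
    g_div <- drop(crossprod(impute0(snps$coding_diverse)[causal, ,
                                                         drop = FALSE],
                            beta))
    g_fam <- drop(crossprod(impute0(snps$coding_family)[causal, ,
                                                        drop = FALSE],
                            beta))
    h2 <- config$heritability
    if (h2 == 0) stop("heritability 0 leaves no genetic signal to scale")
    # scale the noise per panel, so each panel realizes the target
    # heritability despite their different genetic variances
    sd_div <- sqrt(stats::var(g_div) * (1 - h2) / h2)
    sd_fam <- sqrt(stats::var(g_fam) * (1 - h2) / h2)
    y_div <- g_div + stats::rnorm(length(g_div), 0, sd_div)
    y_fam <- g_fam + stats::rnorm(length(g_fam), 0, sd_fam)
    list(y_diverse = y_div, y_family = y_fam, causal = causal,
         beta = beta, sd_e = c(diverse = sd_div, family = sd_fam),
         genetic_diverse = g_div, genetic_family = g_fam)
  })
}

#' Generate the complete synthetic fixture bundle
#'
#' Runs the whole generator: genome and gene models, candidate mutations,
#' SIFT scores, transposons, annotations, conservation scores with planted
#' structure, SNPs with panel genotypes, and phenotypes. One master seed
#' yields a fully deterministic bundle.
#'
#' @param config A [sim_config()].
#' @return A list bundling every simulated component (see the individual
#'   `simulate_*` functions), plus `mutations` with `is_snp` set and the
#'   ready-to-train `annotations` table.
#' @export
simulate_picnc_data <- function(config = sim_config()) {
  gen <- simulate_genome(config)
  mutations <- enumerate_mutations(gen$genome, gen$genes, snps = NULL,
                                   mode = "monomorphic", per_site = 1L,
                                   seed = config$seed)
  te <- simulate_transposons(gen$genome, seed = config$seed)
  sift <- simulate_sift(mutations, config)
  kidx <- kmer_index(gen$genome)
  annotations <- annotate_mutations(gen$genome, mutations, gen$genes,
                                    te = te, sift = sift$table,
                                    D = config$embed_dim, kmer_idx = kidx)
  cons <- simulate_conservation(annotations, config)
  snps <- simulate_snps(mutations, cons$truth, gen$genome, config)
  phen <- simulate_phenotypes(snps, config)
  snp_key <- paste(snps$sites$chrom, snps$sites$pos)
  is_snp <- paste(mutations$chrom, mutations$pos) %in% snp_key
  mutations$is_snp <- is_snp
  annotations$is_snp <- is_snp
  list(genome = gen$genome, features = gen$features, genes = gen$genes,
       mutations = mutations, te = te, sift = sift,
       annotations = annotations, scores = cons$scores,
       truth = cons$truth, snps = snps, phenotypes = phen,
       config = config)
}

#' Write a fixture bundle to disk
#'
#' Serializes the bundle through the package's standard-format writers
#' (FASTA, GFF3, BED, VCF, TSV) plus a ground-truth JSON, exercising every
#' reader in the package on re-import.
#'
#' @param bundle Output of [simulate_picnc_data()].
#' @param dir Output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gff = file.path(dir, "genes.gff3"),
             scores = file.path(dir, "scores.tsv"),
             sift = file.path(dir, "sift.tsv"),
             te = file.path(dir, "transposons.bed"),
             vcf_diverse = file.path(dir, "panel_diverse.vcf"),
             vcf_family = file.path(dir, "panel_family.vcf"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.json"))
  write_fasta(bundle$genome, paths["genome"])
  write_gff3(bundle$features, paths["gff"])
  write_conservation_scores(bundle$scores, paths["scores"])
  utils::write.table(bundle$sift$table, paths["sift"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  te <- bundle$te
  writeLines(sprintf("%s\t%d\t%d\t%s", te$chrom, te$start - 1L, te$end,
                     te$family), paths["te"])
  sites <- bundle$snps$sites[c("chrom", "pos", "ref", "alt")]
  write_vcf(sites, bundle$snps$coding_diverse, paths["vcf_diverse"])
  write_vcf(sites, bundle$snps$coding_family, paths["vcf_family"])
  phen <- rbind(
    data.frame(id = colnames(bundle$snps$coding_diverse),
               panel = "diverse", family = NA_character_,
               y = bundle$phenotypes$y_diverse, stringsAsFactors = FALSE),
    data.frame(id = colnames(bundle$snps$coding_family),
               panel = "family", family = bundle$snps$families,
               y = bundle$phenotypes$y_family, stringsAsFactors = FALSE))
  utils::write.table(phen, paths["phenotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(seed = bundle$config$seed,
                causal = bundle$snps$sites[bundle$phenotypes$causal,
                                           c("chrom", "pos")],
                beta = bundle$phenotypes$beta,
                p1 = bundle$truth$p1, w = bundle$truth$w)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
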