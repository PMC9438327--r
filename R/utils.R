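# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so simulation helpers compose predictably.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic 31-bit polynomial hash of a character scalar; used for
# site-keyed draws and the toy embedder's bucket assignment. Kept in plain R
# so tests can re-derive it independently.
string_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2147483647
  h
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(rev(unname(COMPLEMENT[chars])), collapse = "")
}

complement_base <- function(base) unname(COMPLEMENT[base])

# Standard nuclear genetic code, codons in DNA alphabet; '*' marks stop.
codon_table <- function() {
  tab <- Biostrings::GENETIC_CODE
  names(tab) <- chartr("U", "T", names(tab))
  tab
}

translate_codon <- function(codon) {
  tab <- codon_table()
  aa <- tab[toupper(codon)]
  if (any(is.na(aa))) stop("invalid codon(s): ",
                           paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

# Translate a coding-strand DNA string codon by codon, stopping at the first
# stop codon. Returns the residues before the stop; attribute `terminated`
# records whether a stop codon was actually reached.
translate_until_stop <- function(seq) {
  n_codon <- nchar(seq) %/% 3L
  if (n_codon == 0L) {
    out <- ""
    attr(out, "terminated") <- FALSE
    return(out)
  }
  starts <- 3L * seq_len(n_codon) - 2L
  codons <- substring(seq, starts, starts + 2L)
  aas <- translate_codon(codons)
  stop_at <- which(aas == "*")
  if (length(stop_at)) {
    out <- paste(aas[seq_len(stop_at[1L] - 1L)], collapse = "")
    attr(out, "terminated") <- TRUE
  } else {
    out <- paste(aas, collapse = "")
    attr(out, "terminated") <- FALSE
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
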