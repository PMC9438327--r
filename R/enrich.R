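#' Prioritize genes from site-level conservation weights
#'
#' A gene is selected when it contains at least one site passing the rule:
#' either a percentile threshold on predicted conservation (using the same
#' nearest-rank / strict-retention convention as [truncate_weights()]), or
#' observed conservation equal to 1.
#'
#' @param w Site weight vector (predicted conservation), or observed 0/1
#'   labels when `rule = "observed"`.
#' @param gene_ids Gene id of each site.
#' @param q Percentile threshold (percentile rule).
#' @param rule `"percentile"` or `"observed"`.
#' @return Character vector of selected gene ids.
#' @export
prioritize_genes <- function(w, gene_ids, q = 0,
                             rule = c("percentile", "observed")) {
  rule <- match.arg(rule)
  stopifnot(length(w) == length(gene_ids))
  pass <- if (rule == "percentile") truncate_weights(w, q) > 0
          else !is.na(w) & w == 1
  sort(unique(gene_ids[pass]))
}

#' Expression enrichment of a prioritized gene set
#'
#' For each expression metric, the difference in mean `log(x + 1)`
#' expression between the selected genes and all genes, with a Welch
#' two-sample t 95% confidence interval.
#'
#' @param selected Character vector of selected gene ids.
#' @param expression Data frame with `gene_id` and one column per
#'   non-negative expression metric.
#' @return Data frame: `metric`, `difference`, `lower`, `upper`,
#'   `p_value`.
#' @export
expression_enrichment <- function(selected, expression) {
  if (!length(selected)) stop("selected gene set is empty")
  metrics <- setdiff(names(expression), "gene_id")
  sel <- expression$gene_id %in% selected
  if (!any(sel)) stop("no selected gene has expression data")
  out <- lapply(metrics, function(m) {
    x <- log1p(expression[[m]])
    tt <- stats::t.test(x[sel], x, var.equal = FALSE)
    data.frame(metric = m, difference = unname(diff(rev(tt$estimate))),
               lower = tt$conf.int[1], upper = tt$conf.int[2],
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Term (GO/pathway) enrichment by Fisher's exact test
#'
#' Tests over-representation of each annotation term among selected genes
#' with a two-sided Fisher exact test on the 2x2 selected-by-membership
#' table, discarding terms with fewer than `min_positives` member genes in
#' the universe. False discovery rates are Benjamini-Hochberg over the
#' tested terms.
#'
#' @param selected Character vector of selected gene ids.
#' @param memberships Data frame with `gene_id`, `term_id` and optionally
#'   `term_name`.
#' @param universe Gene universe (default: all genes in `memberships`);
#'   typically the genes containing analyzed nonsynonymous SNPs.
#' @param min_positives Minimum term size (default 20).
#' @return Data frame sorted by FDR: `term_id`, `term_name`, `observed`,
#'   `expected`, `enrichment`, `p_value`, `fdr`.
#' @export
fisher_enrichment <- function(selected, memberships,
                              universe = unique(memberships$gene_id),
                              min_positives = 20L) {
  memberships <- memberships[memberships$gene_id %in% universe, ,
                             drop = FALSE]
  selected <- intersect(selected, universe)
  n_univ <- length(universe)
  n_sel <- length(selected)
  terms <- split(memberships$gene_id, memberships$term_id)
  terms <- terms[vapply(terms, function(g) length(unique(g)), 0L) >=
                   min_positives]
  if (!length(terms))
    return(data.frame(term_id = character(), term_name = character(),
                      observed = integer(), expected = numeric(),
                      enrichment = numeric(), p_value = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  names_map <- if ("term_name" %in% names(memberships))
    memberships$term_name[match(names(terms), memberships$term_id)]
  else names(terms)
  rows <- lapply(seq_along(terms), function(i) {
    in_term <- unique(terms[[i]])
    a <- length(intersect(selected, in_term))
    b <- n_sel - a
    c_ <- length(in_term) - a
    d <- n_univ - n_sel - c_
    expected <- n_sel * length(in_term) / n_univ
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2L),
                            alternative = "two.sided")$p.value
    data.frame(term_id = names(terms)[i], term_name = names_map[i],
               observed = a, expected = expected,
               enrichment = a / expected, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$fdr, out$p_value), ]
}

#' Per-gene nonsynonymous/synonymous SNP statistics
#'
#' The ratio `Pn / Ps` and the proportion `Pn / (Pn + Ps)` of segregating
#' nonsynonymous to synonymous SNPs, computed only for genes with at least
#' `min_ps` synonymous SNPs (others are marked excluded).
#'
#' @param gene_id Gene ids.
#' @param pn,ps Counts of segregating nonsynonymous and synonymous SNPs.
#' @param min_ps Minimum synonymous count for inclusion (default 5).
#' @return Data frame: `gene_id`, `pn`, `ps`, `ratio`, `proportion`,
#'   `excluded`.
#' @export
pnps <- function(gene_id, pn, ps, min_ps = 5L) {
  stopifnot(length(gene_id) == length(pn), length(pn) == length(ps),
            all(pn >= 0), all(ps >= 0))
  excluded <- ps < min_ps
  data.frame(gene_id = gene_id, pn = pn, ps = ps,
             ratio = ifelse(excluded, NA_real_, pn / ps),
             proportion = ifelse(excluded, NA_real_, pn / (pn + ps)),
             excluded = excluded, stringsAsFactors = FALSE)
}
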