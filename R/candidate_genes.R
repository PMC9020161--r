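#' Aberration G-score for one gene in one subtype
#'
#' A transparent surrogate for the GISTIC G-score: the product of the
#' frequency of copy-number aberration in the subtype and the mean absolute
#' aberration amplitude over the aberrant subtype samples. A sample is
#' aberrant when its absolute copy-number log-ratio is at least
#' `amp_threshold`; amplification and deletion are pooled.
#'
#' @param copy_number_row Named numeric vector of log-ratios, one per sample.
#' @param subtype_samples Character vector of sample ids in the subtype.
#' @param amp_threshold Positive log-ratio magnitude defining aberration
#'   (default 0.5).
#' @return List with `g_score` and `aberrant_count_in`. `g_score` is 0 iff no
#'   subtype sample is aberrant.
#' @examples
#' gscore(c(s1 = 1, s2 = 1, s3 = 0, s4 = 0), paste0("s", 1:4))  # 0.5
#' @export
gscore <- function(copy_number_row, subtype_samples, amp_threshold = 0.5) {
  stopifnot(amp_threshold > 0)
  if (length(subtype_samples) == 0L) stop("subtype has no samples")
  x <- copy_number_row[subtype_samples]
  ab <- abs(x) >= amp_threshold
  k <- sum(ab)
  g <- if (k == 0L) 0 else (k / length(x)) * mean(abs(x[ab]))
  list(g_score = g, aberrant_count_in = as.integer(k))
}

#' Fisher's exact test for subtype-specific aberration
#'
#' Two-sided Fisher's exact p-value for the 2x2 table of
#' aberrant / non-aberrant counts inside versus outside the subtype.
#'
#' @param aberrant_in,n_in Aberrant count and total inside the subtype.
#' @param aberrant_out,n_out Aberrant count and total outside the subtype.
#' @return p-value in \[0, 1\].
#' @export
aberration_significance <- function(aberrant_in, n_in, aberrant_out, n_out) {
  stopifnot(aberrant_in >= 0, aberrant_out >= 0,
            aberrant_in <= n_in, aberrant_out <= n_out)
  if (n_in == 0L || n_out == 0L) stop("both groups must be non-empty")
  tab <- matrix(c(aberrant_in, n_in - aberrant_in,
                  aberrant_out, n_out - aberrant_out), nrow = 2L)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Exclude common copy-number variant genes
#'
#' Keeps only genes that have somatic copy-number aberration but no common
#' germline copy-number variation: plain set difference against the
#' common-variant catalogue.
#'
#' @param genes Character vector of gene symbols.
#' @param common_variant_genes Character vector of common-variant genes.
#' @return `genes` with common-variant genes removed.
#' @export
filter_common_variants <- function(genes, common_variant_genes) {
  setdiff(genes, common_variant_genes)
}

#' Rank genes by chi-square separation of a subtype
#'
#' Per gene, expression values are discretized into `n_bins` equal-frequency
#' bins over all samples; the chi-square statistic (no continuity
#' correction) of the bins x (subtype vs rest) contingency table measures
#' how well the gene separates the subtype. Genes are returned sorted by
#' statistic descending, ties broken by gene symbol ascending. A constant
#' gene has statistic 0.
#'
#' @param expression Numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns.
#' @param labels Named character vector mapping sample id to subtype id.
#' @param subtype Subtype id to separate from the rest.
#' @param n_bins Number of equal-frequency bins (default 3, minimum 2).
#' @return data.frame with columns `gene`, `chi2_statistic`, `rank`.
#' @export
chi2_rank <- function(expression, labels, subtype, n_bins = 3L) {
  stopifnot(n_bins >= 2L)
  samples <- colnames(expression)
  stopifnot(all(samples %in% names(labels)))
  grp <- factor(labels[samples] == subtype, levels = c(FALSE, TRUE))
  if (sum(grp == TRUE) == 0L) stop("subtype not present in labels: ", subtype)

  stat <- apply(expression, 1L, function(x) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                                 names = FALSE, type = 7))
    if (length(br) < 3L) return(0)  # constant / near-constant gene
    bins <- cut(x, breaks = br, include.lowest = TRUE)
    tab <- table(bins, grp)
    if (nrow(tab) < 2L) return(0)
    suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  })
  ord <- order(-stat, rownames(expression))
  data.frame(gene = rownames(expression)[ord],
             chi2_statistic = unname(stat[ord]),
             rank = seq_along(stat),
             stringsAsFactors = FALSE)
}

#' Select per-subtype candidate disease genes
#'
#' Implements the two-arm candidate-gene selection: (1) the copy-number arm
#' keeps genes that have aberration but no common variant, scores them with
#' [gscore()], and tests subtype-specificity with Fisher's exact test
#' (Benjamini-Hochberg adjusted across tested genes by default); (2) the
#' expression arm ranks all genes by [chi2_rank()] and keeps the top N,
#' where N is the size of the copy-number arm. The candidate set is the
#' intersection of the two arms.
#'
#' @param cohort List with `copy_number` and `expression` (gene x sample
#'   matrices sharing columns) and `labels` (named character vector
#'   sample -> subtype).
#' @param variants Character vector of common-variant genes to exclude.
#' @param subtype Subtype id.
#' @param amp_threshold Aberration log-ratio threshold (default 0.5).
#' @param alpha Significance level on (adjusted) Fisher p-values
#'   (default 0.05).
#' @param n_bins Bins for the chi-square ranking (default 3).
#' @param adjust Multiple-testing adjustment: `"BH"` (default) or `"none"`.
#' @return An object of class `candidate_gene_set`: list with `subtype`,
#'   `genes` (sorted character vector), `n_cna` (N of the copy-number arm),
#'   `cna_genes`, `ge_genes`, and `stats` (per-gene data.frame with
#'   `g_score`, `p_value`, `p_adjusted`, aberrant counts).
#' @export
select_candidates <- function(cohort, variants, subtype,
                              amp_threshold = 0.5, alpha = 0.05,
                              n_bins = 3L, adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  cn <- cohort$copy_number
  ge <- cohort$expression
  labels <- cohort$labels
  stopifnot(identical(colnames(cn), colnames(ge)),
            all(colnames(cn) %in% names(labels)))
  if (!subtype %in% labels[colnames(cn)]) {
    stop("subtype not present in labels: ", subtype)
  }
  samples <- colnames(cn)
  in_s <- samples[labels[samples] == subtype]
  out_s <- setdiff(samples, in_s)

  tested <- filter_common_variants(rownames(cn), variants)
  ab <- abs(cn[tested, , drop = FALSE]) >= amp_threshold
  k_in <- rowSums(ab[, in_s, drop = FALSE])
  k_out <- rowSums(ab[, out_s, drop = FALSE])
  gs <- vapply(tested, function(g) {
    gscore(cn[g, ], in_s, amp_threshold)$g_score
  }, numeric(1))
  pv <- vapply(tested, function(g) {
    aberration_significance(k_in[[g]], length(in_s), k_out[[g]], length(out_s))
  }, numeric(1))
  padj <- if (adjust == "BH") stats::p.adjust(pv, method = "BH") else pv

  cna_genes <- sort(tested[padj <= alpha & k_in > 0])
  n_cna <- length(cna_genes)
  if (n_cna == 0L) {
    warning("no gene passes the copy-number significance filter for subtype ",
            subtype)
    ge_genes <- character()
  } else {
    rk <- chi2_rank(ge, labels, subtype, n_bins = n_bins)
    ge_genes <- rk$gene[seq_len(min(n_cna, nrow(rk)))]
  }
  cand <- sort(intersect(cna_genes, ge_genes))

  structure(list(
    subtype = subtype,
    genes = cand,
    n_cna = n_cna,
    cna_genes = cna_genes,
    ge_genes = ge_genes,
    stats = data.frame(gene = tested, g_score = unname(gs),
                       p_value = unname(pv), p_adjusted = unname(padj),
                       aberrant_count_in = unname(k_in),
                       aberrant_count_out = unname(k_out),
                       stringsAsFactors = FALSE)
  ), class = "candidate_gene_set")
}

#' @export
print.candidate_gene_set <- function(x, ...) {
  cat("Candidate genes for subtype", x$subtype, ":", length(x$genes),
      "genes (copy-number arm N =", x$n_cna, ")\n")
  invisible(x)
}

#' Write a candidate gene set with provenance columns
#'
#' @param cand A `candidate_gene_set`.
#' @param path Output TSV path.
#' @export
write_candidates <- function(cand, path) {
  stopifnot(inherits(cand, "candidate_gene_set"))
  genes <- sort(union(cand$cna_genes, cand$ge_genes))
  utils::write.table(
    data.frame(gene = genes,
               from_cna = as.integer(genes %in% cand$cna_genes),
               from_ge = as.integer(genes %in% cand$ge_genes),
               candidate = as.integer(genes %in% cand$genes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
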