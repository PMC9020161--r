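#' Read a drug-drug interaction table
#'
#' A local surrogate for an interaction checker: a TSV with columns
#' `drug1`, `drug2`, `severity` (one of minor, moderate, major). Pairs are
#' stored order-independently; self-pairs are rejected.
#'
#' @param path TSV path.
#' @return Object of class `interaction_table`: data.frame with `drug1`,
#'   `drug2`, `severity`, `key`.
#' @export
read_interaction_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  interaction_table(df$drug1, df$drug2, df$severity)
}

#' Construct an interaction table from vectors
#'
#' @param drug1,drug2 Drug id vectors.
#' @param severity Severity labels in `{minor, moderate, major}`.
#' @return An `interaction_table`.
#' @export
interaction_table <- function(drug1 = character(), drug2 = character(),
                              severity = character()) {
  stopifnot(length(drug1) == length(drug2),
            length(drug1) == length(severity))
  if (any(drug1 == drug2)) stop("self-pairs are not allowed")
  bad <- setdiff(severity, c("minor", "moderate", "major"))
  if (length(bad) > 0L) {
    stop("unknown severity label(s): ", paste(unique(bad), collapse = ", "))
  }
  df <- data.frame(drug1 = pmin(drug1, drug2), drug2 = pmax(drug1, drug2),
                   severity = severity, stringsAsFactors = FALSE)
  df$key <- pair_key(df$drug1, df$drug2)
  df <- df[!duplicated(df$key), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Screen all drug pairs against a disease signature
#'
#' For every unordered pair of profiles belonging to two different drugs,
#' forms the additive combined profile, selects its top-`k` genes, builds
#' the pair's drug-disease network, and computes the combined repurposing
#' score. Each record also carries the two single-condition scores and the
#' three ranks (combined rank among defined pairs, single ranks among the
#' screened conditions). Pairs with an undefined combined score are dropped
#' (their count is kept in the `n_undefined` attribute).
#'
#' @param profiles List of `perturbation_profile` objects (>= 2 drugs).
#' @param signature `disease_signature`.
#' @param disease_genes Candidate disease genes.
#' @param ughp A `ughp` object.
#' @param k Top combined genes (default 50, same as single drugs).
#' @param directed Directed traversal flag.
#' @param single_scores Optional precomputed list of `repurposing_score`
#'   objects for `profiles` (computed if omitted).
#' @return data.frame of class `pair_records` with columns `drug1_id`,
#'   `drug2_id`, `drug1_key`, `drug2_key`, `combined_r`, `single_r1`,
#'   `single_r2`, `combined_rank`, `rank1`, `rank2`, `n_genes_scored`;
#'   attributes `n_pairs_scored`, `n_undefined`.
#' @export
screen_pairs <- function(profiles, signature, disease_genes, ughp,
                         k = 50L, directed = FALSE, single_scores = NULL) {
  if (length(profiles) < 2L) stop("need at least two profiles")
  if (is.null(single_scores)) {
    single_scores <- score_library(profiles, signature, disease_genes, ughp,
                                   k = k, directed = directed)
  }
  stopifnot(length(single_scores) == length(profiles))
  single_rank <- rank_drugs(single_scores)
  keys <- vapply(profiles, `[[`, character(1), "key")
  r_single <- stats::setNames(
    vapply(single_scores, function(s) if (s$defined) s$r else NA_real_,
           numeric(1)), keys)
  rk_single <- stats::setNames(single_rank$rank, single_rank$drug_key)

  idx <- utils::combn(length(profiles), 2L)
  rows <- vector("list", ncol(idx))
  n_undef <- 0L
  for (j in seq_len(ncol(idx))) {
    p1 <- profiles[[idx[1L, j]]]
    p2 <- profiles[[idx[2L, j]]]
    if (p1$drug_id == p2$drug_id) next  # two conditions of the same drug
    # canonical order for order-independence of the output
    if (p1$key > p2$key) { tmp <- p1; p1 <- p2; p2 <- tmp }
    comb <- combine_profiles(p1, p2)
    dg <- select_drug_genes(comb, k = k)
    ddn <- build_ddn(ughp, dg, disease_genes, directed = directed)
    sc <- score_ddn(ddn, comb, signature)
    if (!sc$defined) { n_undef <- n_undef + 1L; next }
    rows[[j]] <- data.frame(
      drug1_id = p1$drug_id, drug2_id = p2$drug_id,
      drug1_key = p1$key, drug2_key = p2$key,
      combined_r = sc$r,
      single_r1 = unname(r_single[p1$key]),
      single_r2 = unname(r_single[p2$key]),
      rank1 = unname(rk_single[p1$key])[1L] %||% NA_integer_,
      rank2 = unname(rk_single[p2$key])[1L] %||% NA_integer_,
      n_genes_scored = sc$n_genes_scored,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    rec <- data.frame(drug1_id = character(), drug2_id = character(),
                      drug1_key = character(), drug2_key = character(),
                      combined_r = numeric(), single_r1 = numeric(),
                      single_r2 = numeric(), combined_rank = integer(),
                      rank1 = integer(), rank2 = integer(),
                      n_genes_scored = integer(), stringsAsFactors = FALSE)
  } else {
    rec <- do.call(rbind, rows)
    rec <- rec[order(rec$combined_r, rec$drug1_key, rec$drug2_key), ,
               drop = FALSE]
    rec$combined_rank <- seq_len(nrow(rec))
    rownames(rec) <- NULL
    rec <- rec[, c("drug1_id", "drug2_id", "drug1_key", "drug2_key",
                   "combined_r", "single_r1", "single_r2", "combined_rank",
                   "rank1", "rank2", "n_genes_scored")]
  }
  attr(rec, "n_pairs_scored") <- sum(!vapply(
    seq_len(ncol(idx)), function(j) {
      profiles[[idx[1L, j]]]$drug_id == profiles[[idx[2L, j]]]$drug_id
    }, logical(1)))
  attr(rec, "n_undefined") <- n_undef
  class(rec) <- c("pair_records", "data.frame")
  rec
}

#' Remove drug pairs with known interactions (post-verification)
#'
#' Scored pairs whose drugs appear in the interaction table at a blocked
#' severity are removed after scoring, so the result tables can be
#' re-filtered against an updated interaction catalogue without rescoring.
#' Removals are reported with their severity via `message()` and returned in
#' the `removed` attribute.
#'
#' @param records `pair_records` from [screen_pairs()].
#' @param table An `interaction_table`.
#' @param blocked_severities Severities to block (default all three).
#' @return Filtered records; attribute `removed` holds the dropped rows with
#'   a `severity` column.
#' @export
filter_interactions <- function(records, table,
                                blocked_severities = c("minor", "moderate",
                                                       "major")) {
  stopifnot(inherits(table, "interaction_table"))
  if (nrow(records) == 0L || nrow(table) == 0L) {
    attr(records, "removed") <- records[0, , drop = FALSE]
    return(records)
  }
  sev <- stats::setNames(table$severity, table$key)
  rec_key <- pair_key(records$drug1_id, records$drug2_id)
  rec_sev <- sev[rec_key]
  flagged <- !is.na(rec_sev)
  drop <- flagged & rec_sev %in% blocked_severities
  warn_only <- flagged & !drop
  if (any(warn_only)) {
    warning(sum(warn_only), " pair(s) have a known interaction at a",
            " non-blocked severity and were retained")
  }
  if (any(drop)) {
    removed <- records[drop, , drop = FALSE]
    removed$severity <- unname(rec_sev[drop])
    message("removed ", sum(drop), " pair(s) with blocked interactions: ",
            paste(sprintf("%s/%s [%s]", removed$drug1_id, removed$drug2_id,
                          removed$severity), collapse = "; "))
  } else {
    removed <- records[0, , drop = FALSE]
    removed$severity <- character(0)
  }
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  attr(out, "n_pairs_scored") <- attr(records, "n_pairs_scored")
  attr(out, "n_undefined") <- attr(records, "n_undefined")
  class(out) <- class(records)
  out
}

#' Pairs with a better anti-correlation than the best single drug
#'
#' Keeps pair records whose combined score is strictly more negative than
#' the best (most negative) defined single-drug score, sorted ascending and
#' truncated to at most `cap` pairs.
#'
#' @param records `pair_records` (normally post [filter_interactions()]).
#' @param single_scores List of `repurposing_score` objects or a ranking
#'   data.frame from [rank_drugs()].
#' @param cap Maximum number of pairs to report (default 100).
#' @return Subset of `records`.
#' @export
pairs_beating_best_single <- function(records, single_scores, cap = 100L) {
  if (is.data.frame(single_scores)) {
    r <- single_scores$score
  } else {
    r <- vapply(Filter(function(s) isTRUE(s$defined), single_scores),
                `[[`, numeric(1), "r")
  }
  if (length(r) == 0L) stop("no defined single-drug scores")
  best <- min(r)
  keep <- records[records$combined_r < best, , drop = FALSE]
  keep <- keep[order(keep$combined_r, keep$drug1_key, keep$drug2_key), ,
               drop = FALSE]
  keep <- utils::head(keep, cap)
  rownames(keep) <- NULL
  keep
}
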