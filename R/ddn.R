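#' Build a drug-disease network (DDN)
#'
#' Maps drug genes and disease genes back onto the unified pathway graph and
#' collects, for every (drug gene, disease gene) pair, all nodes lying on
#' any minimum-hop path between them. The DDN node set is the union of the
#' mapped drug genes, the mapped disease genes, and those path nodes;
#' its size is bounded above by `G_dr + G_di + G_i` (the bound is attained
#' exactly when no gene plays two roles). Genes absent from the graph are
#' dropped with their counts recorded; a pair with no connecting path
#' contributes only its two endpoints and is counted in `unreachable_pairs`.
#'
#' A gene that is both a drug and a disease gene is categorized once (role
#' `both`) and never double-counted.
#'
#' @param ughp A `ughp` object.
#' @param drug_genes Character vector of drug genes.
#' @param disease_genes Character vector of disease genes.
#' @param directed Traverse edges directionally (default `FALSE`).
#' @return Object of class `ddn`: list with `drug_genes`, `disease_genes`,
#'   `both_genes`, `intermediate_genes`, `nodes`, `unreachable_pairs`,
#'   `n_drug_unmapped`, `n_disease_unmapped`, `degenerate` (TRUE when either
#'   side maps to nothing, signalling an undefined score downstream).
#' @export
build_ddn <- function(ughp, drug_genes, disease_genes, directed = FALSE) {
  stopifnot(inherits(ughp, "ughp"))
  if (length(ughp$nodes) == 0L) stop("empty pathway graph")
  drug_genes <- unique(drug_genes)
  disease_genes <- unique(disease_genes)
  dr <- intersect(drug_genes, ughp$nodes)
  di <- intersect(disease_genes, ughp$nodes)
  n_drug_unmapped <- length(drug_genes) - length(dr)
  n_disease_unmapped <- length(disease_genes) - length(di)

  if (length(dr) == 0L || length(di) == 0L) {
    return(structure(list(
      drug_genes = sort(dr), disease_genes = sort(di),
      both_genes = character(), intermediate_genes = character(),
      nodes = sort(union(dr, di)), unreachable_pairs = 0L,
      n_drug_unmapped = n_drug_unmapped,
      n_disease_unmapped = n_disease_unmapped,
      directed = directed, degenerate = TRUE), class = "ddn"))
  }

  mode_fwd <- if (directed) "out" else "all"
  mode_bwd <- if (directed) "in" else "all"
  ds <- .ughp_dist(ughp, mode_fwd, from = dr)   # |dr| x |V|
  dt <- .ughp_dist(ughp, mode_bwd, from = di)   # |di| x |V|, d(v -> t)

  on_path <- rep(FALSE, length(ughp$nodes))
  names(on_path) <- ughp$nodes
  unreachable <- 0L
  for (i in seq_along(dr)) {
    dsv <- ds[i, ]
    dst <- dsv[di]
    reach <- is.finite(dst)
    unreachable <- unreachable + sum(!reach)
    if (!any(reach)) next
    # v on a shortest s->t path iff d(s,v) + d(v,t) == d(s,t)
    tot <- sweep(dt[reach, , drop = FALSE], 2L, dsv, `+`)
    hit <- tot == dst[reach]
    hit[!is.finite(tot)] <- FALSE
    on_path <- on_path | (colSums(hit) > 0L)
  }

  nodes <- sort(union(union(dr, di), names(on_path)[on_path]))
  both <- intersect(dr, di)
  inter <- setdiff(nodes, union(dr, di))
  # structural upper bound on the node count, asserted on every DDN
  stopifnot(length(nodes) <= length(dr) + length(di) + length(inter))

  structure(list(drug_genes = sort(dr), disease_genes = sort(di),
                 both_genes = sort(both), intermediate_genes = inter,
                 nodes = nodes, unreachable_pairs = unreachable,
                 n_drug_unmapped = n_drug_unmapped,
                 n_disease_unmapped = n_disease_unmapped,
                 directed = directed, degenerate = FALSE),
            class = "ddn")
}

#' @export
print.ddn <- function(x, ...) {
  cat("Drug-disease network:", length(x$nodes), "nodes (",
      length(x$drug_genes), "drug,", length(x$disease_genes), "disease,",
      length(x$intermediate_genes), "intermediate;",
      length(x$both_genes), "shared ),",
      x$unreachable_pairs, "unreachable pair(s)\n")
  invisible(x)
}

#' Export a DDN as node and edge tables
#'
#' Writes `<prefix>_nodes.tsv` (columns `gene`, `role` in
#' drug/disease/both/intermediate) and `<prefix>_edges.tsv` (the UGHP edges
#' induced on the DDN nodes, with their sign and conflict flag).
#'
#' @param ddn A `ddn` object.
#' @param ughp The `ughp` the DDN was built from.
#' @param prefix Output path prefix.
#' @export
write_ddn <- function(ddn, ughp, prefix) {
  role <- ifelse(ddn$nodes %in% ddn$both_genes, "both",
          ifelse(ddn$nodes %in% ddn$drug_genes, "drug",
          ifelse(ddn$nodes %in% ddn$disease_genes, "disease", "intermediate")))
  utils::write.table(data.frame(gene = ddn$nodes, role = role),
                     paste0(prefix, "_nodes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  e <- ughp$edges
  keep <- e$source %in% ddn$nodes & e$target %in% ddn$nodes
  utils::write.table(e[keep, , drop = FALSE], paste0(prefix, "_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

# Pearson correlation written out from its sum form; the quantity the whole
# pipeline ranks on. Returns NA when fewer than 3 points or either array has
# zero variance.
pearson_r <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sqrt(sum(dx^2))
  sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(dx * dy) / (sx * sy)
}

#' Repurposing score of a drug condition against a disease signature
#'
#' Restricts the DDN nodes to genes that carry a z-score in both the drug
#' profile and the disease signature, builds the two z-score arrays in
#' identical gene order, and computes their Pearson correlation. A negative
#' score means the drug's transcriptomic effect opposes the disease
#' signature (the favorable case). The score is undefined (`r = NA`,
#' `defined = FALSE`) when fewer than 3 genes survive or either array has
#' zero variance; undefined is a value, not an error.
#'
#' @param ddn A `ddn` object.
#' @param drug_profile `perturbation_profile` or `combined_profile`.
#' @param disease_signature `disease_signature`.
#' @return Object of class `repurposing_score`: list with `drug_key`,
#'   `drug_id`, `dose`, `time_h`, `subtype_id`, `r`, `defined`,
#'   `n_genes_scored`.
#' @export
score_ddn <- function(ddn, drug_profile, disease_signature) {
  stopifnot(inherits(ddn, "ddn"),
            inherits(disease_signature, "disease_signature"))
  genes <- ddn$nodes
  genes <- genes[genes %in% names(drug_profile$z) &
                 genes %in% names(disease_signature$z)]
  x <- unname(drug_profile$z[genes])
  y <- unname(disease_signature$z[genes])
  r <- if (ddn$degenerate) NA_real_ else pearson_r(x, y)
  combined <- inherits(drug_profile, "combined_profile")
  structure(list(
    drug_key = if (combined) paste(drug_profile$component_keys, collapse = " + ")
               else drug_profile$key,
    drug_id = if (combined) paste(drug_profile$drug_ids, collapse = " + ")
              else drug_profile$drug_id,
    dose = if (combined) NA_real_ else drug_profile$dose,
    time_h = if (combined) NA_real_ else drug_profile$time_h,
    subtype_id = disease_signature$subtype_id,
    r = r, defined = !is.na(r),
    n_genes_scored = length(genes)), class = "repurposing_score")
}

#' @export
print.repurposing_score <- function(x, ...) {
  cat("Repurposing score", x$drug_key, "vs", x$subtype_id, ":",
      if (x$defined) round(x$r, 4) else "undefined",
      "(", x$n_genes_scored, "genes )\n")
  invisible(x)
}

#' Score a library of drug conditions against one disease signature
#'
#' Convenience wrapper running [select_drug_genes()], [build_ddn()] and
#' [score_ddn()] for each profile.
#'
#' @param profiles List of `perturbation_profile` objects.
#' @param signature `disease_signature`.
#' @param disease_genes Candidate disease genes (e.g. from
#'   [select_candidates()]).
#' @param ughp A `ughp` object.
#' @param k Number of top drug genes (default 50).
#' @param directed Directed traversal flag.
#' @return List of `repurposing_score` objects, one per profile.
#' @export
score_library <- function(profiles, signature, disease_genes, ughp,
                          k = 50L, directed = FALSE) {
  lapply(profiles, function(p) {
    dg <- select_drug_genes(p, k = k)
    ddn <- build_ddn(ughp, dg, disease_genes, directed = directed)
    score_ddn(ddn, p, signature)
  })
}

#' Rank drug conditions by repurposing score
#'
#' Defined scores are sorted ascending (most negative, i.e. most
#' disease-opposing, first); undefined scores are excluded rather than
#' treated as neutral. Ties are broken lexicographically on the profile key.
#'
#' @param scores List of `repurposing_score` objects.
#' @param best_per_drug If `TRUE`, keep only each drug's best (most
#'   negative) condition before ranking.
#' @return data.frame with columns `rank`, `drug_id`, `dose`, `time_h`,
#'   `drug_key`, `score`, `n_genes_scored`.
#' @export
rank_drugs <- function(scores, best_per_drug = FALSE) {
  defined <- Filter(function(s) isTRUE(s$defined), scores)
  if (length(defined) == 0L) {
    return(data.frame(rank = integer(), drug_id = character(),
                      dose = numeric(), time_h = numeric(),
                      drug_key = character(), score = numeric(),
                      n_genes_scored = integer(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    drug_id = vapply(defined, `[[`, character(1), "drug_id"),
    dose = vapply(defined, `[[`, numeric(1), "dose"),
    time_h = vapply(defined, `[[`, numeric(1), "time_h"),
    drug_key = vapply(defined, `[[`, character(1), "drug_key"),
    score = vapply(defined, `[[`, numeric(1), "r"),
    n_genes_scored = vapply(defined, `[[`, integer(1), "n_genes_scored"),
    stringsAsFactors = FALSE)
  df <- df[order(df$score, df$drug_key), , drop = FALSE]
  if (best_per_drug) df <- df[!duplicated(df$drug_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("rank", "drug_id", "dose", "time_h", "drug_key", "score",
         "n_genes_scored")]
}

#' Five-number summary of repurposing scores
#'
#' @param scores List of `repurposing_score` objects (>= 1 defined), or a
#'   ranking data.frame from [rank_drugs()].
#' @return data.frame with `subtype`, `n`, `min`, `q1`, `median`, `q3`,
#'   `max`.
#' @export
score_distribution <- function(scores) {
  if (is.data.frame(scores)) {
    r <- scores$score
    subtype <- NA_character_
  } else {
    defined <- Filter(function(s) isTRUE(s$defined), scores)
    if (length(defined) == 0L) stop("no defined scores")
    r <- vapply(defined, `[[`, numeric(1), "r")
    subtype <- defined[[1L]]$subtype_id
  }
  q <- unname(stats::quantile(r, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  data.frame(subtype = subtype, n = length(r), min = q[1L], q1 = q[2L],
             median = q[3L], q3 = q[4L], max = q[5L],
             stringsAsFactors = FALSE)
}
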