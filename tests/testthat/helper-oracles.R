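# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms (distance-criterion path unions, fisher.test).

# Exhaustive enumeration of all minimum-hop paths via BFS depth + DFS over
# simple paths. Returns the union of nodes on all shortest source->target
# paths, with the same degenerate conventions as the package.
bf_shortest_path_nodes <- function(edges, nodes, source, target,
                                   directed = FALSE) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    s <- edges$source[i]; t <- edges$target[i]
    adj[[s]] <- union(adj[[s]], t)
    if (!directed) adj[[t]] <- union(adj[[t]], s)
  }
  if (source == target) return(list(nodes = source, reachable = TRUE))
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[[source]] <- 0
  q <- source
  while (length(q) > 0L) {
    v <- q[[1L]]; q <- q[-1L]
    for (w in adj[[v]]) {
      if (!is.finite(dist[[w]])) { dist[[w]] <- dist[[v]] + 1; q <- c(q, w) }
    }
  }
  if (!is.finite(dist[[target]])) {
    return(list(nodes = sort(unique(c(source, target))), reachable = FALSE))
  }
  dmin <- dist[[target]]
  found <- character(0)
  dfs <- function(path) {
    v <- path[length(path)]
    k <- length(path) - 1L
    if (v == target) {
      if (k == dmin) found <<- union(found, path)
      return(invisible())
    }
    if (k >= dmin) return(invisible())
    for (w in adj[[v]]) {
      # any node at position k+1 of a shortest path has BFS depth k+1
      if (!(w %in% path) && dist[[w]] == k + 1L) dfs(c(path, w))
    }
  }
  dfs(source)
  list(nodes = sort(found), reachable = TRUE)
}

# Two-sided Fisher's exact p by direct hypergeometric table enumeration
# (sum of table probabilities not exceeding the observed one, with the
# conventional 1 + 1e-7 relative guard against ties lost to rounding).
fisher_enum_oracle <- function(aberrant_in, n_in, aberrant_out, n_out) {
  m <- aberrant_in + aberrant_out
  k <- max(0L, m - n_out):min(m, n_in)
  p <- stats::dhyper(k, n_in, n_out, m)
  p_obs <- stats::dhyper(aberrant_in, n_in, n_out, m)
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Random signed directed edge list over n nodes (no self-loops, no duplicate
# ordered pairs), as a pathway_record the package can consume.
random_pathway <- function(n_nodes, n_edges, seed, id = "RP") {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  src <- sample(nodes, 3L * n_edges, replace = TRUE)
  tgt <- sample(nodes, 3L * n_edges, replace = TRUE)
  keep <- src != tgt & !duplicated(paste(src, tgt))
  df <- data.frame(source = src[keep], target = tgt[keep],
                   stringsAsFactors = FALSE)
  df <- utils::head(df, n_edges)
  df$sign <- sample(c(1L, -1L), nrow(df), replace = TRUE)
  structure(list(pathway_id = id, name = id, edges = df),
            class = "pathway_record")
}

make_pathway <- function(id, source, target, sign = 1L) {
  structure(list(pathway_id = id, name = id,
                 edges = data.frame(source = source, target = target,
                                    sign = sign, stringsAsFactors = FALSE)),
            class = "pathway_record")
}

make_profile <- function(drug_id, z, dose = 10, time_h = 24) {
  perturbation_profile(drug_id, dose, time_h, z)
}

make_signature <- function(z, subtype = "S1") {
  structure(list(subtype_id = subtype, z = z), class = "disease_signature")
}

# Memoised synthetic study worlds so the simulation-based acceptance
# criteria share one pipeline run per seed.
.world_cache <- new.env(parent = emptyenv())

single_drug_world <- function(seed) {
  key <- sprintf("single_%d", seed)
  if (is.null(.world_cache[[key]])) {
    u <- suppressWarnings(build_ughp(generate_pathways(seed = seed)))
    coh <- generate_cohort(seed = seed + 100L)
    cand <- suppressWarnings(
      select_candidates(coh$cohort, coh$variants, coh$truth$subtype))
    sig <- normalize_signature(coh$cohort$expression, coh$cohort$labels,
                               coh$truth$subtype)
    lib <- generate_drug_library(sig, seed = seed + 200L,
                                 driver_genes = coh$truth$driver_genes)
    sel <- select_conditions(lib$profiles)
    scores <- score_library(sel, sig, cand$genes, u)
    .world_cache[[key]] <- list(
      ughp = u, cohort = coh, candidates = cand, signature = sig,
      library = lib, profiles = sel, scores = scores,
      ranking = rank_drugs(scores))
  }
  .world_cache[[key]]
}

# Smaller library for the quadratic pair screen; generated without the
# full-reversal drug so the best single drug is an ordinary one (the
# regime in which combination superiority is observable at all).
pair_screen_world <- function(seed) {
  key <- sprintf("pair_%d", seed)
  if (is.null(.world_cache[[key]])) {
    w <- single_drug_world(seed)
    lib <- generate_drug_library(w$signature, n_drugs = 30L,
                                 plant_reversal = FALSE,
                                 driver_genes = w$cohort$truth$driver_genes,
                                 seed = seed + 300L)
    sel <- select_conditions(lib$profiles)
    scores <- score_library(sel, w$signature, w$candidates$genes, w$ughp)
    ranking <- rank_drugs(scores)
    best <- ranking[!duplicated(ranking$drug_id), , drop = FALSE]
    profs <- sel[best$drug_key]
    rec <- screen_pairs(profs, w$signature, w$candidates$genes, w$ughp,
                        single_scores = scores[best$drug_key])
    .world_cache[[key]] <- list(world = w, library = lib, profiles = profs,
                                single_scores = scores, ranking = ranking,
                                records = rec)
  }
  .world_cache[[key]]
}

write_pathway_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
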