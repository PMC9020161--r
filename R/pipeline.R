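#' Assemble and validate a pipeline run configuration
#'
#' A run configuration bundles the input paths and tunable parameters of the
#' pipeline. It can be built directly or loaded from a YAML file via
#' [read_run_config()]; command-line flags override file values in the CLI.
#'
#' @param pathway_dir Directory of pathway edge TSVs.
#' @param profiles Profiles TSV path.
#' @param copy_number,expression,labels Cohort TSV paths.
#' @param variants Common-variant gene list path (one gene per line).
#' @param interactions Interaction table TSV path (optional; `NULL` skips
#'   interaction filtering).
#' @param out_dir Output directory.
#' @param subtype Subtype id to analyse (default `"S1"`).
#' @param k Top drug genes (default 50).
#' @param amp_threshold Copy-number aberration threshold (default 0.5).
#' @param alpha Significance level (default 0.05).
#' @param n_bins Chi-square bins (default 3).
#' @param directed Directed graph traversal (default FALSE).
#' @param blocked_severities Interaction severities to block (default all).
#' @param pair_cap Maximum reported pairs (default 100).
#' @param seed Integer seed (used only by `simulate`).
#' @param check_paths Validate that input paths exist (default TRUE).
#' @return A `run_config` list.
#' @export
run_config <- function(pathway_dir = NULL, profiles = NULL,
                       copy_number = NULL, expression = NULL, labels = NULL,
                       variants = NULL, interactions = NULL,
                       out_dir = ".", subtype = "S1", k = 50L,
                       amp_threshold = 0.5, alpha = 0.05, n_bins = 3L,
                       directed = FALSE,
                       blocked_severities = c("minor", "moderate", "major"),
                       pair_cap = 100L, seed = 1L, check_paths = TRUE) {
  cfg <- list(pathway_dir = pathway_dir, profiles = profiles,
              copy_number = copy_number, expression = expression,
              labels = labels, variants = variants,
              interactions = interactions, out_dir = out_dir,
              subtype = subtype, k = as.integer(k),
              amp_threshold = amp_threshold, alpha = alpha,
              n_bins = as.integer(n_bins), directed = isTRUE(directed),
              blocked_severities = blocked_severities,
              pair_cap = as.integer(pair_cap), seed = as.integer(seed))
  stopifnot(cfg$k >= 1L, cfg$amp_threshold > 0, cfg$alpha >= 0,
            cfg$alpha <= 1, cfg$n_bins >= 2L, cfg$pair_cap >= 1L)
  if (check_paths) {
    for (f in c("pathway_dir", "profiles", "copy_number", "expression",
                "labels", "variants", "interactions")) {
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
        stop("input path does not exist (", f, "): ", cfg[[f]])
      }
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file; keys match [run_config()] arguments. Relative
#'   paths are resolved against the YAML file's directory.
#' @param ... Overrides applied on top of the file values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  base <- dirname(normalizePath(path))
  for (f in c("pathway_dir", "profiles", "copy_number", "expression",
              "labels", "variants", "interactions", "out_dir")) {
    if (!is.null(vals[[f]]) && !grepl("^(/|[A-Za-z]:)", vals[[f]])) {
      vals[[f]] <- file.path(base, vals[[f]])
    }
  }
  do.call(run_config, vals)
}

.load_cohort <- function(config) {
  lab <- utils::read.delim(config$labels, stringsAsFactors = FALSE)
  list(copy_number = read_matrix_tsv(config$copy_number),
       expression = read_matrix_tsv(config$expression),
       labels = stats::setNames(lab$subtype, lab$sample))
}

#' Build and export the unified pathway graph
#'
#' Reads every pathway file in `config$pathway_dir`, builds the unified
#' graph, writes `ughp_edges.tsv` and a one-row `ughp_summary.tsv`
#' (n_nodes, n_edges, n_conflicts) under `config$out_dir`.
#'
#' @param config A `run_config`.
#' @return The `ughp`, invisibly.
#' @export
cmd_build_ughp <- function(config) {
  pws <- read_pathway_dir(config$pathway_dir)
  u <- build_ughp(pws)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ughp(u, file.path(config$out_dir, "ughp_edges.tsv"))
  utils::write.table(
    data.frame(n_nodes = length(u$nodes), n_edges = nrow(u$edges),
               n_conflicts = nrow(u$conflict_edges)),
    file.path(config$out_dir, "ughp_summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(u)
}

#' Select and export candidate disease genes for the configured subtype
#'
#' @param config A `run_config`.
#' @return The `candidate_gene_set`, invisibly.
#' @export
cmd_select_genes <- function(config) {
  cohort <- .load_cohort(config)
  variants <- readLines(config$variants, warn = FALSE)
  cand <- select_candidates(cohort, variants, config$subtype,
                            amp_threshold = config$amp_threshold,
                            alpha = config$alpha, n_bins = config$n_bins)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_candidates(cand, file.path(config$out_dir,
                                   paste0("candidates_", config$subtype,
                                          ".tsv")))
  invisible(cand)
}

#' Score every single drug condition and export the ranking
#'
#' Runs the full single-drug pipeline for the configured subtype: unified
#' graph, candidate genes, disease signature, condition selection
#' (lowest/highest dose, 24 h preferred), drug-gene selection, drug-disease
#' network construction, and Pearson scoring. Writes
#' `ranking_<subtype>.tsv` (columns rank, drug_id, dose, time_h, drug_key,
#' score, n_genes_scored) and `score_distribution_<subtype>.tsv`.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `ughp`, `candidates`, `signature`,
#'   `profiles` (selected conditions), `scores`, `ranking`.
#' @export
cmd_score_single <- function(config) {
  u <- cmd_build_ughp(config)
  cand <- cmd_select_genes(config)
  cohort <- .load_cohort(config)
  signature <- normalize_signature(cohort$expression, cohort$labels,
                                   config$subtype)
  profiles <- select_conditions(load_profiles(config$profiles))
  scores <- score_library(profiles, signature, cand$genes, u,
                          k = config$k, directed = config$directed)
  ranking <- rank_drugs(scores)
  if (nrow(ranking) == 0L) stop("no defined repurposing scores")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(ranking,
                     file.path(config$out_dir,
                               paste0("ranking_", config$subtype, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(score_distribution(scores),
                     file.path(config$out_dir,
                               paste0("score_distribution_", config$subtype,
                                      ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(ughp = u, candidates = cand, signature = signature,
                 profiles = profiles, scores = scores, ranking = ranking))
}

#' Screen drug pairs, filter interactions, and export pair reports
#'
#' Runs [cmd_score_single()] first, keeps each drug's best-scoring single
#' condition, screens all unordered pairs of those conditions under the
#' additive assumption, removes pairs with blocked known interactions
#' (logged to `pair_removals_<subtype>.tsv`), and writes the full
#' post-filter pair table (`pairs_<subtype>.tsv`) plus the pairs beating the
#' best single drug (`pairs_beating_best_single_<subtype>.tsv`, capped at
#' `config$pair_cap`).
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `records`, `beating`, `removed`, plus the
#'   [cmd_score_single()] outputs.
#' @export
cmd_score_pairs <- function(config) {
  single <- cmd_score_single(config)
  best <- single$ranking[!duplicated(single$ranking$drug_id), , drop = FALSE]
  profs <- single$profiles[best$drug_key]
  scores <- single$scores[best$drug_key]
  rec <- screen_pairs(profs, single$signature, single$candidates$genes,
                      single$ughp, k = config$k, directed = config$directed,
                      single_scores = scores)
  if (!is.null(config$interactions)) {
    itab <- read_interaction_table(config$interactions)
    rec <- filter_interactions(rec, itab,
                               blocked_severities = config$blocked_severities)
  } else {
    attr(rec, "removed") <- rec[0, , drop = FALSE]
  }
  beating <- pairs_beating_best_single(rec, single$ranking,
                                       cap = config$pair_cap)
  out <- config$out_dir
  removed <- attr(rec, "removed")
  utils::write.table(as.data.frame(rec),
                     file.path(out, paste0("pairs_", config$subtype, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(removed),
                     file.path(out, paste0("pair_removals_", config$subtype,
                                           ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(beating),
                     file.path(out,
                               paste0("pairs_beating_best_single_",
                                      config$subtype, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(list(records = rec, beating = beating, removed = removed),
              single))
}

#' Generate a synthetic input bundle (CLI wrapper)
#'
#' Writes the full bundle with [simulate_bundle()] into `config$out_dir`
#' using `config$seed`.
#'
#' @param config A `run_config` (paths need not exist).
#' @param ... Passed to [simulate_bundle()].
#' @return Invisibly, the [simulate_bundle()] result.
#' @export
cmd_simulate <- function(config, ...) {
  simulate_bundle(config$out_dir, seed = config$seed, ...)
}
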