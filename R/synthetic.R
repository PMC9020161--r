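#' Gene universe used by the synthetic generators
#'
#' @param n_genes Number of genes.
#' @return Character vector `G001`, `G002`, ...
#' @export
gene_universe <- function(n_genes) sprintf("G%03d", seq_len(n_genes))

#' Generate a set of synthetic signed pathways
#'
#' Emulates a pathway database: each pathway covers a random subset of a
#' shared gene universe with a random spanning tree (guaranteeing a
#' connected backbone) plus extra random edges, every edge carrying an
#' activation (+1, 70%) or suppression (-1, 30%) sign. Only the first
#' `pathway_gene_frac` of the universe participates in pathways, so a
#' fraction of genes is deliberately absent from the unified graph
#' (exercising unmapped-gene handling downstream). Fully deterministic under
#' `seed`.
#'
#' @param n_genes Universe size (default 200).
#' @param n_pathways Number of pathways (default 12).
#' @param mean_edges Mean edges per pathway (default 40).
#' @param seed Integer seed.
#' @param pathway_gene_frac Fraction of the universe eligible for pathway
#'   membership (default 0.8).
#' @return List of `pathway_record` objects.
#' @export
generate_pathways <- function(n_genes = 200L, n_pathways = 12L,
                              mean_edges = 40L, seed = 1L,
                              pathway_gene_frac = 0.8) {
  stopifnot(n_genes > 2L, n_pathways >= 1L, mean_edges >= 2L)
  universe <- gene_universe(n_genes)
  eligible <- universe[seq_len(max(3L, floor(pathway_gene_frac * n_genes)))]
  with_seed(seed, {
    lapply(seq_len(n_pathways), function(i) {
      m <- max(3L, stats::rpois(1L, mean_edges))
      n_nodes <- min(length(eligible), max(3L, ceiling(0.7 * m)) + 1L)
      nodes <- sample(eligible, n_nodes)
      # spanning tree backbone: node j attaches to a random earlier node
      src <- vapply(2:n_nodes, function(j) nodes[sample.int(j - 1L, 1L)],
                    character(1))
      tree <- data.frame(source = src, target = nodes[-1L],
                         stringsAsFactors = FALSE)
      extra <- m - nrow(tree)
      if (extra > 0L) {
        e_src <- sample(nodes, extra, replace = TRUE)
        e_tgt <- sample(nodes, extra, replace = TRUE)
        keep <- e_src != e_tgt
        tree <- rbind(tree, data.frame(source = e_src[keep],
                                       target = e_tgt[keep],
                                       stringsAsFactors = FALSE))
      }
      tree <- unique(tree)
      tree$sign <- sample(c(1L, -1L), nrow(tree), replace = TRUE,
                          prob = c(0.7, 0.3))
      structure(list(pathway_id = sprintf("PW%02d", i),
                     name = sprintf("PW%02d", i), edges = tree),
                class = "pathway_record")
    })
  })
}

#' Generate a synthetic cohort with planted driver genes
#'
#' Emulates a tumor cohort with matched copy-number log-ratios, expression,
#' and subtype labels. `n_drivers` genes are planted as drivers of the first
#' subtype: a copy-number shift of `cna_effect` log-ratio units (random
#' direction per gene) in `aberrant_frac` of that subtype's samples, and a
#' subtype-wide expression shift of `expr_effect` standard deviations in the
#' same direction (drivers are subtype-defining in expression, while their
#' copy-number aberration has incomplete penetrance). A disjoint decoy set
#' receives the same copy-number
#' aberration but is listed in the common-variant set, exercising the
#' "aberration but no common variant" exclusion. A further `diff_frac` of
#' background genes are differentially expressed in one random subtype
#' (shift ~ Normal(0, `diff_sd`)), giving the disease signature a realistic
#' spread beyond the drivers.
#'
#' @param n_genes Universe size (default 200).
#' @param n_samples Cohort size (default 120).
#' @param n_subtypes Number of subtypes (default 3; labels `S1`, `S2`, ...).
#' @param n_drivers Planted drivers of subtype `S1` (default 20).
#' @param n_decoys Common-variant decoy genes (default 10).
#' @param cna_effect Copy-number log-ratio shift of drivers/decoys
#'   (default 1.0).
#' @param aberrant_frac Fraction of subtype samples carrying the aberration
#'   (default 0.8).
#' @param cna_noise Copy-number noise sd (default 0.15).
#' @param expr_effect Driver expression shift in sd units (default 4).
#' @param diff_frac Fraction of background genes differentially expressed in
#'   some subtype (default 0.3).
#' @param diff_sd Sd of background differential shifts (default 1).
#' @param seed Integer seed.
#' @return List with `cohort` (list `copy_number`, `expression`, `labels`),
#'   `variants` (character vector), and `truth` (list `driver_genes`,
#'   `decoy_genes`, `subtype`, `seed`).
#' @export
generate_cohort <- function(n_genes = 200L, n_samples = 120L,
                            n_subtypes = 3L, n_drivers = 20L,
                            n_decoys = 10L, cna_effect = 1.0,
                            aberrant_frac = 0.8, cna_noise = 0.15,
                            expr_effect = 4, diff_frac = 0.3, diff_sd = 1,
                            seed = 1L) {
  stopifnot(n_drivers + n_decoys < n_genes, n_subtypes >= 2L)
  genes <- gene_universe(n_genes)
  samples <- sprintf("T%03d", seq_len(n_samples))
  with_seed(seed, {
    labels <- stats::setNames(
      sprintf("S%d", rep_len(seq_len(n_subtypes), n_samples)), samples)
    focal <- "S1"
    in_s <- samples[labels == focal]

    special <- sample(genes, n_drivers + n_decoys)
    drivers <- sort(special[seq_len(n_drivers)])
    decoys <- sort(special[n_drivers + seq_len(n_decoys)])

    cn <- matrix(stats::rnorm(n_genes * n_samples, sd = cna_noise),
                 nrow = n_genes, dimnames = list(genes, samples))
    ge <- matrix(stats::rnorm(n_genes * n_samples),
                 nrow = n_genes, dimnames = list(genes, samples))

    for (g in c(drivers, decoys)) {
      dir <- sample(c(1, -1), 1L)
      carriers <- sample(in_s, round(aberrant_frac * length(in_s)))
      cn[g, carriers] <- cn[g, carriers] + dir * cna_effect
      if (g %in% drivers) {
        # drivers are subtype-defining: expression shifts across the whole
        # subtype, in the same direction as the copy-number aberration
        ge[g, in_s] <- ge[g, in_s] + dir * expr_effect
      }
    }

    background <- setdiff(genes, c(drivers, decoys))
    n_diff <- round(diff_frac * length(background))
    diff_genes <- sample(background, n_diff)
    for (g in diff_genes) {
      st <- sample(sprintf("S%d", seq_len(n_subtypes)), 1L)
      ge[g, labels == st] <- ge[g, labels == st] + stats::rnorm(1L, sd = diff_sd)
    }

    list(cohort = list(copy_number = cn, expression = ge, labels = labels),
         variants = decoys,
         truth = list(driver_genes = drivers, decoy_genes = decoys,
                      subtype = focal, seed = seed))
  })
}

#' Generate a synthetic drug perturbation library
#'
#' Emulates a level-5 perturbation library against a given disease
#' signature. Background drugs carry pure Gaussian noise
#' (sd `background_sd`, clipped to \[-10, 10\]). Optionally one planted
#' reversal drug (`RVRSL`) has `z = -signature + Normal(0, noise_sd)` in all
#' its conditions, and one planted complementary pair (`CMBOA`, `CMBOB`)
#' each reverses a disjoint half of the signature genes (near-zero on the
#' other half). The halves are stratified over `driver_genes` when given, so
#' each pair member reverses half of the disease-relevant genes - the
#' planted ground truth behind the combination "catalyzing effect". Each
#' drug is emitted at two doses (0.04 and 10 micromol) and two time points
#' (6 h and 24 h).
#'
#' @param signature A `disease_signature` defining the gene set and target.
#' @param n_drugs Total number of drugs including planted ones
#'   (default 200).
#' @param noise_sd Noise sd of the planted drugs (default 0.5).
#' @param background_sd Noise sd of background drugs (default 2).
#' @param plant_reversal Plant the full-reversal drug (default TRUE).
#' @param plant_pair Plant the complementary pair (default TRUE).
#' @param driver_genes Optional disease-relevant genes used to stratify the
#'   pair's half-masks.
#' @param seed Integer seed.
#' @return List with `profiles` (named list of `perturbation_profile`) and
#'   `truth` (list `reversal_drug`, `reversal_key`, `pair_drugs`,
#'   `pair_keys`, `mask_a`, `mask_b`, `background_drugs`, `seed`).
#' @export
generate_drug_library <- function(signature, n_drugs = 200L, noise_sd = 0.5,
                                  background_sd = 2, plant_reversal = TRUE,
                                  plant_pair = TRUE, driver_genes = NULL,
                                  seed = 1L) {
  stopifnot(inherits(signature, "disease_signature"), n_drugs >= 3L)
  genes <- names(signature$z)
  sig <- signature$z
  doses <- c(0.04, 10)
  times <- c(6, 24)
  n_planted <- plant_reversal + 2L * plant_pair
  stopifnot(n_drugs > n_planted)
  bg_ids <- sprintf("DRUG%03d", seq_len(n_drugs - n_planted))

  with_seed(seed, {
    mask_a <- mask_b <- NULL
    if (plant_pair) {
      strat <- intersect(driver_genes %||% character(), genes)
      rest <- setdiff(genes, strat)
      half_strat <- sample(strat, floor(length(strat) / 2))
      half_rest <- sample(rest, floor(length(rest) / 2))
      mask_a <- genes %in% c(half_strat, half_rest)
      mask_b <- !mask_a
    }

    profiles <- list()
    emit <- function(drug_id, z_fun) {
      for (d in doses) for (t in times) {
        z <- clip(z_fun(), -10, 10)
        names(z) <- genes
        p <- perturbation_profile(drug_id, d, t, z)
        profiles[[p$key]] <<- p
      }
    }
    for (id in bg_ids) {
      emit(id, function() stats::rnorm(length(genes), sd = background_sd))
    }
    if (plant_reversal) {
      emit("RVRSL", function() -sig + stats::rnorm(length(genes), sd = noise_sd))
    }
    if (plant_pair) {
      emit("CMBOA", function() -sig * mask_a + stats::rnorm(length(genes), sd = noise_sd))
      emit("CMBOB", function() -sig * mask_b + stats::rnorm(length(genes), sd = noise_sd))
    }

    truth <- list(
      reversal_drug = if (plant_reversal) "RVRSL" else NULL,
      reversal_key = if (plant_reversal) profile_key("RVRSL", 10, 24) else NULL,
      pair_drugs = if (plant_pair) c("CMBOA", "CMBOB") else NULL,
      pair_keys = if (plant_pair) c(profile_key("CMBOA", 10, 24),
                                    profile_key("CMBOB", 10, 24)) else NULL,
      mask_a = if (plant_pair) stats::setNames(mask_a, genes) else NULL,
      mask_b = if (plant_pair) stats::setNames(mask_b, genes) else NULL,
      background_drugs = bg_ids, seed = seed)
    list(profiles = profiles, truth = truth)
  })
}

#' Generate a synthetic drug-drug interaction table
#'
#' Samples random unordered drug pairs with severities, never flagging the
#' pairs listed in `exclude` (so planted combinations stay reportable).
#'
#' @param drug_ids Drug identifier pool.
#' @param n_entries Number of interaction entries (default 15).
#' @param exclude Character vector of `pair_key()`-style keys, or a 2-column
#'   matrix of drug pairs, never to flag.
#' @param seed Integer seed.
#' @return An `interaction_table`.
#' @export
generate_interaction_table <- function(drug_ids, n_entries = 15L,
                                       exclude = NULL, seed = 1L) {
  stopifnot(length(drug_ids) >= 2L)
  if (is.matrix(exclude)) exclude <- pair_key(exclude[, 1L], exclude[, 2L])
  with_seed(seed, {
    d1 <- character(0); d2 <- character(0)
    guard <- 0L
    while (length(d1) < n_entries && guard < 50L * n_entries) {
      guard <- guard + 1L
      p <- sample(drug_ids, 2L)
      k <- pair_key(p[1L], p[2L])
      if (k %in% c(exclude, pair_key(d1, d2))) next
      d1 <- c(d1, p[1L]); d2 <- c(d2, p[2L])
    }
    interaction_table(d1, d2,
                      sample(c("minor", "moderate", "major"), length(d1),
                             replace = TRUE))
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates pathways, cohort, drug library and interaction table with a
#' single master seed and writes them in the TSV dialects the pipeline
#' reads, together with a YAML manifest recording every parameter and the
#' planted ground truth. Sub-seeds are derived deterministically from
#' `seed`.
#'
#' @param dir Output directory (created if missing).
#' @param seed Master integer seed.
#' @param n_genes,n_pathways,n_drugs,n_samples,n_subtypes,n_drivers Sizes
#'   passed to the generators.
#' @param noise_sd Planted-drug noise sd (default 0.5).
#' @param plant_reversal,plant_pair Passed to [generate_drug_library()].
#' @return Invisibly, a list with the generated objects and `paths`.
#' @export
simulate_bundle <- function(dir, seed = 1L, n_genes = 200L, n_pathways = 12L,
                            n_drugs = 200L, n_samples = 120L,
                            n_subtypes = 3L, n_drivers = 20L, noise_sd = 0.5,
                            plant_reversal = TRUE, plant_pair = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pathways"), showWarnings = FALSE)

  pathways <- generate_pathways(n_genes = n_genes, n_pathways = n_pathways,
                                seed = seed)
  for (p in pathways) {
    utils::write.table(p$edges,
                       file.path(dir, "pathways", paste0(p$pathway_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }

  coh <- generate_cohort(n_genes = n_genes, n_samples = n_samples,
                         n_subtypes = n_subtypes, n_drivers = n_drivers,
                         seed = seed + 1L)
  write_matrix_tsv(coh$cohort$copy_number, file.path(dir, "copy_number.tsv"))
  write_matrix_tsv(coh$cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(
    data.frame(sample = names(coh$cohort$labels),
               subtype = unname(coh$cohort$labels)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(coh$variants, file.path(dir, "variants.txt"))

  signature <- normalize_signature(coh$cohort$expression, coh$cohort$labels,
                                   coh$truth$subtype)
  lib <- generate_drug_library(signature, n_drugs = n_drugs,
                               noise_sd = noise_sd,
                               plant_reversal = plant_reversal,
                               plant_pair = plant_pair,
                               driver_genes = coh$truth$driver_genes,
                               seed = seed + 2L)
  write_profiles(lib$profiles, file.path(dir, "profiles.tsv"))

  drug_ids <- unique(vapply(lib$profiles, `[[`, character(1), "drug_id"))
  itab <- generate_interaction_table(
    drug_ids, exclude = if (plant_pair) pair_key("CMBOA", "CMBOB"),
    seed = seed + 3L)
  utils::write.table(itab[, c("drug1", "drug2", "severity")],
                     file.path(dir, "interactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    seed = seed, n_genes = n_genes, n_pathways = n_pathways,
    n_drugs = n_drugs, n_samples = n_samples, n_subtypes = n_subtypes,
    n_drivers = n_drivers, noise_sd = noise_sd,
    focal_subtype = coh$truth$subtype,
    driver_genes = coh$truth$driver_genes,
    decoy_genes = coh$truth$decoy_genes,
    reversal_drug = lib$truth$reversal_drug,
    reversal_key = lib$truth$reversal_key,
    pair_drugs = lib$truth$pair_drugs,
    pair_keys = lib$truth$pair_keys)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))

  invisible(list(pathways = pathways, cohort = coh, signature = signature,
                 library = lib, interactions = itab, manifest = manifest,
                 paths = list(dir = dir)))
}

#' Write a gene x sample matrix as TSV (genes in rows)
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample matrix TSV written by [write_matrix_tsv()]
#'
#' @param path TSV path (first column `gene`, remaining columns samples).
#' @return Numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
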