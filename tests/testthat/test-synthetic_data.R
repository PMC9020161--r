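test_that("generators are fully deterministic under a seed", {
  p1 <- generate_pathways(seed = 7L)
  p2 <- generate_pathways(seed = 7L)
  expect_identical(p1, p2)
  expect_false(identical(p1, generate_pathways(seed = 8L)))

  c1 <- generate_cohort(seed = 7L)
  c2 <- generate_cohort(seed = 7L)
  expect_identical(c1, c2)

  sig <- make_signature(stats::setNames(rnorm(50), gene_universe(50L)))
  l1 <- generate_drug_library(sig, n_drugs = 10L, seed = 7L)
  l2 <- generate_drug_library(sig, n_drugs = 10L, seed = 7L)
  expect_identical(l1, l2)
})

test_that("generated pathways stay inside the gene universe and union correctly", {
  pws <- generate_pathways(n_genes = 200L, n_pathways = 12L, seed = 3L)
  universe <- gene_universe(200L)
  for (p in pws) {
    expect_true(all(c(p$edges$source, p$edges$target) %in% universe))
    expect_true(all(p$edges$source != p$edges$target))
    expect_true(all(p$edges$sign %in% c(-1L, 1L)))
  }
  # single pathway: the unified graph is that pathway
  one <- generate_pathways(n_pathways = 1L, seed = 4L)
  u <- build_ughp(one)
  expect_setequal(u$nodes, unique(c(one[[1]]$edges$source,
                                    one[[1]]$edges$target)))
  expect_equal(nrow(u$edges), nrow(unique(one[[1]]$edges[, c("source", "target")])))
})

test_that("cohorts plant recoverable drivers and null cohorts stay null", {
  coh <- generate_cohort(seed = 9L)
  expect_length(coh$truth$driver_genes, 20L)
  expect_setequal(coh$variants, coh$truth$decoy_genes)
  expect_length(intersect(coh$truth$driver_genes, coh$truth$decoy_genes), 0L)
  expect_equal(dim(coh$cohort$copy_number), c(200L, 120L))
  expect_identical(colnames(coh$cohort$copy_number),
                   colnames(coh$cohort$expression))

  # zero effect size: selection returns (near-)alpha-level false positives
  for (seed in 1:5) {
    null_coh <- generate_cohort(cna_effect = 0, expr_effect = 0, seed = seed)
    cand <- suppressWarnings(
      select_candidates(null_coh$cohort, null_coh$variants, "S1"))
    expect_lte(length(cand$genes), 2L, label = sprintf("seed %d", seed))
  }
})

test_that("drug libraries emit bounded z, planted structure, and condition grid", {
  coh <- generate_cohort(seed = 13L)
  sig <- normalize_signature(coh$cohort$expression, coh$cohort$labels, "S1")
  lib <- generate_drug_library(sig, n_drugs = 12L, seed = 13L,
                               driver_genes = coh$truth$driver_genes)
  expect_length(lib$profiles, 12L * 4L)  # 2 doses x 2 time points per drug
  for (p in lib$profiles) expect_true(all(p$z >= -10 & p$z <= 10))
  expect_true(lib$truth$reversal_key %in% names(lib$profiles))
  expect_true(all(lib$truth$pair_keys %in% names(lib$profiles)))
  # the half-masks are disjoint and cover the gene set, stratified on drivers
  expect_true(all(xor(lib$truth$mask_a, lib$truth$mask_b)))
  n_drv_a <- sum(lib$truth$mask_a[coh$truth$driver_genes])
  expect_equal(n_drv_a, 10L)

  expect_length(generate_drug_library(sig, n_drugs = 5L, seed = 1L,
                                      plant_reversal = FALSE,
                                      plant_pair = FALSE)$profiles, 20L)
})

test_that("background drug scores center on zero", {
  w <- single_drug_world(0L)
  rk <- w$ranking
  bg <- rk$score[rk$drug_id %in% w$library$truth$background_drugs]
  expect_gte(length(bg), 100L)
  expect_lt(abs(median(bg)), 0.2)
  expect_gt(stats::binom.test(sum(bg > 0), length(bg))$p.value, 0.01)
})

test_that("interaction-table generation avoids excluded pairs", {
  it <- generate_interaction_table(sprintf("D%02d", 1:10), n_entries = 10L,
                                  exclude = ddnscreen:::pair_key("D01", "D02"),
                                  seed = 2L)
  expect_equal(nrow(it), 10L)
  expect_false(ddnscreen:::pair_key("D01", "D02") %in% it$key)
  expect_true(all(it$severity %in% c("minor", "moderate", "major")))
})

test_that("simulated bundles are byte-identical per seed and loadable", {
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  unlink(c(d1, d2), recursive = TRUE)
  b1 <- simulate_bundle(d1, seed = 5L, n_genes = 60L, n_pathways = 4L,
                        n_drugs = 6L, n_samples = 60L, n_drivers = 6L)
  simulate_bundle(d2, seed = 5L, n_genes = 60L, n_pathways = 4L,
                  n_drugs = 6L, n_samples = 60L, n_drivers = 6L)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }

  # round-trip: every written artifact loads back through the pipeline readers
  pws <- read_pathway_dir(file.path(d1, "pathways"))
  expect_length(pws, 4L)
  profs <- load_profiles(file.path(d1, "profiles.tsv"))
  expect_length(profs, 6L * 4L)
  cn <- read_matrix_tsv(file.path(d1, "copy_number.tsv"))
  expect_equal(dim(cn), c(60L, 60L))
  manifest <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  expect_equal(manifest$seed, 5L)
  expect_true(all(manifest$pair_keys %in% names(profs)))
  expect_setequal(manifest$driver_genes, b1$cohort$truth$driver_genes)
})
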