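# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators never perturb user RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Canonical profile key: drug|dose|time, the unit of ranking throughout.
profile_key <- function(drug_id, dose, time_h) {
  sprintf("%s|%g|%g", drug_id, dose, time_h)
}

# Order-independent key for a drug pair (interaction tables, pair records).
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "||")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
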