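#' Construct a drug perturbation profile
#'
#' A profile is the transcriptomic effect of one (drug, dose, time)
#' condition, as gene-level z-scores bounded in \[-10, 10\] (values outside
#' the bound are clipped with a message, mirroring the level-5 perturbation
#' data contract).
#'
#' @param drug_id Drug identifier.
#' @param dose Dose in micromol.
#' @param time_h Treatment time in hours.
#' @param z Named numeric vector of gene z-scores.
#' @return Object of class `perturbation_profile` with fields `drug_id`,
#'   `dose`, `time_h`, `z`, `key`.
#' @export
perturbation_profile <- function(drug_id, dose, time_h, z) {
  stopifnot(is.numeric(z), !is.null(names(z)))
  n_clip <- sum(z < -10 | z > 10)
  if (n_clip > 0L) {
    message(n_clip, " z-score(s) clipped to [-10, 10] for ",
            profile_key(drug_id, dose, time_h))
    z <- clip(z, -10, 10)
  }
  structure(list(drug_id = drug_id, dose = dose, time_h = time_h, z = z,
                 key = profile_key(drug_id, dose, time_h)),
            class = "perturbation_profile")
}

#' @export
print.perturbation_profile <- function(x, ...) {
  cat("Perturbation profile", x$key, "-", length(x$z), "genes\n")
  invisible(x)
}

#' Load perturbation profiles from a TSV file
#'
#' Accepts two layouts: wide (columns `drug_id`, `dose`, `time_h`, then one
#' column per gene) or long (columns `drug_id`, `dose`, `time_h`, `gene`,
#' `z`). z-scores outside \[-10, 10\] are clipped (count reported).
#' Duplicate (drug, dose, time) keys are an error.
#'
#' @param path TSV file path.
#' @return Named list of `perturbation_profile` objects (names are profile
#'   keys).
#' @export
load_profiles <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("drug_id", "dose", "time_h")
  if (!all(need %in% colnames(df))) {
    stop("profile file must have columns drug_id, dose, time_h: ", path)
  }
  long <- all(c("gene", "z") %in% colnames(df))
  if (long) {
    keys <- unique(df[need])
    profs <- lapply(seq_len(nrow(keys)), function(i) {
      sel <- df$drug_id == keys$drug_id[i] & df$dose == keys$dose[i] &
        df$time_h == keys$time_h[i]
      z <- stats::setNames(df$z[sel], df$gene[sel])
      perturbation_profile(keys$drug_id[i], keys$dose[i], keys$time_h[i], z)
    })
  } else {
    gene_cols <- setdiff(colnames(df), need)
    zm <- as.matrix(df[gene_cols])
    profs <- lapply(seq_len(nrow(df)), function(i) {
      perturbation_profile(df$drug_id[i], df$dose[i], df$time_h[i], zm[i, ])
    })
  }
  keys <- vapply(profs, `[[`, character(1), "key")
  dup <- duplicated(keys)
  if (any(dup)) {
    stop("duplicate (drug, dose, time) key(s): ",
         paste(unique(keys[dup]), collapse = ", "))
  }
  stats::setNames(profs, keys)
}

#' Write perturbation profiles to a wide TSV
#'
#' @param profiles List of `perturbation_profile` objects sharing a gene set.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  genes <- names(profiles[[1L]]$z)
  zmat <- t(vapply(profiles, function(p) {
    stopifnot(identical(names(p$z), genes))
    p$z
  }, numeric(length(genes))))
  df <- cbind(
    data.frame(drug_id = vapply(profiles, `[[`, character(1), "drug_id"),
               dose = vapply(profiles, `[[`, numeric(1), "dose"),
               time_h = vapply(profiles, `[[`, numeric(1), "time_h"),
               stringsAsFactors = FALSE),
    as.data.frame(zmat, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select the analysis conditions for each drug
#'
#' Keeps, per drug, the profiles at the minimum and maximum dose; among
#' time points the 24-hour frame is preferred, and when a chosen dose has no
#' 24-hour profile the drug's default time point is used instead (the most
#' frequent time point among that drug's profiles, first in ascending order
#' on ties).
#'
#' @param profiles List of `perturbation_profile` objects (one or more
#'   drugs).
#' @return Named list of selected profiles.
#' @export
select_conditions <- function(profiles) {
  if (length(profiles) == 0L) return(profiles)
  drug <- vapply(profiles, `[[`, character(1), "drug_id")
  out <- list()
  for (d in unique(drug)) {
    ps <- profiles[drug == d]
    doses <- vapply(ps, `[[`, numeric(1), "dose")
    times <- vapply(ps, `[[`, numeric(1), "time_h")
    tt <- table(times)
    default_t <- min(as.numeric(names(tt)[tt == max(tt)]))  # ties: lowest time
    for (dd in unique(c(min(doses), max(doses)))) {
      at_dose <- ps[doses == dd]
      t_at <- vapply(at_dose, `[[`, numeric(1), "time_h")
      pick <- if (any(t_at == 24)) which(t_at == 24)[1L]
              else if (any(t_at == default_t)) which(t_at == default_t)[1L]
              else which.min(t_at)
      out[[at_dose[[pick]]$key]] <- at_dose[[pick]]
    }
  }
  out
}

#' Disease signature: robust subtype z-scores from an expression cohort
#'
#' For each gene, the signature z-score contrasts the subtype against the
#' rest of the cohort: `z = (median_in - median_out) / (1.4826 * MAD_out)`,
#' clipped to \[-10, 10\]. The MAD of the out-group is floored at 1e-6 times
#' the dynamic range of the expression matrix so that flat genes yield
#' finite values. Positive z means the gene is higher in the subtype.
#'
#' @param expression Gene x sample matrix.
#' @param labels Named character vector sample -> subtype.
#' @param subtype Subtype id (needs >= 3 samples in and out).
#' @return Object of class `disease_signature`: list with `subtype_id` and
#'   `z` (named numeric in \[-10, 10\]).
#' @export
normalize_signature <- function(expression, labels, subtype) {
  samples <- colnames(expression)
  stopifnot(all(samples %in% names(labels)))
  in_s <- samples[labels[samples] == subtype]
  out_s <- setdiff(samples, in_s)
  if (length(in_s) < 3L || length(out_s) < 3L) {
    stop("need >= 3 samples in the subtype and in the rest of the cohort")
  }
  rng <- diff(range(expression))
  floor_mad <- 1e-6 * max(rng, .Machine$double.eps)
  med_in <- apply(expression[, in_s, drop = FALSE], 1L, stats::median)
  med_out <- apply(expression[, out_s, drop = FALSE], 1L, stats::median)
  mad_out <- apply(expression[, out_s, drop = FALSE], 1L, stats::mad,
                   constant = 1)
  z <- (med_in - med_out) / (1.4826 * pmax(mad_out, floor_mad))
  structure(list(subtype_id = subtype, z = clip(z, -10, 10)),
            class = "disease_signature")
}

#' @export
print.disease_signature <- function(x, ...) {
  cat("Disease signature for subtype", x$subtype_id, "-", length(x$z),
      "genes, z range [", round(min(x$z), 2), ",", round(max(x$z), 2), "]\n")
  invisible(x)
}

#' Top drug genes by absolute z-score
#'
#' The drug genes of a condition are the `k` genes with the largest
#' absolute z-score (ties broken by gene symbol ascending). Works for both
#' single and combined profiles.
#'
#' @param profile A `perturbation_profile` or `combined_profile`.
#' @param k Number of genes to keep (default 50).
#' @return Character vector of at most `k` genes, strongest first.
#' @export
select_drug_genes <- function(profile, k = 50L) {
  stopifnot(k >= 1L)
  z <- profile$z
  if (length(z) == 0L) stop("empty profile")
  ord <- order(-abs(z), names(z))
  names(z)[ord][seq_len(min(k, length(z)))]
}

#' Additive combined profile for a drug pair
#'
#' Under the additivity assumption the pair's z-score on a gene is the sum
#' of the two single-drug z-scores. Only genes measured in both profiles are
#' kept; the sum is deliberately not clipped.
#'
#' @param p1,p2 `perturbation_profile` objects for two drugs.
#' @return Object of class `combined_profile` with `drug_ids`,
#'   `component_keys`, and `z`.
#' @export
combine_profiles <- function(p1, p2) {
  shared <- intersect(names(p1$z), names(p2$z))
  if (length(shared) == 0L) stop("profiles share no genes")
  structure(list(drug_ids = c(p1$drug_id, p2$drug_id),
                 component_keys = c(p1$key, p2$key),
                 z = p1$z[shared] + p2$z[shared]),
            class = "combined_profile")
}

#' @export
print.combined_profile <- function(x, ...) {
  cat("Combined profile", paste(x$component_keys, collapse = " + "), "-",
      length(x$z), "shared genes\n")
  invisible(x)
}
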