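# Validation experiments on ground-truthed synthetic data. The defaults ARE
# the study conditions: 200 genes, 10 types x 8 markers with 8-fold
# enrichment, two reference publications per type; cohort noise 0.3 on the
# log2 scale. They are fixed here so every report of these experiments runs
# under the same conditions.

.validation_profiles <- function(seed) {
  make_profiles(n_genes = 200L, markers_per_type = 8L, fold = 8,
                n_types = 10L, seed = seed)
}

.validation_db <- function(profiles, seed) {
  make_synthetic_db(profiles, pubs_per_type = 2L, seed = seed)
}

#' Pure-sample recovery experiment
#'
#' Generates one pure (one-hot) sample per cell type, scores the mixture
#' with [cell_type_indices()], and asks whether the largest consolidated
#' index of each sample identifies its true type. Repeated over `n_seeds`
#' independent profile/noise draws.
#'
#' @param noise_sd Log2-scale observation noise (0 = noiseless).
#' @param n_seeds Number of independent replicates.
#' @param seed Master seed; replicate seeds are derived from it.
#' @return Mean fraction of samples assigned to their true type
#'   (1 = perfect recovery).
#' @export
pure_type_recovery <- function(noise_sd = 0, n_seeds = 1L, seed = 1L) {
  acc <- vapply(seq_len(n_seeds), function(i) {
    si <- .child_seed(seed, i)
    profs <- .validation_profiles(si)
    db <- .validation_db(profs, si)
    mix <- simulate_mixture(profs, one_hot_design(length(profs$types)),
                            noise_sd = noise_sd, seed = .child_seed(si, 1L))
    ix <- suppressWarnings(suppressMessages(
      cell_type_indices(mix$expr, db)))
    truth <- colnames(mix$proportions)[apply(mix$proportions, 1L, which.max)]
    pred <- colnames(ix$consolidated)[apply(ix$consolidated, 1L, which.max)]
    mean(pred == truth)
  }, numeric(1))
  mean(acc)
}

#' Titration linearity experiment
#'
#' Builds noiseless two-type titration series (proportions 0, 0.25, 0.5,
#' 0.75, 1) for five disjoint type pairs and relates each mixed type's
#' consolidated index to its true proportion. Physical mixing is linear in
#' expression space while the indices are computed from log2 data, so exact
#' linearity is not guaranteed; rank agreement is.
#'
#' @param seed Master seed for the profile draw.
#' @return List with `min_spearman` and `min_r2`, the worst-case Spearman
#'   correlation and Pearson R-squared over all mixed type/pair
#'   combinations.
#' @export
titration_linearity <- function(seed = 1L) {
  profs <- .validation_profiles(seed)
  db <- .validation_db(profs, seed)
  n_types <- length(profs$types)
  pairs <- split(seq_len(n_types), rep(seq_len(n_types / 2), each = 2))
  rho <- r2 <- numeric(0)
  for (pr in pairs) {
    des <- titration_design(n_types, type_a = pr[1], type_b = pr[2])
    mix <- simulate_mixture(profs, des, noise_sd = 0,
                            seed = .child_seed(seed, pr[1]))
    ix <- suppressWarnings(suppressMessages(
      cell_type_indices(mix$expr, db)))
    for (ty in profs$types[pr]) {
      p_true <- mix$proportions[, ty]
      idx <- ix$consolidated[, ty]
      rho <- c(rho, stats::cor(idx, p_true, method = "spearman"))
      r2 <- c(r2, stats::cor(idx, p_true)^2)
    }
  }
  list(min_spearman = min(rho), min_r2 = min(r2))
}

#' Null-cohort false-positive-rate experiment
#'
#' Simulates cohorts with no covariate effect on composition, scans every
#' consolidated index against the standard covariate model
#' ([index_covariate_scan()] preset `"eq1"`), and reports the fraction of
#' nominal p-values below 0.05 — the empirical type-I error of the scan,
#' which should sit near 5%.
#'
#' @param n_reps Number of simulated cohorts.
#' @param n_samples Samples per cohort.
#' @param seed Master seed.
#' @return False-positive rate in percent.
#' @export
null_scan_fpr <- function(n_reps = 500L, n_samples = 200L, seed = 1L) {
  profs <- .validation_profiles(seed)
  db <- .validation_db(profs, seed)
  pvals <- unlist(lapply(seq_len(n_reps), function(i) {
    co <- simulate_cohort(profs, n_samples = n_samples,
                          seed = .child_seed(seed, i))
    ix <- suppressWarnings(suppressMessages(
      cell_type_indices(co$expr, db)))
    index_covariate_scan(ix, co$metadata, model = "eq1")$p
  }))
  100 * mean(pvals < 0.05)
}

#' Diagnosis effect-recovery experiment
#'
#' Simulates cohorts in which major depression shifts the astrocyte
#' log-odds by `effect` (negative = fewer astrocytes), scans the indices
#' against the covariate model, and reports how often the fitted MDD
#' coefficient on the Astrocyte index is negative — sign recovery of a
#' known compositional effect.
#'
#' @param n_seeds Number of simulated cohorts.
#' @param effect Astrocyte log-odds shift for MDD samples (default -0.5).
#' @param n_samples Samples per cohort.
#' @param noise_sd Log2-scale expression noise.
#' @param seed Master seed.
#' @return Fraction of cohorts with a negative Astrocyte-index MDD beta.
#' @export
mdd_astrocyte_recovery <- function(n_seeds = 200L, effect = -0.5,
                                   n_samples = 150L, noise_sd = 0.3,
                                   seed = 1L) {
  profs <- .validation_profiles(seed)
  db <- .validation_db(profs, seed)
  hits <- vapply(seq_len(n_seeds), function(i) {
    co <- simulate_cohort(profs, n_samples = n_samples,
                          effects = list(diagnosisMDD = c(Astrocyte = effect)),
                          noise_sd = noise_sd, seed = .child_seed(seed, i))
    ix <- suppressWarnings(suppressMessages(
      cell_type_indices(co$expr, db)))
    sc <- index_covariate_scan(ix, co$metadata, model = "eq1")
    sc$beta[sc$cell_type == "Astrocyte" & sc$covariate == "diagnosisMDD"] < 0
  }, logical(1))
  mean(hits)
}

#' Composition-mediation experiment for differential expression
#'
#' Simulates cohorts whose only diagnosis effect is a shift in astrocyte
#' proportion, so astrocyte marker genes show diagnosis "differential
#' expression" that is entirely composition-driven. Each cohort is fitted
#' under the standard covariate model (M2) and the model adding the five
#' prevalent cell-type indices (M4). Reports how often (a) the mean
#' absolute diagnosis effect over astrocyte markers shrinks from M2 to M4
#' (attenuation by the composition covariates) and (b) the mean per-gene
#' centered BIC over those same composition-driven marker genes favors M4
#' over M2.
#'
#' @param n_seeds Number of simulated cohorts.
#' @param effect Astrocyte log-odds shift for MDD samples (default -0.8, a
#'   marked composition shift).
#' @param n_samples Samples per cohort.
#' @param seed Master seed.
#' @return List: `attenuation_rate`, `bic_favors_m4_rate`, and
#'   `mean_bic_diff` (across-seed mean of centered BIC(M4) - BIC(M2);
#'   negative favors M4).
#' @export
mediation_experiment <- function(n_seeds = 200L, effect = -0.8,
                                 n_samples = 150L, seed = 1L) {
  profs <- .validation_profiles(seed)
  db <- .validation_db(profs, seed)
  astro <- names(profs$marker_map)[profs$marker_map == "Astrocyte"]
  specs <- de_model_specs()[c("M2", "M4")]
  class(specs) <- "de_model_specs"

  res <- vapply(seq_len(n_seeds), function(i) {
    co <- simulate_cohort(profs, n_samples = n_samples,
                          effects = list(diagnosisMDD = c(Astrocyte = effect)),
                          seed = .child_seed(seed, i))
    ix <- suppressWarnings(suppressMessages(
      cell_type_indices(co$expr, db)))
    de <- suppressMessages(
      fit_de_models(co$expr, co$metadata, ix, specs = specs,
                    contrast = "MDD"))
    d <- as.data.frame(de)
    b2 <- abs(d$beta[d$model == "M2" & d$gene %in% astro])
    b4 <- abs(d$beta[d$model == "M4" & d$gene %in% astro])
    cs <- model_fit_summary(de, center = TRUE, genes = astro)
    bic_diff <- cs$mean_bic[cs$model == "M4"] - cs$mean_bic[cs$model == "M2"]
    c(attenuated = mean(b4) < mean(b2), bic_diff = bic_diff)
  }, numeric(2))
  list(attenuation_rate = mean(res["attenuated", ]),
       bic_favors_m4_rate = mean(res["bic_diff", ] < 0),
       mean_bic_diff = mean(res["bic_diff", ]))
}
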