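# Ground-truthed simulator: purified cell profiles, linear-space mixtures
# observed on the log2 scale, and covariate-driven cohorts. A single seed
# drives every draw; child seeds are derived with a Lehmer step so nested
# generators are reproducible yet decoupled.

.child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate purified cell-type expression profiles
#'
#' Generates linear-scale mean expression profiles for `n_types` cell types
#' (labeled from [CELL_TYPE_CATEGORIES]). Baseline expression per gene is
#' log-normal (meanlog 5, sdlog 1, i.e. typical linear intensities of a few
#' hundred with a long right tail); each type receives a disjoint block of
#' `markers_per_type` marker genes whose mean in that type is `fold` times
#' baseline.
#'
#' @param n_genes Total genes (>= `n_types * markers_per_type`).
#' @param markers_per_type Markers per cell type.
#' @param fold Marker enrichment factor (> 1). Purified-cell studies report
#'   specific transcripts enriched several-fold to orders of magnitude; the
#'   default of 8 is a moderate, realistic enrichment.
#' @param n_types Number of cell types (<= 10).
#' @param seed Integer seed; the same seed reproduces the profiles exactly.
#' @return Object of class `cell_profiles`: list with `profiles` (genes x
#'   types linear-scale matrix), `marker_map` (named character, marker gene
#'   -> cell type), `baseline`, `fold`, `types`, `seed`.
#' @export
make_profiles <- function(n_genes = 200L, markers_per_type = 8L, fold = 8,
                          n_types = 10L, seed = 1L) {
  n_genes <- as.integer(n_genes)
  markers_per_type <- as.integer(markers_per_type)
  n_types <- as.integer(n_types)
  if (n_types < 1L || n_types > length(CELL_TYPE_CATEGORIES))
    stop("n_types must be between 1 and ", length(CELL_TYPE_CATEGORIES))
  if (markers_per_type < 1L) stop("markers_per_type must be >= 1")
  if (n_genes < n_types * markers_per_type)
    stop("infeasible marker allocation: need n_genes >= n_types * markers_per_type")
  if (!is.finite(fold) || fold <= 1)
    stop("fold must be > 1 (markers must be enriched in their own type)")

  types <- CELL_TYPE_CATEGORIES[seq_len(n_types)]
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  .with_seed(seed, {
    baseline <- stats::rlnorm(n_genes, meanlog = 5, sdlog = 1)
  })
  names(baseline) <- genes

  profiles <- matrix(baseline, nrow = n_genes, ncol = n_types,
                     dimnames = list(genes, types))
  marker_map <- character(0)
  for (k in seq_len(n_types)) {
    rows <- ((k - 1L) * markers_per_type + 1L):(k * markers_per_type)
    profiles[rows, k] <- fold * baseline[rows]
    mm <- rep(types[k], length(rows))
    names(mm) <- genes[rows]
    marker_map <- c(marker_map, mm)
  }
  structure(
    list(profiles = profiles, marker_map = marker_map, baseline = baseline,
         fold = fold, types = types, seed = as.integer(seed)),
    class = "cell_profiles")
}

#' @export
print.cell_profiles <- function(x, ...) {
  cat("Simulated purified cell profiles\n")
  cat("  genes: ", nrow(x$profiles), " (", length(x$marker_map),
      " markers)\n", sep = "")
  cat("  types: ", paste(x$types, collapse = ", "), "\n", sep = "")
  cat("  marker fold enrichment: ", x$fold, "\n", sep = "")
  invisible(x)
}

#' One-hot (pure sample) mixture design
#'
#' @param n_types Number of types; returns the identity design with one
#'   pure sample per type.
#' @return `n_types` x `n_types` proportion matrix.
#' @export
one_hot_design <- function(n_types) {
  diag(n_types)
}

#' Two-type titration mixture design
#'
#' Titration series between two cell types: proportions of `type_a` running
#' over `points` (default 0, 0.25, 0.5, 0.75, 1) with the remainder
#' assigned to `type_b`, all other types absent.
#'
#' @param n_types Total number of types in the profile set.
#' @param type_a,type_b Column indices of the two mixed types.
#' @param points Proportions of `type_a`.
#' @return `length(points)` x `n_types` proportion matrix.
#' @export
titration_design <- function(n_types, type_a = 1L, type_b = 2L,
                             points = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(type_a != type_b, all(points >= 0), all(points <= 1))
  p <- matrix(0, nrow = length(points), ncol = n_types)
  p[, type_a] <- points
  p[, type_b] <- 1 - points
  p
}

#' Simulate expression for mixtures of purified profiles
#'
#' Cells mix physically in linear expression space: the expected linear
#' value of a sample is the proportion-weighted sum of the type profiles.
#' The observed value is `log2(x + 1)` plus additive Gaussian noise of sd
#' `noise_sd` on the log2 scale (the standard microarray error model).
#'
#' @param profiles A `cell_profiles` object.
#' @param proportions Samples x types matrix; every row must lie on the
#'   simplex (non-negative, sums to 1 within 1e-12).
#' @param noise_sd Log2-scale noise sd (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return List with `expr` (genes x samples log2-scale matrix),
#'   `gene_map` (identity row id -> gene symbol map), `proportions`
#'   (the ground truth, with type column names attached).
#' @export
simulate_mixture <- function(profiles, proportions, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(profiles, "cell_profiles"))
  p <- as.matrix(proportions)
  if (ncol(p) != length(profiles$types))
    stop("proportions must have one column per profile type")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-12))
    stop("every proportions row must be non-negative and sum to 1")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  colnames(p) <- profiles$types
  if (is.null(rownames(p)))
    rownames(p) <- sprintf("sample_%02d", seq_len(nrow(p)))

  linear <- profiles$profiles %*% t(p)       # genes x samples
  expr <- log2(linear + 1)
  if (noise_sd > 0) {
    .with_seed(seed, {
      expr <- expr + matrix(stats::rnorm(length(expr), sd = noise_sd),
                            nrow = nrow(expr))
    })
  }
  dimnames(expr) <- list(rownames(profiles$profiles), rownames(p))
  gene_map <- rownames(expr)
  names(gene_map) <- rownames(expr)
  list(expr = expr, gene_map = gene_map, proportions = p)
}

.default_base_proportions <- c(
  Astrocyte = 0.19, Endothelial = 0.05, Microglia = 0.06, Mural = 0.02,
  Neuron_All = 0.20, Neuron_Interneuron = 0.09, Neuron_Projection = 0.18,
  Oligodendrocyte = 0.15, Oligodendrocyte_Immature = 0.04, RBC = 0.02
)

#' Simulate a post-mortem brain cohort with covariate-driven composition
#'
#' Generates a cohort of bulk samples whose cell-type proportions respond to
#' subject covariates. Per-sample proportions are
#' `softmax(base log-odds + per-sample jitter + sum(covariate x effect))`,
#' keeping them on the simplex under arbitrary effects; expression then
#' follows [simulate_mixture()]. Covariates mimic a post-mortem brain
#' cohort: brain pH ~ N(6.7, 0.25), agonal factor uniform on 0..4, PMI
#' (hours) ~ Gamma(shape 6, scale 4), age ~ N(50, 15) truncated at 18,
#' sex F/M (balanced), diagnosis CTRL/MDD/BP/SCHIZ with probabilities
#' 0.45/0.25/0.15/0.15, two batches.
#'
#' Effects are specified on the log-odds scale per design-matrix term:
#' `effects = list(diagnosisMDD = c(Astrocyte = -0.5))` shifts the astrocyte
#' log-odds of MDD samples by -0.5. Continuous covariates (pH, PMI, age,
#' agonal factor) enter the composition model centered and scaled so effect
#' sizes are comparable across units; factor terms enter as 0/1 dummies
#' (reference levels: diagnosis CTRL, sex F).
#'
#' @param profiles A `cell_profiles` object.
#' @param n_samples Number of samples (>= 2).
#' @param effects Named list: design term -> named numeric vector of
#'   per-type log-odds shifts. Unknown terms or types are an error.
#' @param noise_sd Log2-scale expression noise sd (default 0.3, a moderate
#'   technical noise level for normalized arrays).
#' @param prop_noise_sd Per-sample log-odds jitter sd (default 0.3), giving
#'   biological composition variability independent of the covariates.
#' @param base_logodds Optional named per-type base log-odds; defaults to
#'   the log of typical cortical proportions for the simulated types.
#' @param seed Integer seed.
#' @return Object of class `synthetic_cohort`: list with `expr`, `gene_map`,
#'   `metadata` (data frame of covariates with factor reference levels set),
#'   `true_proportions`, `true_effects`, `seed`.
#' @export
simulate_cohort <- function(profiles, n_samples = 100L, effects = list(),
                            noise_sd = 0.3, prop_noise_sd = 0.3,
                            base_logodds = NULL, seed = 1L) {
  stopifnot(inherits(profiles, "cell_profiles"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) stop("n_samples must be >= 2")
  types <- profiles$types

  if (is.null(base_logodds)) {
    bp <- .default_base_proportions[types]
    base_logodds <- log(bp / sum(bp))
  } else {
    if (is.null(names(base_logodds)) || !all(types %in% names(base_logodds)))
      stop("base_logodds must be named with every profile type")
    base_logodds <- base_logodds[types]
  }

  meta <- .with_seed(.child_seed(seed, 1L), {
    data.frame(
      sample_id = sprintf("sample_%03d", seq_len(n_samples)),
      pH = stats::rnorm(n_samples, 6.7, 0.25),
      agonal_factor = sample(0:4, n_samples, replace = TRUE),
      PMI = stats::rgamma(n_samples, shape = 6, scale = 4),
      age = pmax(18, stats::rnorm(n_samples, 50, 15)),
      sex = factor(sample(c("F", "M"), n_samples, replace = TRUE),
                   levels = c("F", "M")),
      diagnosis = factor(sample(c("CTRL", "MDD", "BP", "SCHIZ"), n_samples,
                                replace = TRUE,
                                prob = c(0.45, 0.25, 0.15, 0.15)),
                         levels = c("CTRL", "MDD", "BP", "SCHIZ")),
      batch = factor(sample(c("b1", "b2"), n_samples, replace = TRUE)),
      stringsAsFactors = FALSE
    )
  })

  # design terms available to effects: scaled continuous + 0/1 dummies
  design <- cbind(
    pH = as.vector(scale(meta$pH)),
    agonal_factor = as.vector(scale(meta$agonal_factor)),
    PMI = as.vector(scale(meta$PMI)),
    age = as.vector(scale(meta$age)),
    sexM = as.numeric(meta$sex == "M"),
    diagnosisMDD = as.numeric(meta$diagnosis == "MDD"),
    diagnosisBP = as.numeric(meta$diagnosis == "BP"),
    diagnosisSCHIZ = as.numeric(meta$diagnosis == "SCHIZ"),
    batchb2 = as.numeric(meta$batch == "b2")
  )

  logodds <- matrix(base_logodds, nrow = n_samples, ncol = length(types),
                    byrow = TRUE, dimnames = list(meta$sample_id, types))
  if (length(effects)) {
    if (is.null(names(effects)) || any(!nzchar(names(effects))))
      stop("effects must be a named list (design term -> per-type shifts)")
    unknown <- setdiff(names(effects), colnames(design))
    if (length(unknown))
      stop("unknown effect term(s): ", paste(unknown, collapse = ", "),
           "; available: ", paste(colnames(design), collapse = ", "))
    for (term in names(effects)) {
      ef <- effects[[term]]
      if (is.null(names(ef)) || !all(names(ef) %in% types))
        stop("effect for '", term, "' must be named with profile types")
      full <- stats::setNames(numeric(length(types)), types)
      full[names(ef)] <- ef
      logodds <- logodds + outer(design[, term], full)
    }
  }
  if (prop_noise_sd > 0) {
    .with_seed(.child_seed(seed, 2L), {
      logodds <- logodds + matrix(
        stats::rnorm(length(logodds), sd = prop_noise_sd),
        nrow = n_samples)
    })
  }
  elo <- exp(logodds - apply(logodds, 1L, max))
  props <- elo / rowSums(elo)
  rownames(props) <- meta$sample_id

  mix <- simulate_mixture(profiles, props, noise_sd = noise_sd,
                          seed = .child_seed(seed, 3L))
  structure(
    list(expr = mix$expr, gene_map = mix$gene_map, metadata = meta,
         true_proportions = props, true_effects = effects,
         seed = as.integer(seed)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic post-mortem cohort\n")
  cat("  samples: ", ncol(x$expr), ", genes: ", nrow(x$expr), "\n", sep = "")
  cat("  types:   ", paste(colnames(x$true_proportions), collapse = ", "),
      "\n", sep = "")
  cat("  covariate effects: ",
      if (length(x$true_effects)) paste(names(x$true_effects), collapse = ", ")
      else "none (null cohort)", "\n", sep = "")
  invisible(x)
}

#' Build a marker database from simulated profiles
#'
#' Mirrors the structure of a curated marker table for testing: each type's
#' markers are assigned to `pubs_per_type` synthetic publication tags
#' (markers duplicated across the tags, as real reference studies
#' re-identify overlapping gene lists), and `overlap_genes` markers are
#' additionally assigned to a second category to exercise cross-category
#' overlap removal.
#'
#' @param profiles A `cell_profiles` object.
#' @param pubs_per_type Publication tags per type (>= 1).
#' @param overlap_genes Number of markers also listed under the next
#'   category (0 or more; cannot exceed the available markers).
#' @param seed Integer seed (draws which markers become cross-category).
#' @return A `marker_db`.
#' @export
make_synthetic_db <- function(profiles, pubs_per_type = 2L, overlap_genes = 0L,
                              seed = 1L) {
  stopifnot(inherits(profiles, "cell_profiles"))
  pubs_per_type <- as.integer(pubs_per_type)
  overlap_genes <- as.integer(overlap_genes)
  if (pubs_per_type < 1L) stop("pubs_per_type must be >= 1")
  if (overlap_genes > length(profiles$marker_map))
    stop("overlap_genes exceeds the number of available markers")

  types <- profiles$types
  rows <- list()
  for (ty in types) {
    markers <- names(profiles$marker_map)[profiles$marker_map == ty]
    for (p in seq_len(pubs_per_type)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_symbol = markers,
        primary_category = ty,
        publication_tag = sprintf("%s_Ref%d", ty, p),
        species = "synthetic", brain_region = "cortex",
        platform = "simulated", citation = "synthetic profile set",
        stringsAsFactors = FALSE)
    }
  }
  if (overlap_genes > 0L) {
    if (length(types) < 2L)
      stop("cross-category overlaps need at least 2 types")
    picked <- .with_seed(.child_seed(seed, 7L),
                         sample(names(profiles$marker_map), overlap_genes))
    own <- profiles$marker_map[picked]
    other <- types[(match(own, types) %% length(types)) + 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_symbol = picked,
      primary_category = other,
      publication_tag = sprintf("%s_Ref1", other),
      species = "synthetic", brain_region = "cortex",
      platform = "simulated", citation = "synthetic cross-category entry",
      stringsAsFactors = FALSE)
  }
  marker_db(do.call(rbind, rows))
}
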