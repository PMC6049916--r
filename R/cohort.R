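# Relating cell-type indices to subject covariates: per-index OLS scans,
# fixed-effects meta-analysis across studies, and the small-sample
# descriptive statistics used in validation (Welch t, Cohen's d, BH
# adjustment, PCA association).

.indices_matrix <- function(indices, which = "consolidated") {
  if (inherits(indices, "celltype_indices")) return(indices[[which]])
  m <- as.matrix(indices)
  if (!is.numeric(m)) stop("indices must be numeric")
  m
}

#' Ordinary least-squares fit with full diagnostics
#'
#' Thin, validated wrapper around [stats::lm()] used throughout the
#' covariate scans: treatment coding against declared reference levels,
#' listwise deletion of incomplete rows (n reported), an explicit
#' rank-deficiency error naming the collinear columns, and information
#' criteria from the full Gaussian log-likelihood (constants included) so
#' differences are comparable across models.
#'
#' @param formula Model formula; the response may name a column of `data`.
#' @param data Data frame of response and covariates.
#' @return Object of class `blendr_lm`: list with `terms` (data frame of
#'   term, beta, se, t, p), `r2`, `adj_r2`, `aic`, `bic`, `n`, `df`,
#'   `residuals`, and the underlying `lm` fit in `fit`.
#' @export
fit_linear <- function(formula, data) {
  data <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  n <- nrow(data)
  fit <- stats::lm(formula, data = data)
  X <- stats::model.matrix(fit)
  if (fit$rank < ncol(X)) {
    aliased <- names(which(is.na(stats::coef(fit))))
    stop("design is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  if (n <= ncol(X))
    stop("need more observations (", n, ") than parameters (", ncol(X), ")")
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(terms = data.frame(term = rownames(co), beta = co[, 1L],
                            se = co[, 2L], t = co[, 3L], p = co[, 4L],
                            row.names = NULL),
         r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
         aic = stats::AIC(fit), bic = stats::BIC(fit),
         n = n, df = fit$df.residual,
         residuals = stats::residuals(fit), fit = fit),
    class = "blendr_lm")
}

#' @export
print.blendr_lm <- function(x, ...) {
  cat("OLS fit: n = ", x$n, ", residual df = ", x$df,
      ", R2 = ", signif(x$r2, 3), " (adj ", signif(x$adj_r2, 3), ")\n",
      sep = "")
  print(x$terms, digits = 3, row.names = FALSE)
  invisible(x)
}

.scan_presets <- list(
  eq1 = list(required = c("pH", "agonal_factor", "PMI", "age", "sex",
                          "diagnosis"),
             optional = "exsanguination"),
  eq2 = list(required = c("pH", "PMI", "age", "sex", "diagnosis",
                          "rna_degradation"),
             optional = "batch"),
  eq3 = list(required = c("pH", "PMI", "age", "sex", "diagnosis",
                          "rna_degradation", "institution",
                          "manner_of_death"),
             optional = character(0))
)

.prepare_covars <- function(covars, ref_diagnosis = "CTRL", ref_sex = "F") {
  covars <- as.data.frame(covars)
  if ("diagnosis" %in% names(covars)) {
    covars$diagnosis <- stats::relevel(factor(covars$diagnosis),
                                       ref = ref_diagnosis)
  }
  if ("sex" %in% names(covars)) {
    covars$sex <- stats::relevel(factor(covars$sex), ref = ref_sex)
  }
  covars
}

#' Scan cell-type indices against subject covariates
#'
#' Fits one multiple-regression model per consolidated cell-type index with
#' all covariates entered simultaneously, and returns a tidy long table of
#' per-term estimates. Model presets mirror the three covariate sets used
#' for post-mortem cohorts: `"eq1"` (pH, agonal factor, PMI, age, sex,
#' diagnosis, plus exsanguination when available), `"eq2"` (pH, PMI, age,
#' sex, diagnosis, RNA degradation, plus batch when available), `"eq3"`
#' (adds institution and manner of death). A custom formula right-hand side
#' may be supplied instead. Categorical covariates are treatment-coded
#' against declared reference levels (diagnosis `CTRL`, sex `F` by
#' default); q-values are BH-adjusted over the entire scan table.
#'
#' @param indices A `celltype_indices` object or samples x indices matrix.
#' @param covars Data frame of per-sample covariates, rows aligned with the
#'   index rows.
#' @param model `"eq1"`, `"eq2"`, `"eq3"`, or a one-sided formula
#'   (e.g. `~ pH + age`).
#' @param dataset Optional label recorded in the output's `dataset` column
#'   (used by [meta_analyze()]).
#' @param ref_diagnosis,ref_sex Reference levels for treatment coding.
#' @return Data frame of class `index_scan` with columns `cell_type`,
#'   `covariate`, `beta`, `se`, `t`, `p`, `q`, `n`, `dataset` (intercept
#'   rows omitted).
#' @export
index_covariate_scan <- function(indices, covars, model = "eq1",
                                 dataset = NA_character_,
                                 ref_diagnosis = "CTRL", ref_sex = "F") {
  im <- .indices_matrix(indices)
  covars <- .prepare_covars(covars, ref_diagnosis, ref_sex)
  if (nrow(covars) != nrow(im))
    stop("covariate table and index table have different numbers of samples")

  if (inherits(model, "formula")) {
    rhs_terms <- attr(stats::terms(model), "term.labels")
    missing_cols <- setdiff(all.vars(model), names(covars))
    if (length(missing_cols))
      stop("covariate table is missing column(s): ",
           paste(missing_cols, collapse = ", "))
  } else {
    model <- match.arg(model, names(.scan_presets))
    preset <- .scan_presets[[model]]
    missing_cols <- setdiff(preset$required, names(covars))
    if (length(missing_cols))
      stop("covariate table is missing required column(s) for ", model, ": ",
           paste(missing_cols, collapse = ", "))
    rhs_terms <- c(preset$required,
                   intersect(preset$optional, names(covars)))
  }
  rhs <- paste(rhs_terms, collapse = " + ")

  rows <- lapply(colnames(im), function(ct) {
    dat <- cbind(data.frame(.y = im[, ct]), covars)
    f <- stats::as.formula(paste(".y ~", rhs))
    fit <- fit_linear(f, dat)
    tt <- fit$terms[fit$terms$term != "(Intercept)", , drop = FALSE]
    data.frame(cell_type = ct, covariate = tt$term, beta = tt$beta,
               se = tt$se, t = tt$t, p = tt$p, n = fit$n,
               dataset = dataset, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[, c("cell_type", "covariate", "beta", "se", "t", "p", "q",
                 "n", "dataset")]
  rownames(out) <- NULL
  class(out) <- c("index_scan", "data.frame")
  out
}

#' Fixed-effects (inverse-variance) meta-analysis of one effect
#'
#' Pools per-study regression coefficients assuming a single common effect:
#' the pooled estimate is the inverse-variance weighted mean
#' `b = sum(b_i/v_i) / sum(1/v_i)` with standard error
#' `SE = (sum(1/v_i))^(-1/2)`; inference uses the normal approximation
#' (z = b/SE, two-sided p).
#'
#' @param b Numeric vector of per-study coefficients (>= 1 study).
#' @param v Numeric vector of their sampling variances (all > 0). Squared
#'   standard errors.
#' @return List with `b`, `se`, `z`, `p`, `k` (number of studies).
#' @export
meta_fixed <- function(b, v) {
  b <- as.numeric(b); v <- as.numeric(v)
  if (length(b) == 0L || length(b) != length(v))
    stop("b and v must be non-empty vectors of equal length")
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all sampling variances must be finite and > 0")
  w <- 1 / v
  est <- sum(w * b) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- est / se
  list(b = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)), k = length(b))
}

#' Meta-analyze covariate scans across datasets
#'
#' Pools the per-(cell type x covariate) betas of several
#' [index_covariate_scan()] tables by fixed-effects inverse-variance
#' weighting ([meta_fixed()]); q-values are BH-adjusted over the whole
#' pooled table (the full family of cell types x covariates).
#'
#' @param scans List of `index_scan` data frames (one per dataset).
#' @return Data frame with columns `cell_type`, `covariate`, `b`, `se`,
#'   `z`, `p`, `q`, `k` (studies pooled).
#' @export
meta_analyze <- function(scans) {
  if (!is.list(scans) || length(scans) == 0L)
    stop("scans must be a non-empty list of scan tables")
  all <- do.call(rbind, lapply(scans, as.data.frame))
  key <- interaction(all$cell_type, all$covariate, drop = TRUE)
  rows <- lapply(split(all, key), function(g) {
    m <- meta_fixed(g$beta, g$se^2)
    data.frame(cell_type = g$cell_type[1L], covariate = g$covariate[1L],
               b = m$b, se = m$se, z = m$z, p = m$p, k = m$k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$cell_type, out$covariate),
             c("cell_type", "covariate", "b", "se", "z", "p", "q", "k")]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Validated wrapper around `stats::p.adjust(method = "BH")`: q-values
#' controlling the false discovery rate,
#' `q_(i) = min_{j >= i} (m * p_(j) / j)` capped at 1, order-preserving.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs propagate).
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad))
    stop("p-values outside [0, 1] at position(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  stats::p.adjust(p, method = "BH")
}

#' Welch's unequal-variance t-test
#'
#' @param x,y Numeric vectors, each with >= 2 finite values and nonzero
#'   combined variance.
#' @return List with `t`, `df` (Welch-Satterthwaite), and two-sided `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 finite values")
  if (stats::var(x) + stats::var(y) == 0)
    stop("degenerate groups: combined variance is zero")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Cohen's d (classic pooled-sd convention)
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled` with the
#' classic pooled standard deviation
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' Antisymmetric in its arguments.
#'
#' @param x,y Numeric vectors (>= 2 finite values each).
#' @return The standardized mean difference (scalar).
#' @export
cohens_d <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 finite values")
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  (mean(x) - mean(y)) / sp
}

#' Associate principal components with cell-type indices
#'
#' Decomposes the expression matrix by PCA (rows centered across samples
#' before decomposition) and regresses each of the first `n_pcs` sample
#' scores on each cell-type index, reporting per-PC percent variance and
#' per (PC x index) R-squared. Declared index combinations (e.g. the
#' average of the astrocyte and endothelial indices) can be added via
#' `combos`. Optionally all database marker genes are excluded first, to
#' check that index-PC correlations do not arise merely from marker genes
#' dominating the variable transcripts.
#'
#' @param x Expression matrix (rows = transcripts, columns = samples).
#' @param indices A `celltype_indices` object or samples x indices matrix.
#' @param n_pcs Number of leading components (<= min(genes, samples)).
#' @param exclude_db_genes If `TRUE`, drop rows annotated to any database
#'   gene before the PCA (requires `db`).
#' @param db A `marker_db` (needed when `exclude_db_genes = TRUE`).
#' @param gene_map Optional row id -> gene symbol map for the exclusion.
#' @param combos Named list of index-column vectors averaged into
#'   additional predictors, e.g.
#'   `list(astro_endo = c("Astrocyte", "Endothelial"))`.
#' @return List with `var_explained` (percent, per PC), `scores`
#'   (samples x PCs), and `r2` (PC x predictor matrix of R-squared).
#' @export
pc_association <- function(x, indices, n_pcs = 2L, exclude_db_genes = FALSE,
                           db = NULL, gene_map = NULL, combos = list()) {
  x <- .as_expr_matrix(x)
  if (exclude_db_genes) {
    if (is.null(db)) stop("exclude_db_genes = TRUE requires db")
    sym <- if (is.null(gene_map)) rownames(x) else
      as.character(gene_map[rownames(x)])
    keep <- !(toupper(sym) %in% unique(db$entries$gene_symbol))
    if (!any(keep))
      stop("excluding database genes leaves an empty matrix")
    x <- x[keep, , drop = FALSE]
  }
  n_pcs <- as.integer(n_pcs)
  if (n_pcs < 1L || n_pcs > min(dim(x)))
    stop("n_pcs must be between 1 and min(genes, samples) = ", min(dim(x)))

  pca <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- 100 * pca$sdev^2 / sum(pca$sdev^2)
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]

  im <- .indices_matrix(indices)
  if (nrow(im) != ncol(x))
    stop("index table and expression matrix have different sample counts")
  preds <- im
  for (nm in names(combos)) {
    cols <- combos[[nm]]
    if (!all(cols %in% colnames(im)))
      stop("combo '", nm, "' references unknown index column(s)")
    preds <- cbind(preds, rowMeans(im[, cols, drop = FALSE]))
    colnames(preds)[ncol(preds)] <- nm
  }
  r2 <- matrix(NA_real_, nrow = n_pcs, ncol = ncol(preds),
               dimnames = list(colnames(scores), colnames(preds)))
  for (i in seq_len(n_pcs)) {
    for (j in seq_len(ncol(preds))) {
      r2[i, j] <- stats::cor(scores[, i], preds[, j])^2
    }
  }
  list(var_explained = ve[seq_len(n_pcs)], scores = scores, r2 = r2)
}
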