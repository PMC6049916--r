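# Per-gene differential expression under nested model specifications
# (diagnosis only; + traditional covariates; + cell-type index covariates),
# compared by information criteria, replication against prior-effect
# reference lists, and Fisher exact enrichment.

#' Nested differential-expression model specifications
#'
#' Defines the five model specifications compared throughout: M1 diagnosis
#' only; M2 diagnosis + traditional subject covariates; M3 diagnosis + the
#' five most prevalent cell-type indices; M4 = M3 + traditional covariates;
#' M5 diagnosis + traditional covariates + all ten indices. By term set,
#' M1 is nested in M2 is nested in M5, and M3 in M4 in M5.
#'
#' @param traditional Character vector of traditional covariate column
#'   names (dataset-specific; default mirrors a pH/agonal/PMI/age/sex
#'   covariate set).
#' @param prevalent Index columns used by the reduced models (default
#'   [PREVALENT_CELL_TYPES], chosen to avoid multicollinearity among all
#'   ten indices).
#' @param all_indices Index columns for the full model; `NULL` (default)
#'   means all available consolidated index columns at fit time.
#' @return Named list of class `de_model_specs`; each element is a list
#'   with `diagnosis` (logical), `covariates`, `indices`.
#' @export
de_model_specs <- function(traditional = c("pH", "agonal_factor", "PMI",
                                           "age", "sex"),
                           prevalent = PREVALENT_CELL_TYPES,
                           all_indices = NULL) {
  structure(list(
    M1 = list(covariates = character(0), indices = character(0)),
    M2 = list(covariates = traditional, indices = character(0)),
    M3 = list(covariates = character(0), indices = prevalent),
    M4 = list(covariates = traditional, indices = prevalent),
    M5 = list(covariates = traditional,
              indices = if (is.null(all_indices)) NA_character_ else all_indices)
  ), class = "de_model_specs")
}

# multi-response OLS: one fixed design, many gene responses.
# Returns per-response coef/se/t/p plus Gaussian AIC/BIC (full
# log-likelihood including constants, sigma counted as a parameter, so
# values agree with stats::AIC/BIC on lm).
.ols_multi <- function(X, Y) {
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (n <= p) stop("need more samples (", n, ") than parameters (", p, ")")
  coef <- qr.coef(qrX, Y)
  res <- Y - X %*% coef
  rss <- colSums(res^2)
  df <- n - p
  # responses fit exactly (e.g. constant genes): no evidence of any effect;
  # report zero effects with p = 1 rather than 0/0 noise ratios
  scale_y <- pmax(1, colSums(Y^2) / n)
  degenerate <- rss < 1e-12 * n * scale_y
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qrX))
  o <- order(qrX$pivot)
  xtx_inv <- xtx_inv[o, o, drop = FALSE]
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  dimnames(se) <- dimnames(coef)
  tval <- coef / se
  pval <- 2 * stats::pt(-abs(tval), df = df)
  if (any(degenerate)) {
    non_int <- rownames(coef) != "(Intercept)"
    coef[non_int, degenerate] <- 0
    se[, degenerate] <- 0
    tval[, degenerate] <- 0
    pval[, degenerate] <- 1
  }
  ll <- -n / 2 * (log(2 * pi) + log(pmax(rss, .Machine$double.xmin) / n) + 1)
  k <- p + 1  # + residual variance
  list(coef = coef, se = se, t = tval, p = pval, df = df,
       aic = -2 * ll + 2 * k, bic = -2 * ll + log(n) * k, rss = rss)
}

#' Fit per-gene differential-expression models of increasing complexity
#'
#' Fits every gene under each model specification by OLS on one shared,
#' listwise-complete sample set (identical data across specifications, so
#' AIC/BIC are comparable between models), and extracts the diagnosis
#' effect for the requested contrast level. Diagnosis enters as a single
#' multi-level factor (treatment-coded against `ref_diagnosis`) with the
#' per-level coefficient extracted, not as per-diagnosis subset models.
#' q-values are BH-adjusted within each model.
#'
#' @param x Expression matrix (rows = genes/probes, columns = samples).
#' @param covars Data frame of per-sample covariates including a
#'   `diagnosis` column; rows aligned with the columns of `x`.
#' @param indices A `celltype_indices` object or samples x indices matrix.
#' @param specs Model specifications from [de_model_specs()].
#' @param contrast Diagnosis level whose effect is reported (e.g.
#'   `"SCHIZ"`); must be a level of `covars$diagnosis` other than the
#'   reference.
#' @param ref_diagnosis,ref_sex Reference levels for treatment coding.
#' @return Object of class `de_result`: data frame with columns `gene`,
#'   `model`, `beta` (log2-scale effect of the contrast level), `se`, `t`,
#'   `p`, `q`, `aic`, `bic`; the common sample size is in attribute `"n"`.
#' @export
fit_de_models <- function(x, covars, indices, specs = de_model_specs(),
                          contrast, ref_diagnosis = "CTRL", ref_sex = "F") {
  x <- .as_expr_matrix(x)
  covars <- .prepare_covars(covars, ref_diagnosis, ref_sex)
  if (nrow(covars) != ncol(x))
    stop("covariate table rows must match expression matrix columns")
  if (!"diagnosis" %in% names(covars))
    stop("covariate table must contain a 'diagnosis' column")
  if (!contrast %in% levels(covars$diagnosis))
    stop("contrast level '", contrast, "' not present in diagnosis")
  im <- .indices_matrix(indices)
  if (nrow(im) != ncol(x))
    stop("index table rows must match expression matrix columns")

  all_idx_cols <- colnames(im)
  spec_cols <- lapply(specs, function(s) {
    idx <- s$indices
    if (length(idx) == 1L && is.na(idx)) idx <- all_idx_cols
    missing_idx <- setdiff(idx, all_idx_cols)
    if (length(missing_idx))
      stop("model requires unavailable index column(s): ",
           paste(missing_idx, collapse = ", "))
    missing_cov <- setdiff(s$covariates, names(covars))
    if (length(missing_cov))
      stop("model requires unavailable covariate column(s): ",
           paste(missing_cov, collapse = ", "))
    list(covariates = s$covariates, indices = idx)
  })

  used_cov <- unique(c("diagnosis", unlist(lapply(spec_cols, `[[`, "covariates"))))
  dat <- cbind(covars[used_cov], as.data.frame(im))
  complete <- stats::complete.cases(dat)
  if (sum(complete) < 3L) stop("fewer than 3 complete samples")
  if (any(!complete))
    message("dropping ", sum(!complete),
            " sample(s) with incomplete covariates (listwise, shared across models)")
  dat <- dat[complete, , drop = FALSE]
  Y <- t(x[, complete, drop = FALSE])  # samples x genes
  term <- paste0("diagnosis", contrast)

  out <- lapply(names(spec_cols), function(mid) {
    sc <- spec_cols[[mid]]
    rhs <- paste(c("diagnosis", sc$covariates,
                   sprintf("`%s`", sc$indices)), collapse = " + ")
    X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = dat)
    fit <- .ols_multi(X, Y)
    if (!term %in% rownames(fit$coef))
      stop("contrast term '", term, "' absent from the design")
    data.frame(gene = colnames(Y), model = mid,
               beta = fit$coef[term, ], se = fit$se[term, ],
               t = fit$t[term, ], p = fit$p[term, ],
               q = bh_adjust(fit$p[term, ]),
               aic = fit$aic, bic = fit$bic,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  attr(res, "n") <- nrow(dat)
  attr(res, "contrast") <- contrast
  class(res) <- c("de_result", "data.frame")
  res
}

#' Summarize model fit across genes
#'
#' Mean and median AIC/BIC per model over all genes (or a subset).
#' With `center = TRUE`, each gene's criteria are centered on that gene's
#' across-model mean before aggregation, so genes with very different
#' baseline variances contribute comparably (centered values of a gene sum
#' to zero across models by construction).
#'
#' @param res A `de_result`.
#' @param center Center per gene across models first (default `FALSE`).
#' @param genes Optional character vector restricting the summary.
#' @return Data frame with columns `model`, `n_genes`, `mean_aic`,
#'   `median_aic`, `mean_bic`, `median_bic`.
#' @export
model_fit_summary <- function(res, center = FALSE, genes = NULL) {
  stopifnot(inherits(res, "de_result"))
  d <- as.data.frame(res)
  if (!is.null(genes)) {
    d <- d[d$gene %in% genes, , drop = FALSE]
    if (nrow(d) == 0L) stop("no requested gene present in the results")
  }
  models <- unique(d$model)
  fitted_everywhere <- Reduce(intersect, split(d$gene, d$model))
  if (length(fitted_everywhere) == 0L)
    stop("no gene fitted under every model")
  d <- d[d$gene %in% fitted_everywhere, , drop = FALSE]
  if (center) {
    for (crit in c("aic", "bic")) {
      gm <- tapply(d[[crit]], d$gene, mean)
      d[[crit]] <- d[[crit]] - gm[d$gene]
    }
  }
  rows <- lapply(models, function(m) {
    g <- d[d$model == m, ]
    data.frame(model = m, n_genes = nrow(g),
               mean_aic = mean(g$aic), median_aic = stats::median(g$aic),
               mean_bic = mean(g$bic), median_bic = stats::median(g$bic),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replication of previously documented effects, per model
#'
#' Compares each model's diagnosis effects against a reference list of
#' previously documented effects (gene + expected direction). Reports, per
#' model, the fraction of reference genes whose fitted effect replicates
#' the documented direction, and the fraction that replicates the
#' direction at nominal p < 0.05 (the detection criterion). Reference
#' genes absent from the fitted results are excluded from the denominator
#' (count reported via `message()`).
#'
#' @param res A `de_result`.
#' @param ref Data frame with columns `gene` and `direction` (`"+"` or
#'   `"-"`); extra columns (e.g. `source_class`, `disorder`) are ignored
#'   here and may be used to subset beforehand.
#' @return Data frame with columns `model`, `n_ref`, `n_used`,
#'   `frac_direction`, `frac_detected`.
#' @export
replication_rates <- function(res, ref) {
  stopifnot(inherits(res, "de_result"))
  if (!all(c("gene", "direction") %in% names(ref)))
    stop("reference list needs columns 'gene' and 'direction'")
  if (!all(ref$direction %in% c("+", "-")))
    stop("direction must be '+' or '-'")
  ref <- ref[!duplicated(ref$gene), , drop = FALSE]
  d <- as.data.frame(res)
  present <- ref$gene %in% unique(d$gene)
  if (!any(present))
    stop("no reference gene overlaps the fitted results")
  if (any(!present))
    message(sum(!present), " reference gene(s) absent from the dataset, ",
            "excluded from the denominator")
  ref <- ref[present, , drop = FALSE]
  want <- ifelse(ref$direction == "+", 1, -1)
  names(want) <- ref$gene

  rows <- lapply(unique(d$model), function(m) {
    g <- d[d$model == m & d$gene %in% ref$gene, ]
    g <- g[match(ref$gene, g$gene), ]
    dir_ok <- sign(g$beta) == want[g$gene]
    data.frame(model = m, n_ref = nrow(ref), n_used = nrow(g),
               frac_direction = mean(dir_ok),
               frac_detected = mean(dir_ok & g$p < 0.05),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with the probability-mass definition of
#' two-sidedness (sum over tables at most as probable as the observed one)
#' and the conditional maximum-likelihood odds ratio, as computed by
#' [stats::fisher.test()].
#'
#' @param tab 2x2 matrix of non-negative integer counts with at least one
#'   nonzero margin.
#' @return List with `p` (two-sided) and `odds_ratio`.
#' @export
fisher_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2")
  if (any(!is.finite(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (sum(tab) == 0) stop("all counts are zero")
  ht <- stats::fisher.test(tab, alternative = "two.sided")
  list(p = unname(ht$p.value), odds_ratio = unname(ht$estimate))
}

#' Enrichment of significant effects in a gene set vs. the background
#'
#' Builds the 2x2 table (in-set vs. background) x (significant vs. not)
#' and delegates to [fisher_2x2()]. The background excludes the set.
#'
#' @param hits_in_set Significant genes inside the set.
#' @param set_size Genes in the set.
#' @param hits_in_background Significant genes outside the set.
#' @param background_size Genes outside the set.
#' @return As [fisher_2x2()], plus the constructed `table`.
#' @export
enrichment_vs_background <- function(hits_in_set, set_size,
                                     hits_in_background, background_size) {
  vals <- c(hits_in_set, set_size, hits_in_background, background_size)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals)))
    stop("all arguments must be non-negative integers")
  if (hits_in_set > set_size || hits_in_background > background_size)
    stop("inconsistent totals: hits exceed the corresponding set size")
  tab <- matrix(c(hits_in_set, set_size - hits_in_set,
                  hits_in_background, background_size - hits_in_background),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("in_set", "background"),
                                c("significant", "not_significant")))
  c(fisher_2x2(tab), list(table = tab))
}
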