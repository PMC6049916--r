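# Core index machinery: z-score rows, collapse transcripts to genes,
# average over marker sets, consolidate into primary-category indices.
# All standard deviations use the n-1 (sample) denominator so results agree
# with scale() and with the closed-form test oracles.

.as_expr_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric matrix (rows = transcripts, columns = samples)")
  if (is.null(rownames(x))) stop("expression matrix must have row names (transcript/probe ids)")
  if (anyDuplicated(rownames(x))) stop("expression matrix row ids must be unique")
  if (ncol(x) < 2L) stop("need at least 2 samples to center and scale across samples")
  x
}

.apply_missing_policy <- function(x, missing = c("drop", "impute")) {
  missing <- match.arg(missing)
  bad <- !is.finite(x)
  if (!any(bad)) return(x)
  if (missing == "drop") {
    drop_rows <- rowSums(bad) > 0L
    message("dropping ", sum(drop_rows), " row(s) with missing/non-finite values")
    x <- x[!drop_rows, , drop = FALSE]
    if (nrow(x) == 0L) stop("all rows removed by the missing-value policy")
  } else {
    rm <- rowMeans(ifelse(bad, NA_real_, x), na.rm = TRUE)
    if (any(!is.finite(rm)))
      stop("cannot mean-impute rows that are entirely missing")
    idx <- which(bad, arr.ind = TRUE)
    x[idx] <- rm[idx[, 1L]]
    message("mean-imputed ", nrow(idx), " missing value(s) in ",
            length(unique(idx[, 1L])), " row(s)")
  }
  x
}

#' Center and scale expression rows across samples
#'
#' Each transcript row is transformed to mean 0 and sample standard
#' deviation 1 (n-1 denominator) across samples, so that highly variable
#' transcripts cannot dominate downstream averages. Zero-variance rows are
#' undefined under this transform and are removed (count reported via
#' `message()` and in the `"dropped"` attribute).
#'
#' @param x Numeric matrix, rows = transcripts/probes, columns = samples
#'   (>= 2), with unique row names. Values are assumed log2-scale,
#'   normalized expression.
#' @return The z-scored matrix, with attribute `dropped` (character vector
#'   of removed zero-variance row ids).
#' @export
zscore_rows <- function(x) {
  x <- .as_expr_matrix(x)
  mu <- rowMeans(x)
  sd <- apply(x, 1L, stats::sd)
  zero <- sd == 0 | !is.finite(sd)
  if (all(zero)) stop("all rows have zero variance; nothing to score")
  if (any(zero))
    message("dropping ", sum(zero), " zero-variance row(s)")
  z <- (x[!zero, , drop = FALSE] - mu[!zero]) / sd[!zero]
  attr(z, "dropped") <- rownames(x)[zero]
  z
}

#' Collapse a z-scored transcript matrix to gene level
#'
#' Rows representing the same gene symbol are averaged per sample and the
#' resulting gene rows are re-scaled to mean 0, sd 1 (the average of unit-sd
#' rows generally has sd < 1, so a second standardization restores the
#' z-unit scale). Genes whose averaged row has zero variance are dropped and
#' reported. Matching of symbols is case-insensitive (symbols uppercased).
#'
#' @param z A z-scored matrix as produced by [zscore_rows()].
#' @param gene_map Named character vector mapping row ids of `z` to gene
#'   symbols. Rows without a (non-empty, non-NA) mapping are dropped with a
#'   message.
#' @return Gene-level z-scored matrix (rows = gene symbols), with attribute
#'   `dropped` (gene symbols removed for zero variance).
#' @export
collapse_to_genes <- function(z, gene_map) {
  if (is.null(names(gene_map)))
    stop("gene_map must be a named character vector (row id -> gene symbol)")
  sym <- toupper(trimws(as.character(gene_map[rownames(z)])))
  ok <- !is.na(sym) & nzchar(sym)
  if (!any(ok)) stop("no row of the matrix has a gene annotation")
  if (any(!ok))
    message("dropping ", sum(!ok), " row(s) without gene annotation")
  z <- z[ok, , drop = FALSE]
  sym <- sym[ok]

  g <- rowsum(z, group = sym, reorder = TRUE)
  n <- as.vector(table(sym)[rownames(g)])
  g <- g / n

  mu <- rowMeans(g)
  sd <- apply(g, 1L, stats::sd)
  zero <- sd == 0 | !is.finite(sd)
  if (all(zero)) stop("all collapsed gene rows have zero variance")
  if (any(zero))
    message("dropping ", sum(zero), " zero-variance gene row(s) after collapse")
  out <- (g[!zero, , drop = FALSE] - mu[!zero]) / sd[!zero]
  attr(out, "dropped") <- rownames(g)[zero]
  out
}

#' Publication-specific cell-type indices
#'
#' For each publication's signature set, the index of a sample is the mean
#' z-value over the set's genes present in the gene-level matrix. Sets
#' matching fewer than `min_genes` genes are omitted with a warning
#' (a floor of one matched gene is always enforced).
#'
#' @param gm Gene-level z-scored matrix ([collapse_to_genes()]).
#' @param sets Named list of gene-symbol vectors ([signature_sets()]).
#' @param min_genes Minimum matched genes per set (default 3; singleton
#'   "indices" are just one gene's z-score, so small counts warrant
#'   skepticism).
#' @return List with `indices` (samples x tags matrix, tags alphabetical)
#'   and `coverage` (named integer vector of matched gene counts, including
#'   omitted tags).
#' @export
publication_indices <- function(gm, sets, min_genes = 3L) {
  if (!is.list(sets) || length(sets) == 0L || is.null(names(sets)))
    stop("sets must be a non-empty named list")
  min_genes <- max(1L, as.integer(min_genes))
  genes <- rownames(gm)
  matched <- lapply(sets, function(s) intersect(toupper(s), genes))
  coverage <- lengths(matched)
  keep <- coverage >= min_genes
  if (!any(coverage > 0L))
    stop("no signature set matches any gene in the matrix")
  if (any(!keep))
    warning("omitting ", sum(!keep), " set(s) matching fewer than ",
            min_genes, " gene(s): ",
            paste(names(sets)[!keep], collapse = ", "))
  if (!any(keep))
    stop("every signature set matches fewer than min_genes genes")
  tags <- sort(names(sets)[keep])
  idx <- vapply(tags, function(tag) {
    colMeans(gm[matched[[tag]], , drop = FALSE])
  }, numeric(ncol(gm)))
  idx <- matrix(idx, nrow = ncol(gm), dimnames = list(colnames(gm), tags))
  list(indices = idx, coverage = coverage)
}

#' Consolidated primary-category indices
#'
#' Recomputes publication indices on signature sets with cross-category
#' genes removed (genes claimed by 2+ primary categories; see
#' [cross_category_genes()]) and averages the publication index columns
#' within each primary category. Categories left without any surviving set
#' are absent from the result, with a warning.
#'
#' @param gm Gene-level z-scored matrix.
#' @param db A `marker_db`.
#' @param exclude Publication tags to exclude up front.
#' @param min_genes Passed to [publication_indices()].
#' @param remove_overlaps If `TRUE` (default) drop cross-category genes from
#'   the sets before averaging; `FALSE` reproduces the naive
#'   overlap-retaining variant for comparison.
#' @return Samples x categories matrix, columns in [CELL_TYPE_CATEGORIES]
#'   order.
#' @export
consolidate_indices <- function(gm, db, exclude = character(), min_genes = 3L,
                                remove_overlaps = TRUE) {
  sets <- signature_sets(db, exclude = exclude)
  if (remove_overlaps) {
    overlap <- cross_category_genes(db)
    sets <- lapply(sets, setdiff, y = overlap)
    empty <- lengths(sets) == 0L
    if (any(empty)) {
      warning("overlap removal empties set(s): ",
              paste(names(sets)[empty], collapse = ", "))
      sets <- sets[!empty]
    }
    if (length(sets) == 0L)
      stop("overlap removal empties every signature set")
  }
  pub <- publication_indices(gm, sets, min_genes = min_genes)
  tags <- colnames(pub$indices)
  cat_of <- db$category_of[tags]
  cats <- intersect(CELL_TYPE_CATEGORIES, unique(cat_of))
  missing_cats <- setdiff(unique(db$category_of), cats)
  if (length(missing_cats))
    warning("no surviving signature set for category(ies): ",
            paste(missing_cats, collapse = ", "))
  out <- vapply(cats, function(cat) {
    rowMeans(pub$indices[, tags[cat_of == cat], drop = FALSE])
  }, numeric(nrow(pub$indices)))
  matrix(out, nrow = nrow(pub$indices),
         dimnames = list(rownames(pub$indices), cats))
}

#' Predict relative cell-type balance from bulk brain expression
#'
#' End-to-end cell-type index computation: expression rows are z-scored
#' across samples ([zscore_rows()]), collapsed from transcripts to genes and
#' re-scaled ([collapse_to_genes()]), averaged over each reference
#' publication's marker set ([publication_indices()]), and consolidated into
#' primary cell-type categories after cross-category gene removal
#' ([consolidate_indices()]). The result is deterministic; publication
#' columns are in alphabetical tag order and consolidated columns in
#' [CELL_TYPE_CATEGORIES] order.
#'
#' Indices are relative, unitless z-scale quantities: a sample with a higher
#' Astrocyte index contains relatively more astrocyte-specific expression
#' than the other samples in the same matrix, not an absolute astrocyte
#' proportion. Each index column has mean 0 across samples and sd in (0, 1].
#'
#' @param x Numeric matrix of log2-scale normalized expression, rows =
#'   transcripts/probes with unique row names, columns = samples (>= 2). A
#'   data frame of numeric columns is accepted.
#' @param db A `marker_db` of cell-type marker assignments.
#' @param gene_map Optional named character vector mapping row ids to gene
#'   symbols; if `NULL`, row names are taken to be gene symbols already.
#' @param exclude Publication tags to exclude (e.g. a "v2" profile dropping
#'   weaker reference sets; the tag list is user-supplied).
#' @param min_genes Minimum matched genes per publication set (default 3).
#' @param missing Missing-value policy before scoring: `"drop"` rows with
#'   any non-finite value (default) or `"impute"` per-row means.
#' @param keep_overlaps If `TRUE`, consolidation retains cross-category
#'   genes (naive variant; default `FALSE`).
#' @return Object of class `celltype_indices`: list with `publication`
#'   (samples x tags index matrix), `consolidated` (samples x categories),
#'   `coverage` (matched gene count per tag), `n_transcripts`, `n_genes`,
#'   and `dropped` (ids removed as zero-variance or unannotated).
#' @examples
#' profs <- make_profiles(n_genes = 60, markers_per_type = 4, fold = 8,
#'                        n_types = 5, seed = 1)
#' db <- make_synthetic_db(profs, pubs_per_type = 2, seed = 1)
#' mix <- simulate_mixture(profs, one_hot_design(5), noise_sd = 0, seed = 1)
#' ix <- cell_type_indices(mix$expr, db, min_genes = 2)
#' ix
#' @export
cell_type_indices <- function(x, db, gene_map = NULL, exclude = character(),
                              min_genes = 3L,
                              missing = c("drop", "impute"),
                              keep_overlaps = FALSE) {
  stopifnot(inherits(db, "marker_db"))
  x <- .as_expr_matrix(x)
  x <- .apply_missing_policy(x, missing)
  z <- zscore_rows(x)
  if (is.null(gene_map)) {
    gene_map <- rownames(z)
    names(gene_map) <- rownames(z)
  }
  gm <- collapse_to_genes(z, gene_map)

  sets <- signature_sets(db, exclude = exclude)
  pub <- publication_indices(gm, sets, min_genes = min_genes)
  cons <- consolidate_indices(gm, db, exclude = exclude,
                              min_genes = min_genes,
                              remove_overlaps = !keep_overlaps)
  structure(
    list(publication = pub$indices,
         consolidated = cons,
         coverage = pub$coverage,
         n_transcripts = nrow(x),
         n_genes = nrow(gm),
         dropped = c(attr(z, "dropped"), attr(gm, "dropped"))),
    class = "celltype_indices")
}

#' @export
print.celltype_indices <- function(x, ...) {
  cat("Cell-type indices (z-units, relative within this dataset)\n")
  cat("  samples:              ", nrow(x$consolidated), "\n", sep = "")
  cat("  publication indices:  ", ncol(x$publication), "\n", sep = "")
  cat("  consolidated indices: ", ncol(x$consolidated), " (",
      paste(colnames(x$consolidated), collapse = ", "), ")\n", sep = "")
  cat("  transcripts used:     ", x$n_transcripts,
      " -> ", x$n_genes, " genes\n", sep = "")
  invisible(x)
}

#' @export
summary.celltype_indices <- function(object, ...) {
  cons <- object$consolidated
  out <- data.frame(
    cell_type = colnames(cons),
    mean = colMeans(cons),
    sd = apply(cons, 2L, stats::sd),
    min = apply(cons, 2L, min),
    max = apply(cons, 2L, max),
    row.names = NULL
  )
  class(out) <- c("summary.celltype_indices", "data.frame")
  out
}

#' @export
print.summary.celltype_indices <- function(x, ...) {
  cat("Consolidated cell-type index summary (z-units):\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.celltype_indices <- function(x, row.names = NULL, optional = FALSE,
                                           which = c("consolidated", "publication"),
                                           ...) {
  which <- match.arg(which)
  m <- x[[which]]
  data.frame(sample_id = rownames(m), as.data.frame(m),
             row.names = row.names, check.names = FALSE)
}

#' Plot consolidated cell-type indices
#'
#' Boxplots of the consolidated index columns across samples, a quick visual
#' check of the relative spread of each predicted cell type.
#'
#' @param x A `celltype_indices` object.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.celltype_indices <- function(x, ...) {
  op <- graphics::par(mar = c(9, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::boxplot(x$consolidated, las = 2,
                    ylab = "consolidated index (z-units)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
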