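#' The ten primary cortical cell-type categories
#'
#' Fixed, closed vocabulary of primary cell-type category labels used
#' throughout the package: six support-cell types, three neuron categories
#' (a pooled "all neurons" category plus interneurons and projection
#' neurons), and erythrocytes (RBC). The consolidation step depends on this
#' vocabulary being closed, so marker databases are validated against it at
#' load time and consolidated index columns are reported in this order.
#'
#' @format Character vector of length 10.
#' @export
CELL_TYPE_CATEGORIES <- c(
  "Astrocyte", "Endothelial", "Microglia", "Mural",
  "Neuron_All", "Neuron_Interneuron", "Neuron_Projection",
  "Oligodendrocyte", "Oligodendrocyte_Immature", "RBC"
)

#' The five most prevalent cortical cell types
#'
#' Subset of [CELL_TYPE_CATEGORIES] used by the reduced differential
#' expression models (M3/M4) to avoid multicollinearity among the full set of
#' ten indices.
#'
#' @format Character vector of length 5.
#' @export
PREVALENT_CELL_TYPES <- c(
  "Astrocyte", "Microglia", "Oligodendrocyte",
  "Neuron_Interneuron", "Neuron_Projection"
)

.required_db_cols <- c("gene_symbol", "primary_category", "publication_tag")

#' Construct a marker-gene database
#'
#' Builds a validated database of cell-type-specific marker genes from a data
#' frame with one row per (gene, category, source publication) assignment.
#' Gene symbols are uppercased, exact duplicate assignments are dropped (with
#' a message giving the count), and the derived structures used by the index
#' computation are attached: per-publication signature gene sets, the
#' category of each publication tag, and the set of genes claimed by more
#' than one primary category.
#'
#' @param entries Data frame with at least the columns `gene_symbol`,
#'   `primary_category`, `publication_tag`; optional columns `species`,
#'   `brain_region`, `platform`, `citation` are retained and any others are
#'   ignored.
#' @return An object of class `marker_db`: a list with elements `entries`
#'   (the cleaned data frame), `signature_sets` (named list, publication tag
#'   to character vector of gene symbols), `category_of` (named character,
#'   tag to primary category), and `overlap_genes` (character vector of
#'   genes assigned to 2 or more distinct primary categories).
#' @seealso [read_marker_db()], [signature_sets()], [cross_category_genes()]
#' @examples
#' db <- marker_db(data.frame(
#'   gene_symbol      = c("GFAP", "SNAP25", "GFAP"),
#'   primary_category = c("Astrocyte", "Neuron_All", "Astrocyte"),
#'   publication_tag  = c("Astrocyte_pubA", "Neuron_All_pubB", "Astrocyte_pubC")
#' ))
#' db
#' @export
marker_db <- function(entries) {
  if (!is.data.frame(entries) || nrow(entries) == 0L)
    stop("marker database is empty: need a data frame with at least one row")
  missing_cols <- setdiff(.required_db_cols, names(entries))
  if (length(missing_cols))
    stop("marker database is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  keep <- intersect(
    c(.required_db_cols, "species", "brain_region", "platform", "citation"),
    names(entries))
  entries <- entries[, keep, drop = FALSE]
  for (cl in keep) entries[[cl]] <- as.character(entries[[cl]])

  entries$gene_symbol <- toupper(trimws(entries$gene_symbol))
  entries$primary_category <- trimws(entries$primary_category)
  entries$publication_tag <- trimws(entries$publication_tag)

  if (any(!nzchar(entries$gene_symbol)))
    stop("empty gene_symbol in row(s): ",
         paste(utils::head(which(!nzchar(entries$gene_symbol)), 5), collapse = ", "))
  if (any(!nzchar(entries$publication_tag)))
    stop("empty publication_tag in row(s): ",
         paste(utils::head(which(!nzchar(entries$publication_tag)), 5), collapse = ", "))
  bad_cat <- !(entries$primary_category %in% CELL_TYPE_CATEGORIES)
  if (any(bad_cat)) {
    i <- which(bad_cat)[1L]
    stop("unknown primary_category '", entries$primary_category[i],
         "' in row ", i, "; must be one of: ",
         paste(CELL_TYPE_CATEGORIES, collapse = ", "))
  }

  key <- paste(entries$gene_symbol, entries$primary_category,
               entries$publication_tag, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message("dropping ", sum(dup), " exact duplicate marker assignment(s)")
    entries <- entries[!dup, , drop = FALSE]
  }
  rownames(entries) <- NULL

  sets <- lapply(split(entries$gene_symbol, entries$publication_tag), unique)
  sets <- sets[sort(names(sets))]

  cat_of <- vapply(split(entries$primary_category, entries$publication_tag),
                   function(x) {
                     u <- unique(x)
                     if (length(u) > 1L)
                       stop("publication tag maps to multiple categories: ",
                            paste(u, collapse = ", "))
                     u
                   }, character(1))
  cat_of <- cat_of[names(sets)]

  gc_pairs <- unique(entries[, c("gene_symbol", "primary_category")])
  tab <- table(gc_pairs$gene_symbol)
  overlap <- sort(names(tab)[tab >= 2L])

  structure(
    list(entries = entries, signature_sets = sets, category_of = cat_of,
         overlap_genes = overlap),
    class = "marker_db")
}

#' Read a marker database from a delimited file
#'
#' Loads a CSV or TSV export of a marker-gene database (one row per gene x
#' category x source-publication assignment, header in the first row) and
#' validates it with [marker_db()]. The delimiter is auto-detected from the
#' file extension (`.tsv`/`.txt` = tab, otherwise comma) and can be forced
#' with `format`.
#'
#' @param path Path to the file.
#' @param format `"auto"` (default), `"csv"`, or `"tsv"`.
#' @return A `marker_db` object. Row and unique-gene counts are reported via
#'   `message()`.
#' @export
read_marker_db <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tsv", "txt", "tab")) "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", check.names = FALSE)
  if (nrow(raw) == 0L) stop("marker database file is empty: ", path)
  db <- marker_db(raw)
  message("loaded marker database: ", nrow(db$entries), " assignments, ",
          length(unique(db$entries$gene_symbol)), " unique gene symbols, ",
          length(db$signature_sets), " signature sets")
  db
}

#' Write a marker database to a delimited file
#'
#' Inverse of [read_marker_db()]: writes the entry table so that reloading
#' reproduces the database.
#'
#' @param db A `marker_db` object.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"`, or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_marker_db <- function(db, path, format = c("auto", "csv", "tsv")) {
  stopifnot(inherits(db, "marker_db"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tsv", "txt", "tab")) "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  utils::write.table(db$entries, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.marker_db <- function(x, ...) {
  cat("Marker-gene database\n")
  cat("  assignments:    ", nrow(x$entries), "\n", sep = "")
  cat("  unique genes:   ", length(unique(x$entries$gene_symbol)), "\n", sep = "")
  cat("  signature sets: ", length(x$signature_sets), "\n", sep = "")
  cat("  categories:     ",
      length(unique(x$category_of)), " (",
      paste(sort(unique(x$category_of)), collapse = ", "), ")\n", sep = "")
  cat("  cross-category genes: ", length(x$overlap_genes), "\n", sep = "")
  invisible(x)
}

#' Publication-specific signature gene sets
#'
#' Returns the per-publication marker gene sets of a database, optionally
#' dropping named sets (e.g. a "v2" profile that excludes weaker reference
#' sets). A warning is raised if an exclusion removes every set of some
#' primary category; removing every set entirely is an error.
#'
#' @param db A `marker_db`.
#' @param exclude Character vector of publication tags to drop. Must all be
#'   known tags.
#' @return Named list of character vectors (publication tag to gene symbols).
#' @export
signature_sets <- function(db, exclude = character()) {
  stopifnot(inherits(db, "marker_db"))
  exclude <- as.character(exclude)
  unknown <- setdiff(exclude, names(db$signature_sets))
  if (length(unknown))
    stop("unknown publication tag(s) in exclude: ",
         paste(unknown, collapse = ", "))
  sets <- db$signature_sets[setdiff(names(db$signature_sets), exclude)]
  if (length(sets) == 0L)
    stop("exclusion removes every signature set")
  lost <- setdiff(unique(db$category_of),
                  unique(db$category_of[names(sets)]))
  if (length(lost))
    warning("exclusion removes all signature sets for category(ies): ",
            paste(lost, collapse = ", "))
  sets
}

#' Genes claimed by more than one primary cell-type category
#'
#' A gene counts as cross-category when it appears under at least two
#' distinct primary categories (in any publications); the same gene listed
#' under one category by several publications does not. These genes are
#' removed before building consolidated indices.
#'
#' @param db A `marker_db`.
#' @return Sorted character vector of gene symbols.
#' @export
cross_category_genes <- function(db) {
  stopifnot(inherits(db, "marker_db"))
  db$overlap_genes
}

#' Write gene sets as a .gmt file
#'
#' Writes gene sets in the tab-separated GSEA .gmt dialect: one set per line
#' as `name<TAB>description<TAB>gene1<TAB>gene2...`, newline-terminated.
#' Empty sets and names/descriptions/symbols containing tabs are rejected
#' (they would corrupt the format).
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of per-set
#'   descriptions; defaults to `"na"` (the conventional placeholder).
#' @return `path`, invisibly.
#' @seealso [read_gmt()]
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list of gene vectors")
  sizes <- lengths(sets)
  if (any(sizes == 0L))
    stop("empty gene set(s): ", paste(names(sets)[sizes == 0L], collapse = ", "))
  if (is.null(descriptions)) {
    descriptions <- rep("na", length(sets))
    names(descriptions) <- names(sets)
  }
  desc <- descriptions[names(sets)]
  desc[is.na(desc)] <- "na"
  all_fields <- c(names(sets), desc, unlist(sets, use.names = FALSE))
  if (any(grepl("\t", all_fields, fixed = TRUE)))
    stop("set names, descriptions and gene symbols must not contain tabs")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read gene sets from a .gmt file
#'
#' @param path Path to a .gmt file.
#' @return Named list of character vectors; the per-set descriptions are
#'   attached as the `"descriptions"` attribute.
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty .gmt file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("malformed .gmt: every line needs name, description and >=1 gene")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  names(desc) <- names(sets)
  attr(sets, "descriptions") <- desc
  sets
}

#' Export a marker database's signature sets as .gmt
#'
#' Convenience wrapper that writes the (optionally filtered) publication
#' signature sets, plus the ten consolidated per-category gene sets (cross-
#' category genes removed), in GSEA-compatible .gmt format.
#'
#' @param db A `marker_db`.
#' @param path Output path.
#' @param exclude Publication tags to drop (see [signature_sets()]).
#' @param consolidated If `TRUE` (default) append one set per primary
#'   category containing the union of its publication sets minus
#'   cross-category genes.
#' @return `path`, invisibly.
#' @export
write_db_gmt <- function(db, path, exclude = character(), consolidated = TRUE) {
  sets <- signature_sets(db, exclude = exclude)
  desc <- paste0("cell-type signature (", db$category_of[names(sets)], ")")
  names(desc) <- names(sets)
  if (consolidated) {
    overlap <- cross_category_genes(db)
    cats <- intersect(CELL_TYPE_CATEGORIES, unique(db$category_of[names(sets)]))
    for (cat in cats) {
      tags <- names(sets)[db$category_of[names(sets)] == cat]
      genes <- setdiff(unique(unlist(sets[tags], use.names = FALSE)), overlap)
      if (length(genes)) {
        nm <- paste0("Consolidated_", cat)
        sets[[nm]] <- genes
        desc[nm] <- paste0("consolidated category set (", cat, ")")
      }
    }
  }
  write_gmt(sets, path, descriptions = desc)
}
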