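# Deterministic structural stand-in for the curated marker-gene table.
# The gene symbols are synthetic placeholders; what is faithful is the
# documented SHAPE of the curated resource: 38 publication-specific
# signature sets drawn from 8 source studies across the 10 primary
# categories, 3383 assignment rows, 2499 unique symbols, and a 17-gene
# erythrocyte set. Use it to exercise loaders, set logic, and .gmt export
# at realistic scale; it carries no real biology.

.synth_db_plan <- list(
  Astrocyte                = list(prefix = "AST", pool = 400L, extras = c(60L, 50L, 40L, 30L)),
  Endothelial              = list(prefix = "END", pool = 280L, extras = c(45L, 35L, 25L)),
  Microglia                = list(prefix = "MIC", pool = 340L, extras = c(50L, 40L, 30L, 20L)),
  Mural                    = list(prefix = "MUR", pool = 120L, extras = 30L),
  Neuron_All               = list(prefix = "NRA", pool = 350L, extras = c(45L, 35L, 25L)),
  Neuron_Interneuron       = list(prefix = "NRI", pool = 300L, extras = c(40L, 30L, 25L, 20L)),
  Neuron_Projection        = list(prefix = "NRP", pool = 320L, extras = c(40L, 30L, 20L, 10L)),
  Oligodendrocyte          = list(prefix = "OLG", pool = 250L, extras = c(30L, 25L, 15L)),
  Oligodendrocyte_Immature = list(prefix = "OPC", pool = 122L, extras = c(15L, 12L)),
  RBC                      = list(prefix = "RBC", pool = 17L, extras = integer(0))
)

#' Synthetic full-scale reference marker database
#'
#' Deterministically generates a marker database with the same structure as
#' a full curated cortical cell-type marker resource: 10 primary categories,
#' 38 publication-specific signature sets attributed to 8 synthetic source
#' studies, 3383 assignment rows over 2499 unique gene symbols (genes
#' re-identified by several studies appear once per study), a 17-gene
#' erythrocyte (RBC) set, and 12 cross-category genes. **All gene symbols
#' are synthetic placeholders** (e.g. `AST0001`); this object validates
#' loading, set derivation, and export machinery at realistic scale and
#' must not be used for real analyses.
#'
#' The construction is fully deterministic: each category has a pool of
#' distinct symbols entirely covered by the category's largest set, smaller
#' sets are rotated subsets of the pool (reference studies re-identifying
#' parts of the same list), and 12 neuron-pool genes are additionally
#' assigned to the astrocyte category to exercise overlap removal.
#'
#' @param path Optional file path; if given, the table is also written there
#'   (CSV or TSV by extension) so file loaders can be exercised.
#' @return A `marker_db`.
#' @export
synthetic_reference_db <- function(path = NULL) {
  pubs <- paste0("Ref", LETTERS[1:8])
  rows <- vector("list", 0L)
  pub_i <- 0L
  pools <- list()

  for (cat in names(.synth_db_plan)) {
    plan <- .synth_db_plan[[cat]]
    pool <- sprintf("%s%04d", plan$prefix, seq_len(plan$pool))
    pools[[cat]] <- pool

    set_sizes <- c(plan$pool, plan$extras)
    for (j in seq_along(set_sizes)) {
      pub_i <- pub_i + 1L
      pub <- pubs[((pub_i - 1L) %% length(pubs)) + 1L]
      tag <- sprintf("%s_Set%d_%s", cat, j, pub)
      if (j == 1L) {
        genes <- pool
      } else {
        rot <- ((j * 17L) %% plan$pool)
        idx <- ((seq_len(set_sizes[j]) + rot - 1L) %% plan$pool) + 1L
        genes <- pool[idx]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_symbol = genes, primary_category = cat, publication_tag = tag,
        species = "synthetic", brain_region = "cortex",
        platform = "synthetic",
        citation = paste0("synthetic structural stand-in (", pub, ")"),
        stringsAsFactors = FALSE)
    }
  }

  # 12 neuron-pool genes also claimed by the astrocyte category
  cross <- pools[["Neuron_All"]][seq_len(12L)]
  rows[[length(rows) + 1L]] <- data.frame(
    gene_symbol = cross, primary_category = "Astrocyte",
    publication_tag = "Astrocyte_Set1_RefA",
    species = "synthetic", brain_region = "cortex", platform = "synthetic",
    citation = "synthetic cross-category entry", stringsAsFactors = FALSE)

  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt", "tab"))
      "\t" else ","
    utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  marker_db(tab)
}
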