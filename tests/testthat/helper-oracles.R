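# Independent, loop-based oracles. These deliberately share no code with
# the package internals: plain for-loops and closed forms only.

# Full naive reimplementation of the index pipeline:
# z-score rows -> average per gene + re-z-score -> per-set mean ->
# per-category mean of publication columns (overlap genes removed).
naive_cell_type_indices <- function(x, db, gene_map = NULL, min_genes = 1L,
                                    exclude = character(),
                                    keep_overlaps = FALSE) {
  if (is.null(gene_map)) {
    gene_map <- rownames(x)
    names(gene_map) <- rownames(x)
  }
  n <- ncol(x)
  # 1. row z-scores
  z <- list()
  for (r in rownames(x)) {
    v <- as.numeric(x[r, ])
    mu <- sum(v) / n
    s <- sqrt(sum((v - mu)^2) / (n - 1))
    if (s > 0) z[[r]] <- (v - mu) / s
  }
  # 2. collapse to genes and re-z-score
  genes <- unique(toupper(unname(gene_map[names(z)])))
  gmat <- list()
  for (g in genes) {
    rows <- names(z)[toupper(gene_map[names(z)]) == g]
    avg <- numeric(n)
    for (r in rows) avg <- avg + z[[r]]
    avg <- avg / length(rows)
    mu <- sum(avg) / n
    s <- sqrt(sum((avg - mu)^2) / (n - 1))
    if (s > 0) gmat[[g]] <- (avg - mu) / s
  }
  # 3. per-publication indices
  sets <- db$signature_sets[setdiff(names(db$signature_sets), exclude)]
  pub <- list()
  for (tag in names(sets)) {
    matched <- intersect(toupper(sets[[tag]]), names(gmat))
    if (length(matched) < min_genes) next
    idx <- numeric(n)
    for (g in matched) idx <- idx + gmat[[g]]
    pub[[tag]] <- idx / length(matched)
  }
  pubm <- do.call(cbind, pub[sort(names(pub))])
  # 4. consolidated: recompute on overlap-filtered sets, average columns
  ov <- if (keep_overlaps) character(0) else db$overlap_genes
  pub2 <- list()
  for (tag in names(sets)) {
    matched <- setdiff(intersect(toupper(sets[[tag]]), names(gmat)), ov)
    if (length(matched) < min_genes) next
    idx <- numeric(n)
    for (g in matched) idx <- idx + gmat[[g]]
    pub2[[tag]] <- idx / length(matched)
  }
  cons <- list()
  for (cat in CELL_TYPE_CATEGORIES) {
    tags <- names(pub2)[db$category_of[names(pub2)] == cat]
    if (length(tags) == 0L) next
    avg <- numeric(n)
    for (tag in tags) avg <- avg + pub2[[tag]]
    cons[[cat]] <- avg / length(tags)
  }
  consm <- do.call(cbind, cons)
  rownames(pubm) <- rownames(consm) <- colnames(x)
  list(publication = pubm, consolidated = consm)
}

# Benjamini-Hochberg step-up, straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, m * p[o[j]] / j)
    q[o[i]] <- min(1, vals)
  }
  q
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration.
fisher_oracle_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  N <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  prob <- function(a) choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
  obs <- prob(tab[1, 1])
  total <- 0
  for (a in lo:hi) {
    pa <- prob(a)
    if (pa <= obs * (1 + 1e-7)) total <- total + pa
  }
  min(1, total)
}

# random expression matrix with multi-probe genes, for oracle comparisons
random_probe_matrix <- function(n_genes, n_samples, probes_extra = 5L,
                                seed = 1L) {
  set.seed(seed)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  probe_gene <- c(genes, sample(genes, probes_extra, replace = TRUE))
  probes <- sprintf("p%03d", seq_along(probe_gene))
  x <- matrix(rnorm(length(probes) * n_samples, mean = 8, sd = 2),
              nrow = length(probes),
              dimnames = list(probes, sprintf("s%02d", seq_len(n_samples))))
  names(probe_gene) <- probes
  list(x = x, gene_map = probe_gene)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
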