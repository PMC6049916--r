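test_that("row z-scoring matches closed forms and drops zero-variance rows", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_message(z <- zscore_rows(m), "1 zero-variance")
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(attr(z, "dropped"), "b")

  # two-sample closed form: (b - a)/sqrt(2) with the n-1 sd
  m2 <- matrix(c(2, 7), nrow = 1, dimnames = list("r", c("s1", "s2")))
  z2 <- zscore_rows(m2)
  expect_equal(unname(z2[1, ]), c(-0.70711, 0.70711), tolerance = 1e-5)

  expect_error(zscore_rows(m[, 1, drop = FALSE]), "at least 2 samples")
  expect_error(zscore_rows(matrix(1, 2, 3,
                                  dimnames = list(c("a", "b"), NULL))),
               "zero variance")
})

test_that("gene collapse averages probes, re-scales, and drops cancelled genes", {
  z <- rbind(p1 = c(-1, 0, 1), p2 = c(-1, 0, 1), p3 = c(1, 0, -1))
  colnames(z) <- paste0("s", 1:3)

  gm <- collapse_to_genes(z[1:2, ], c(p1 = "G", p2 = "G"))
  expect_equal(unname(gm["G", ]), c(-1, 0, 1))

  expect_error(
    suppressMessages(collapse_to_genes(z[c(1, 3), ],
                                       c(p1 = "G", p3 = "G"))),
    "zero variance")

  expect_error(collapse_to_genes(z, c(q1 = "G")), "no row")
})

test_that("collapse equals the naive average-then-restandardize loop", {
  rp <- random_probe_matrix(n_genes = 2, n_samples = 6, probes_extra = 4,
                            seed = 7)
  z <- zscore_rows(rp$x)
  gm <- collapse_to_genes(z, rp$gene_map)

  for (g in rownames(gm)) {
    rows <- names(rp$gene_map)[rp$gene_map == g]
    rows <- intersect(rows, rownames(z))
    avg <- colMeans(z[rows, , drop = FALSE])
    expected <- (avg - mean(avg)) / sd(avg)
    expect_equal(unname(gm[g, ]), unname(expected), tolerance = 1e-12)
  }
})

test_that("publication indices are set means with coverage and min_genes gating", {
  gm <- rbind(G1 = c(-1, 0, 1), G2 = c(1, 0, -1))
  colnames(gm) <- paste0("s", 1:3)

  one <- publication_indices(gm, list(tagA = "G1"), min_genes = 1)
  expect_equal(unname(one$indices[, "tagA"]), c(-1, 0, 1))
  expect_equal(unname(one$coverage["tagA"]), 1L)

  sym <- publication_indices(gm, list(tagA = c("G1", "G2")), min_genes = 2)
  expect_equal(unname(sym$indices[, "tagA"]), c(0, 0, 0))

  expect_warning(
    both <- publication_indices(gm, list(big = c("G1", "G2"), small = "G1"),
                                min_genes = 2),
    "small")
  expect_equal(colnames(both$indices), "big")
  expect_equal(unname(both$coverage["small"]), 1L)

  expect_error(publication_indices(gm, list(tagA = "NOPE")), "no signature set")
})

test_that("random publication indices equal the brute-force per-sample mean", {
  set.seed(11)
  gm <- zscore_rows(matrix(rnorm(160), nrow = 20,
                           dimnames = list(sprintf("G%02d", 1:20),
                                           sprintf("s%d", 1:8))))
  sets <- list(t1 = sprintf("G%02d", 1:5), t2 = sprintf("G%02d", 4:9),
               t3 = sprintf("G%02d", c(2, 11, 17)), t4 = sprintf("G%02d", 15:20))
  res <- publication_indices(gm, sets)
  for (tag in names(sets)) {
    for (s in colnames(gm)) {
      vals <- numeric(0)
      for (g in sets[[tag]]) vals <- c(vals, gm[g, s])
      expect_equal(res$indices[s, tag], mean(vals), tolerance = 1e-12)
    }
  }
})

test_that("consolidation averages publication columns and removes cross-category genes", {
  set.seed(3)
  gm <- zscore_rows(matrix(rnorm(60), nrow = 10,
                           dimnames = list(c("X", sprintf("G%d", 1:9)),
                                           sprintf("s%d", 1:6))))
  # gene X claimed by both astrocyte (pubA) and neuron (pubB)
  db <- marker_db(data.frame(
    gene_symbol = c("X", "G1", "G2", "X", "G3", "G4", "G5", "G6"),
    primary_category = c(rep("Astrocyte", 3), rep("Neuron_All", 5)),
    publication_tag = c(rep("pubA", 3), rep("pubB", 5))))

  cons <- consolidate_indices(gm, db, min_genes = 1)
  # with a single publication per category the consolidated column equals
  # the publication index computed on the overlap-filtered set
  expect_equal(unname(cons[, "Astrocyte"]),
               unname(colMeans(gm[c("G1", "G2"), ])), tolerance = 1e-12)
  # and differs from the naive overlap-retaining variant
  keep <- consolidate_indices(gm, db, min_genes = 1, remove_overlaps = FALSE)
  expect_equal(unname(keep[, "Astrocyte"]),
               unname(colMeans(gm[c("X", "G1", "G2"), ])), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cons[, "Astrocyte"], keep[, "Astrocyte"])))

  # category with a single publication set: consolidated == publication
  pub <- publication_indices(gm, list(pubB = setdiff(db$signature_sets$pubB, "X")),
                             min_genes = 1)
  expect_equal(unname(cons[, "Neuron_All"]),
               unname(pub$indices[, "pubB"]), tolerance = 1e-12)

  # two opposite publication columns average to zero
  gm2 <- rbind(A = c(0.5, -0.5), B = c(-0.5, 0.5))
  expect_equal(unname((gm2["A", ] + gm2["B", ]) / 2), c(0, 0))
})

test_that("end-to-end indices match the naive loop oracle including collapse", {
  profs <- make_profiles(n_genes = 30, markers_per_type = 3, fold = 8,
                         n_types = 5, seed = 21)
  db <- make_synthetic_db(profs, pubs_per_type = 2, overlap_genes = 2,
                          seed = 21)
  rp <- random_probe_matrix(n_genes = 30, n_samples = 10, probes_extra = 6,
                            seed = 22)
  ix <- quiet(cell_type_indices(rp$x, db, gene_map = rp$gene_map,
                                min_genes = 1))
  oracle <- naive_cell_type_indices(rp$x, db, gene_map = rp$gene_map,
                                    min_genes = 1)
  expect_equal(ix$publication, oracle$publication, tolerance = 1e-10)
  expect_equal(ix$consolidated, oracle$consolidated, tolerance = 1e-10)
})

test_that("indices are invariant under positive per-gene affine maps", {
  profs <- make_profiles(n_genes = 40, markers_per_type = 4, fold = 8,
                         n_types = 4, seed = 5)
  db <- make_synthetic_db(profs, pubs_per_type = 2, seed = 5)
  set.seed(6)
  x <- matrix(rnorm(40 * 8, 8, 2), nrow = 40,
              dimnames = list(rownames(profs$profiles),
                              sprintf("s%d", 1:8)))
  ix <- quiet(cell_type_indices(x, db))

  y <- x
  y["GENE0001", ] <- y["GENE0001", ] + 7.3
  y["GENE0002", ] <- y["GENE0002", ] * 2
  set.seed(8)
  scale_all <- exp(rnorm(nrow(x), 0, 0.5))
  shift_all <- rnorm(nrow(x), 0, 3)
  y2 <- x * scale_all + shift_all
  for (other in list(y, y2)) {
    ix2 <- quiet(cell_type_indices(other, db))
    expect_equal(ix2$publication, ix$publication, tolerance = 1e-10)
    expect_equal(ix2$consolidated, ix$consolidated, tolerance = 1e-10)
  }
})

test_that("index columns are centered, bounded in spread, and deterministically ordered", {
  profs <- make_profiles(n_genes = 60, markers_per_type = 5, fold = 8,
                         n_types = 6, seed = 9)
  db <- make_synthetic_db(profs, pubs_per_type = 3, seed = 9)
  set.seed(10)
  x <- matrix(rnorm(60 * 12, 8, 2), nrow = 60,
              dimnames = list(rownames(profs$profiles),
                              sprintf("s%02d", 1:12)))
  ix <- quiet(cell_type_indices(x, db))

  all_cols <- cbind(ix$publication, ix$consolidated)
  expect_true(all(abs(colMeans(all_cols)) < 1e-8))
  sds <- apply(all_cols, 2, sd)
  expect_true(all(sds > 0 & sds <= 1 + 1e-12))

  expect_equal(colnames(ix$publication), sort(colnames(ix$publication)))
  expect_equal(colnames(ix$consolidated),
               intersect(CELL_TYPE_CATEGORIES, colnames(ix$consolidated)))
})

test_that("missing-value policies drop or impute as documented", {
  set.seed(13)
  x <- matrix(rnorm(30, 8, 2), nrow = 5,
              dimnames = list(paste0("r", 1:5), paste0("s", 1:6)))
  x[2, 3] <- NA
  expect_message(dropped <- blendr:::.apply_missing_policy(x, "drop"),
                 "dropping 1 row")
  expect_false("r2" %in% rownames(dropped))
  expect_message(imp <- blendr:::.apply_missing_policy(x, "impute"),
                 "mean-imputed 1")
  expect_equal(imp[2, 3], mean(x[2, -3]))
})
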