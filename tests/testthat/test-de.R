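make_de_fixture <- function(seed = 41, n = 120,
                            effects = list(diagnosisMDD = c(Astrocyte = -0.8))) {
  profs <- make_profiles(n_genes = 120, markers_per_type = 5, fold = 8,
                         n_types = 10, seed = seed)
  db <- make_synthetic_db(profs, pubs_per_type = 2, seed = seed)
  co <- simulate_cohort(profs, n_samples = n, effects = effects, seed = seed + 1)
  ix <- quiet(cell_type_indices(co$expr, db))
  list(profs = profs, db = db, co = co, ix = ix)
}

test_that("model specifications nest by term set", {
  sp <- de_model_specs(all_indices = CELL_TYPE_CATEGORIES)
  terms_of <- function(s) c("diagnosis", s$covariates, s$indices)
  expect_true(all(terms_of(sp$M1) %in% terms_of(sp$M2)))
  expect_true(all(terms_of(sp$M2) %in% terms_of(sp$M5)))
  expect_true(all(terms_of(sp$M3) %in% terms_of(sp$M4)))
  expect_true(all(terms_of(sp$M4) %in% terms_of(sp$M5)))
  expect_setequal(sp$M4$indices, PREVALENT_CELL_TYPES)
})

test_that("per-gene fits agree with stats::lm gene by gene", {
  fx <- make_de_fixture(n = 60)
  res <- quiet(fit_de_models(fx$co$expr, fx$co$metadata, fx$ix,
                             contrast = "SCHIZ"))
  d <- as.data.frame(res)
  dat <- cbind(fx$co$metadata, as.data.frame(fx$ix$consolidated))

  for (g in sample(unique(d$gene), 4)) {
    for (m in c("M1", "M2", "M4")) {
      sp <- de_model_specs()[[m]]
      rhs <- paste(c("diagnosis", sp$covariates,
                     sprintf("`%s`", sp$indices)), collapse = " + ")
      dat$.y <- fx$co$expr[g, ]
      ref <- lm(as.formula(paste(".y ~", rhs)), data = dat)
      row <- d[d$gene == g & d$model == m, ]
      co <- summary(ref)$coefficients["diagnosisSCHIZ", ]
      expect_equal(row$beta, unname(co[1]), tolerance = 1e-8)
      expect_equal(row$se, unname(co[2]), tolerance = 1e-8)
      expect_equal(row$p, unname(co[4]), tolerance = 1e-8)
      expect_equal(row$aic, AIC(ref), tolerance = 1e-8)
      expect_equal(row$bic, BIC(ref), tolerance = 1e-8)
    }
  }
  expect_equal(d$q[d$model == "M2"], bh_adjust(d$p[d$model == "M2"]))
})

test_that("constant genes yield zero effect and p = 1; bad inputs error", {
  fx <- make_de_fixture(n = 40)
  expr <- fx$co$expr
  expr["GENE0001", ] <- 3.7
  res <- quiet(fit_de_models(expr, fx$co$metadata, fx$ix, contrast = "MDD"))
  flat <- as.data.frame(res)
  flat <- flat[flat$gene == "GENE0001", ]
  expect_true(all(flat$beta == 0))
  expect_true(all(flat$p == 1))

  expect_error(quiet(fit_de_models(fx$co$expr, fx$co$metadata, fx$ix,
                                   contrast = "NOPE")),
               "contrast level")
  meta2 <- fx$co$metadata
  names(meta2)[names(meta2) == "diagnosis"] <- "dx"
  expect_error(quiet(fit_de_models(fx$co$expr, meta2, fx$ix,
                                   contrast = "MDD")),
               "diagnosis")
})

test_that("composition-driven diagnosis effects attenuate once indices enter the model", {
  fx <- make_de_fixture(seed = 43, n = 150,
                        effects = list(diagnosisMDD = c(Astrocyte = -1)))
  res <- quiet(fit_de_models(fx$co$expr, fx$co$metadata, fx$ix,
                             contrast = "MDD"))
  d <- as.data.frame(res)
  astro_markers <- names(fx$profs$marker_map)[
    fx$profs$marker_map == "Astrocyte"]
  b2 <- d$beta[d$model == "M2" & d$gene %in% astro_markers]
  b4 <- d$beta[d$model == "M4" & d$gene %in% astro_markers]
  expect_lt(mean(abs(b4)), mean(abs(b2)))
})

test_that("model-fit summaries respect centering and duplicate models", {
  fx <- make_de_fixture(n = 60)
  res <- quiet(fit_de_models(fx$co$expr, fx$co$metadata, fx$ix,
                             contrast = "MDD"))
  s <- model_fit_summary(res)
  expect_setequal(s$model, c("M1", "M2", "M3", "M4", "M5"))

  cs <- model_fit_summary(res, center = TRUE)
  # per-gene centered criteria average to zero across models
  expect_equal(sum(cs$mean_bic), 0, tolerance = 1e-8)
  expect_equal(sum(cs$mean_aic), 0, tolerance = 1e-8)

  dup <- as.data.frame(res)
  dup2 <- dup[dup$model %in% c("M1", "M2"), ]
  dup2$model[dup2$model == "M2"] <- "M1copy"
  dup2$aic[dup2$model == "M1copy"] <- dup2$aic[dup2$model == "M1"]
  dup2$bic[dup2$model == "M1copy"] <- dup2$bic[dup2$model == "M1"]
  class(dup2) <- class(res)
  s2 <- model_fit_summary(dup2)
  expect_equal(s2$mean_bic[1], s2$mean_bic[2])

  expect_error(model_fit_summary(res, genes = "NOT_A_GENE"), "no requested")
})

test_that("replication rates hit 1 on perfectly matching references and error on no overlap", {
  fx <- make_de_fixture(seed = 47, n = 200,
                        effects = list(diagnosisSCHIZ = c(
                          Oligodendrocyte = -1.5)))
  res <- quiet(fit_de_models(fx$co$expr, fx$co$metadata, fx$ix,
                             contrast = "SCHIZ"))
  d <- as.data.frame(res)
  m2 <- d[d$model == "M2", ]
  strong <- m2[m2$p < 1e-4, ]
  skip_if(nrow(strong) < 3)  # effect this large always yields hits
  ref <- data.frame(gene = strong$gene,
                    direction = ifelse(strong$beta > 0, "+", "-"))
  rr <- replication_rates(res, ref)
  m2row <- rr[rr$model == "M2", ]
  expect_equal(m2row$frac_direction, 1)
  expect_equal(m2row$frac_detected, 1)

  expect_error(replication_rates(res, data.frame(gene = "ZZZ",
                                                 direction = "+")),
               "no reference gene")
  expect_message(
    replication_rates(res, rbind(ref, data.frame(gene = "ZZZ",
                                                 direction = "+"))),
    "absent from the dataset")
})

test_that("direction replication is at chance for randomized reference directions", {
  fx <- make_de_fixture(seed = 53, n = 100, effects = list())
  res <- quiet(fit_de_models(fx$co$expr, fx$co$metadata, fx$ix,
                             contrast = "SCHIZ"))
  set.seed(54)
  genes <- unique(as.data.frame(res)$gene)
  ref <- data.frame(gene = genes,
                    direction = sample(c("+", "-"), length(genes),
                                       replace = TRUE))
  rr <- replication_rates(res, ref)
  expect_true(all(abs(rr$frac_direction - 0.5) < 0.2))
})

test_that("Fisher's exact test equals the enumeration oracle on the worked tables", {
  t1 <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher_2x2(t1)$p, 0.48571, tolerance = 1e-5)
  expect_equal(fisher_2x2(t1)$p, fisher_oracle_p(t1), tolerance = 1e-10)

  t2 <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  expect_equal(fisher_2x2(t2)$p, 2 / choose(20, 10), tolerance = 1e-10)

  t3 <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(fisher_2x2(t3)$p, 1)

  expect_error(fisher_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisher_2x2(matrix(0, 2, 2)), "zero")
})

test_that("enrichment builds the right 2x2 and is label-transposition invariant", {
  sym <- enrichment_vs_background(5, 10, 50, 100)
  expect_equal(sym$p, 1)

  e <- enrichment_vs_background(8, 10, 5, 90)
  expect_equal(e$p, fisher_2x2(e$table)$p)
  expect_equal(fisher_2x2(t(e$table))$p, e$p, tolerance = 1e-12)

  expect_error(enrichment_vs_background(11, 10, 5, 90), "inconsistent")

  # all in-set hits, no background hits: closed-form hypergeometric tail
  all_in <- enrichment_vs_background(4, 4, 0, 16)
  expect_equal(all_in$p, 1 / choose(20, 4), tolerance = 1e-12)
})
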