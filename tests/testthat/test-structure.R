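test_that(".rsa files round-trip through the fixed-record parser", {
  df <- data.frame(position = c(12L, 13L, 14L), residue = c("S", "A", "Y"),
                   rsa_all_atom = c(45.67, 3.21, 101.5),
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".rsa")
  writeRSAFile(df, path)
  back <- readRSAFile(path, model_id = "m1")
  expect_equal(back$position, df$position)
  expect_equal(back$residue, df$residue)
  expect_equal(back$rsa_all_atom, df$rsa_all_atom, tolerance = 0.01)

  # malformed RES lines are collected, not fatal
  writeLines(c(readLines(path), "RES SER A  xx  bad line"), path)
  back2 <- readRSAFile(path)
  expect_equal(nrow(back2), 3)
  expect_length(attr(back2, "rejects"), 1)

  writeLines("REM nothing here", path)
  expect_error(readRSAFile(path), "RES")
})

test_that("model acceptance needs 25% identity plus one quality criterion", {
  meta <- data.frame(
    template_identity = c(30, 20, 30, 30, 24.9),
    no35 = c(NA, 80, 39, 45, 80),
    ga341 = c(NA, 0.9, 0.6, NA, 0.9),
    evalue = c(NA, 1e-6, 1e-3, NA, 1e-6),
    zdope = c(-0.5, -1, 0.2, NA, -1))
  expect_equal(acceptModel(meta), c(TRUE, FALSE, FALSE, TRUE, FALSE))

  # monotone: improving any single criterion never revokes acceptance
  set.seed(61)
  for (i in 1:50) {
    m <- data.frame(template_identity = runif(1, 0, 60),
                    no35 = runif(1, 0, 90), ga341 = runif(1, 0, 1),
                    evalue = 10^runif(1, -8, 0), zdope = runif(1, -3, 3))
    before <- acceptModel(m)
    better <- m
    j <- sample(5, 1)
    better[[j]] <- switch(j, better[[1]] + 10, better[[2]] + 10,
                          better[[3]] + 0.2, better[[4]] / 100,
                          better[[5]] - 1)
    expect_true(!before || acceptModel(better))
  }
})

test_that("largest-model selection breaks ties by zDOPE then id", {
  meta <- data.frame(model_id = c("mB", "mA", "mC"),
                     coverage_start = c(1L, 1L, 41L),
                     coverage_end = c(120L, 80L, 160L),
                     zdope = c(-0.3, -1.2, -1.2),
                     stringsAsFactors = FALSE)
  expect_equal(selectLargestModel(meta)$model_id, "mC")   # covers 120 residues
  tie <- meta[c(1, 3), ]
  tie$coverage_start <- 1L; tie$coverage_end <- 120L      # equal size
  expect_equal(selectLargestModel(tie)$model_id, "mC")    # zdope -1.2 beats -0.3
  tie$zdope <- c(-1, -1)
  expect_equal(selectLargestModel(tie)$model_id, "mB")    # then lexicographic
  expect_equal(selectLargestModel(meta[2, ])$model_id, "mA")
  expect_error(selectLargestModel(meta[0, ]), "no model")
})

test_that("low-accessibility classification is strictly below threshold", {
  expect_true(classifyLowAccessibility(19.9))
  expect_false(classifyLowAccessibility(20.0))
  expect_true(classifyLowAccessibility(0))
  expect_equal(classifyLowAccessibility(c(5, 20, 35)),
               c(TRUE, FALSE, FALSE))
})

test_that("per-site accessibility uses the largest accepted covering model", {
  meta <- data.frame(model_id = c("m1", "m2", "m_rej"),
                     protein_id = "P1",
                     template_identity = c(40, 40, 10),
                     coverage_start = c(1L, 5L, 1L),
                     coverage_end = c(50L, 100L, 200L),
                     no35 = 60, ga341 = NA, evalue = NA, zdope = NA,
                     stringsAsFactors = FALSE)
  rsa <- data.frame(model_id = c("m1", "m2", "m_rej"), protein_id = "P1",
                    position = 10L, residue = "S",
                    rsa_all_atom = c(25, 12, 80), stringsAsFactors = FALSE)
  sites <- data.frame(protein_id = "P1", position = 10L)
  acc <- siteAccessibility(sites, rsa, meta)
  expect_equal(acc$selected_model, "m2")  # m_rej fails acceptance
  expect_equal(acc$rsa, 12)
  expect_true(acc$low_accessibility)
  expect_equal(acc$n_models, 2L)
})

test_that("flexibility deltas are symmetric, non-negative and match a brute force", {
  rsa <- data.frame(
    model_id = rep(c("m1", "m2"), each = 4),
    protein_id = "P1",
    position = rep(c(3L, 7L, 11L, 15L), 2),
    residue = rep(c("S", "T", "Y", "A"), 2),
    rsa_all_atom = c(30, 50, 10, 5, 41.55, 48, 22, 9),
    stringsAsFactors = FALSE)
  meta <- data.frame(model_id = c("m1", "m2"), protein_id = "P1",
                     template_identity = 50, no35 = 60,
                     coverage_start = 1L, coverage_end = 20L,
                     stringsAsFactors = FALSE)
  flex <- flexibilityAnalysis(rsa, meta)
  # the non-acceptor residue is excluded; |delta| per shared S/T/Y residue
  expect_equal(sort(flex$pairs$delta), sort(c(11.55, 2, 12)))
  expect_true(all(flex$pairs$delta >= 0))
  expect_equal(flex$correlation,
               cor(c(30, 50, 10), c(41.55, 48, 22)))
  expect_equal(unname(flex$medians["acceptor"]), 11.55)

  # identical models: all deltas zero, correlation 1
  rsa0 <- rsa; rsa0$rsa_all_atom <- rep(c(30, 50, 10, 5), 2)
  flex0 <- flexibilityAnalysis(rsa0, meta)
  expect_true(all(flex0$pairs$delta == 0))
  expect_equal(flex0$correlation, 1)

  # class medians via explicit site keys
  flex2 <- flexibilityAnalysis(rsa, meta,
                               site_classes = list(phosphosite = "P1:3"))
  expect_equal(unname(flex2$medians["phosphosite"]), 11.55)

  # per-residue max summary behind the flag
  flex3 <- flexibilityAnalysis(rsa, meta, summary = "max")
  expect_equal(sort(flex3$deltas$acceptor), sort(c(11.55, 2, 12)))

  expect_error(flexibilityAnalysis(rsa[rsa$model_id == "m1", ], meta),
               "2 accepted models")
})

test_that("two-sample KS statistic follows the ECDF supremum", {
  expect_equal(ksTwoSample(1:10, 1:10)$D, 0)
  expect_equal(ksTwoSample(c(1, 2), c(3, 4))$D, 1)
  expect_equal(ksTwoSample(c(1, 3), c(2, 4))$D, 0.5)
  expect_error(ksTwoSample(numeric(), 1:3), "non-empty")
})

test_that("phosphosite class shows larger accessibility variability in most seeded runs", {
  cfg <- cohortConfig(n_proteins = 25, n_species = 1, seed = 1)
  coh <- generateCohort(cfg)
  wins <- 0L
  for (s in 1:20) {
    cfg_s <- cfg; cfg_s$seed <- 100 + s
    fx <- generateRSAFixtures(cfg_s, coh)
    flex <- flexibilityAnalysis(
      fx$rsa, fx$meta,
      site_classes = list(phosphosite = fx$flexible_residues))
    keyed <- skey(flex$pairs$protein_id, flex$pairs$position)
    background <- flex$pairs$delta[!keyed %in% fx$flexible_residues]
    if (median(flex$deltas$phosphosite) > median(background)) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})
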