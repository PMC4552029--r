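test_that("window extraction pads sequence overhang with dashes", {
  expect_equal(extractWindow("MKSPLR", 3, 2), "MKSPL")
  expect_equal(extractWindow("SKAPLR", 1, 2), "--SKA")
  expect_equal(extractWindow("MKAPLS", 6, 2), "PLS--")
  expect_error(extractWindow("MKSPLR", 6, 2), "acceptor")
  expect_error(extractWindow("MKSPLR", 9, 2), "range")
})

test_that("PSSM frequencies follow the pseudocount formula", {
  # single peptide, no pseudocount: indicator columns, I = ln 20 everywhere
  m <- buildPSSM("k", "ARSKW", pseudocount_weight = 0)
  expect_equal(unname(m@info), rep(log(20), 4), tolerance = 1e-12)
  expect_equal(m@freq["A", "-2"], 1)
  expect_equal(colSums(m@freq), setNames(rep(1, 4), colnames(m@freq)))

  # two peptides agreeing at a position, beta = 1
  m2 <- buildPSSM("k", c("RASKA", "RTSKW"), pseudocount_weight = 1)
  expect_equal(m2@freq["R", "-2"], (2 + 1 / 20) / 3)
  expect_equal(m2@freq["K", "1"], (2 + 1 / 20) / 3)
  # positive everywhere under beta > 0
  expect_true(all(m2@freq > 0))

  # pads are not counted as observations
  m3 <- buildPSSM("k", c("--SKA", "--SKW"), pseudocount_weight = 1)
  expect_equal(m3@freq["A", "-2"], (0 + 1 / 20) / 1)  # N_i = 0, beta = 1
})

test_that("MSS reproduces the hand-computed toy value and its analytic bounds", {
  freq <- matrix(c(0.7, 0.3, 0, 0.5, 0, 0.5), nrow = 3,
                 dimnames = list(c("A", "R", "K"), c("-1", "1")))
  m <- kinasePSSM("toy", freq)
  expect_equal(m@info[["-1"]], 0.7 * log(14) + 0.3 * log(6), tolerance = 1e-12)
  expect_equal(m@info[["1"]], log(10), tolerance = 1e-12)
  expect_equal(mssScore(m, "RSK"), 0.662, tolerance = 1e-3)

  expect_equal(mssScore(m, "ASK"), 1)  # consensus attains the max bound
  # anti-consensus (zero-frequency residues) attains the min bound
  expect_equal(mssScore(m, "KSR"), 0)

  # invariant under positive rescaling of the information weights
  m_scaled <- m
  m_scaled@info <- m@info * 3.7
  m_scaled@scoreMin <- m@scoreMin * 3.7
  m_scaled@scoreMax <- m@scoreMax * 3.7
  expect_equal(mssScore(m_scaled, "RSK"), mssScore(m, "RSK"))
})

test_that("MSS stays in [0, 1] for arbitrary peptides including pads", {
  set.seed(41)
  m <- buildPSSM("k", vapply(1:25, function(i) randomWindow(3), ""))
  peps <- c(vapply(1:500, function(i) randomWindow(3), ""),
            "---S---", "XXXTXXX")
  sc <- mssScore(m, peps)
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("AROC equals brute-force pair counting, with ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)),
               0.5)
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "class")

  set.seed(42)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) next
    expect_equal(auroc(scores, labels), oracleAuroc(scores, labels))
  }
})

test_that("cross-validation detects an implanted motif and nothing in noise", {
  set.seed(43)
  motif <- c(`-3` = "R", `-2` = "R", `1` = "L", `3` = "F")
  pos <- vapply(1:100, function(i) motifWindow(7, motif), "")
  neg <- vapply(1:1000, function(i) randomWindow(7), "")
  cv <- crossValidateKinase(pos, neg, k = 10, seed = 5, kinase = "KinA")
  expect_gt(cv$median_aroc, 0.9)
  expect_true(cv$selected)
  expect_equal(cv$median_aroc, median(cv$fold_arocs))

  # shuffled labels: same windows, membership randomized
  pool <- c(pos, neg)
  set.seed(44)
  shuf <- sample(length(pool))
  cv_null <- crossValidateKinase(pool[shuf[1:100]], pool[shuf[-(1:100)]],
                                 k = 10, seed = 5)
  expect_gte(cv_null$median_aroc, 0.4)
  expect_lte(cv_null$median_aroc, 0.6)

  # identical positive and negative windows: pure ties, AROC 0.5 per fold
  same <- rep(randomWindow(7), 12)
  cv_tie <- crossValidateKinase(same, same, k = 4, seed = 5)
  expect_equal(unname(cv_tie$fold_arocs), rep(0.5, 4))

  expect_error(crossValidateKinase(pos[1], neg, seed = 1), "2 positives")
  expect_message(crossValidateKinase(pos[1:3], neg, k = 10, seed = 1),
                 "reducing folds")
})

test_that("cutoff calibration maximizes accuracy over score midpoints", {
  expect_equal(calibrateCutoff(c(0.8, 0.9), c(0.1, 0.2), seed = 1), 0.5)
  # equal sizes: no resampling, so the seed cannot matter
  expect_equal(calibrateCutoff(c(0.8, 0.9), c(0.1, 0.2), seed = 99), 0.5)
  # degenerate: all scores identical, single candidate at that value
  expect_equal(calibrateCutoff(rep(0.3, 4), rep(0.3, 6), seed = 1), 0.3)
  # smallest maximizer wins when several thresholds tie
  expect_equal(calibrateCutoff(c(0.6, 0.9), c(0.1), seed = 1), 0.35)
})

test_that("published kinase cutoffs are available as constants", {
  cuts <- defaultKinaseCutoffs()
  expect_equal(unname(cuts["Cdk1"]), 0.929)
  expect_equal(unname(cuts["Cdk2"]), 0.126)
  expect_length(cuts, 10)
})

test_that("target-site prediction recovers implanted motif sites", {
  set.seed(45)
  motif <- c(`-3` = "R", `-2` = "R", `1` = "L", `3` = "F")
  pos_train <- vapply(1:60, function(i) motifWindow(7, motif), "")
  neg_train <- vapply(1:600, function(i) randomWindow(7), "")
  m <- buildPSSM("KinA", pos_train)
  pssmCutoff(m) <- calibrateCutoff(mssScore(m, pos_train),
                                   mssScore(m, neg_train), seed = 7)

  # proteome with 5 implanted motif sites and 50 background sites
  seqs <- character(); rows <- list()
  for (i in 1:55) {
    pid <- sprintf("P%02d", i)
    s <- strsplit(randomProtein(60), "")[[1]]
    p <- 30L
    s[p] <- "S"
    if (i <= 5) for (nm in names(motif)) s[p + as.integer(nm)] <- motif[[nm]]
    seqs[pid] <- paste(s, collapse = "")
    rows[[i]] <- data.frame(protein_id = pid, position = p, residue = "S",
                            stringsAsFactors = FALSE)
  }
  ps <- PhosphoSet(do.call(rbind, rows), species = "toy")
  pred <- predictTargetSites(ps, seqs, m)
  expect_true(all(sprintf("P%02d", 1:5) %in% pred$protein_id))
  expect_lt(nrow(pred), 20)  # background passes only sporadically

  # a cutoff of 1 admits only the exact consensus
  pred_strict <- predictTargetSites(ps, seqs, m, cutoff = 1)
  expect_equal(nrow(pred_strict), 0)

  # sites on proteins without sequence are skipped, with a report
  ps_extra <- PhosphoSet(rbind(siteTable(ps)[, 1:3],
                               data.frame(protein_id = "MISSING",
                                          position = 10L, residue = "S")),
                         species = "toy")
  expect_message(pred2 <- predictTargetSites(ps_extra, seqs, m), "skipping")
  expect_equal(attr(pred2, "skipped")$protein_id, "MISSING")
})
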