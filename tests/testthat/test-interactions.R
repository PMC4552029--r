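predRow <- function(kinase, protein, pos, mss = 0.9) {
  data.frame(kinase = kinase, protein_id = protein, position = pos,
             residue = "S", peptide = NA_character_, mss = mss,
             stringsAsFactors = FALSE)
}

test_that("site predictions collapse to one interaction per kinase-protein", {
  sites <- rbind(predRow("Cdk1", "P1", 10), predRow("Cdk1", "P1", 20),
                 predRow("Cdk1", "P1", 30), predRow("Plk1", "P1", 20),
                 predRow("Cdk1", "P2", 5))
  ints <- predictInteractions(sites)
  expect_equal(nrow(ints), 3)
  cdk1_p1 <- ints[ints$kinase == "Cdk1" & ints$protein_id == "P1", ]
  expect_equal(cdk1_p1$n_sites, 3)
  expect_match(cdk1_p1$supporting_sites, "10.*20.*30")

  expect_equal(nrow(predictInteractions(predRow("x", "y", 1)[0, ])), 0)
})

test_that("interaction conservation is position-independent and needs an ortholog", {
  qseq <- paste0(strrep("A", 9), "S", strrep("A", 30))
  maps <- list(sp1 = toyMap("sp1", "P1", "o1", qseq),
               sp2 = toyMap("sp2", "P1", "o2", qseq),
               sp3 = toyMap("sp3", "OTHER", "o3", qseq))
  ints <- predictInteractions(predRow("Cdk1", "P1", 10))
  per_species <- list(
    sp1 = predictInteractions(predRow("Cdk1", "o1", 33)),  # far position
    sp2 = predictInteractions(predRow("Plk1", "o2", 10)),  # other kinase
    sp3 = predictInteractions(predRow("Cdk1", "o3", 10))   # no ortholog
  )
  out <- interactionConservation(ints, maps, per_species)
  expect_equal(out$n_cons, 1L)
  expect_equal(out$conserved_species, "sp1")
})

test_that("three-species toy: orthologs in 3, predictions in 2, degree 2", {
  qseq <- paste0("S", strrep("A", 9))
  maps <- lapply(paste0("sp", 1:3), function(sp)
    toyMap(sp, "P1", paste0(sp, "_o"), qseq))
  names(maps) <- paste0("sp", 1:3)
  ints <- predictInteractions(predRow("Cdk1", "P1", 1))
  per_species <- list(
    sp1 = predictInteractions(predRow("Cdk1", "sp1_o", 1)),
    sp2 = predictInteractions(predRow("Cdk1", "sp2_o", 5)),
    sp3 = predictInteractions(predRow("x", "y", 1)[0, ]))
  out <- interactionConservation(ints, maps, per_species)
  expect_equal(out$n_cons, 2L)
})

test_that("conservation-degree ROC uses midrank ties", {
  ints <- data.frame(n_cons = c(3L, 2L, 2L, 0L))
  roc <- rankInteractionsROC(ints, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc$aroc, 0.875)  # (1 + 1 + 0.5 + 1) / 4

  perfect <- data.frame(n_cons = c(13L, 13L, 0L, 0L))
  expect_equal(rankInteractionsROC(perfect, c(TRUE, TRUE, FALSE, FALSE))$aroc,
               1)
  expect_error(rankInteractionsROC(perfect, rep(TRUE, 4)), "class")

  # label independent of degree: AROC near one half (seeded)
  sim <- simulateInteractionCohort(400, 8, p_true = 0.5, p_background = 0.5,
                                   true_fraction = 0.5, seed = 9)
  null_roc <- rankInteractionsROC(sim, sim$label)
  expect_gte(null_roc$aroc, 0.45)
  expect_lte(null_roc$aroc, 0.55)
})

test_that("enrichment fold is the positive-fraction ratio", {
  ints <- data.frame(kinase = "K", protein_id = paste0("P", 1:10),
                     n_cons = c(rep(7L, 4), rep(0L, 6)),
                     stringsAsFactors = FALSE)
  positives <- c("P1", "P2")  # both inside the degree >= 7 subset
  expect_equal(enrichmentFold(ints, positives, 7, by = "protein"),
               (2 / 4) / (2 / 10))
  expect_equal(enrichmentFold(ints, positives, 0, by = "protein"), 1)
  expect_error(enrichmentFold(ints, character(), 0, by = "protein"),
               "undefined")
  expect_error(enrichmentFold(ints, positives, 12, by = "protein"),
               "degree")
})

test_that("degree of conservation separates true interactions on simulated cohorts", {
  sim <- simulateInteractionCohort(400, 8, p_true = 0.8,
                                   p_background = 0.15,
                                   true_fraction = 0.25, seed = 17)
  roc <- rankInteractionsROC(sim, sim$label)
  expect_gte(roc$aroc, 0.8)
  truth_keys <- sim$protein_id[sim$label]
  expect_gt(enrichmentFold(sim, truth_keys, 5, by = "protein"), 1.5)
})

test_that("identical-peptide exclusion removes exact window matches only", {
  set.seed(51)
  w <- 3
  seqs <- character(); rows <- list()
  for (i in 1:20) {
    pid <- sprintf("P%02d", i)
    s <- strsplit(randomProtein(20), "")[[1]]
    s[10] <- "S"
    seqs[pid] <- paste(s, collapse = "")
    rows[[i]] <- data.frame(protein_id = pid, position = 10L, residue = "S",
                            stringsAsFactors = FALSE)
  }
  ps <- PhosphoSet(do.call(rbind, rows), species = "toy")
  known <- vapply(sprintf("P%02d", 1:3), function(pid)
    extractWindow(seqs[[pid]], 10, w), "")
  filtered <- excludeIdenticalPeptides(ps, seqs, unname(known), w)
  expect_equal(length(filtered), 17)
  expect_false(any(sprintf("P%02d", 1:3) %in%
                     siteTable(filtered)$protein_id))

  # one-residue mismatch survives
  near <- sub("S", "T", known[1])  # differs at the acceptor character
  filtered2 <- excludeIdenticalPeptides(ps, seqs, near, w)
  expect_equal(length(filtered2), 20)
})

test_that("network export filters by degree and annotates edges", {
  ints <- data.frame(kinase = c("Cdk1", "Cdk1", "Plk1"),
                     protein_id = c("P1", "P2", "P3"),
                     n_cons = c(8L, 6L, 7L), stringsAsFactors = FALSE)
  ann <- list(known_interactions = interactionKey("Cdk1", "P1"),
              cellcycle_regulated = "P3", phenotype_genes = character())
  net <- exportNetwork(ints, ann, min_degree = 7)
  expect_equal(nrow(net), 2)            # the degree-6 edge is excluded
  expect_true(net$known_interaction[net$protein_id == "P1"])
  expect_true(net$cellcycle_regulated[net$protein_id == "P3"])
  expect_equal(nrow(net), sum(ints$n_cons >= 7))  # independent recount

  empty <- exportNetwork(ints[0, ], ann)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("kinase", "protein_id", "n_cons") %in% names(empty)))

  stem <- tempfile()
  exportNetwork(ints, ann, min_degree = 7, path = stem)
  expect_true(file.exists(paste0(stem, ".tsv")))
  expect_equal(readLines(paste0(stem, ".sif")),
               c("Cdk1 phosphorylates P1", "Plk1 phosphorylates P3"))
})
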