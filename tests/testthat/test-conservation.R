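test_that("aligned-position mapping follows target residue numbering", {
  ident <- list(aligned_query = "ACDEFGHIK", aligned_target = "ACDEFGHIK")
  expect_equal(mapAlignedPosition(ident, 7), 7L)

  gap <- list(aligned_query = "ACDEF", aligned_target = "AC-EF")
  expect_equal(mapAlignedPosition(gap, 3), 2L)  # nearest preceding residue

  lead <- list(aligned_query = "ACD", aligned_target = "--D")
  expect_true(is.na(mapAlignedPosition(lead, 1)))

  expect_error(mapAlignedPosition(ident, 0), "range")
  expect_error(mapAlignedPosition(ident, 10), "range")

  # query gaps do not consume query positions
  ins <- list(aligned_query = "AC--DEF", aligned_target = "ACWWDEF")
  expect_equal(mapAlignedPosition(ins, 3), 5L)
})

test_that("window rule calls conservation within +/-2 target residues", {
  seq50 <- paste0(strrep("A", 39), "S", strrep("A", 10))
  al <- list(aligned_query = seq50, aligned_target = seq50)
  hit <- callSiteConservation(40, c(40L), al, window = 2)
  expect_true(hit$conserved)
  expect_equal(hit$matched_target_position, 40L)

  miss <- callSiteConservation(40, c(43L), al, window = 2)
  expect_false(miss$conserved)

  none <- callSiteConservation(40, integer(), al, window = 2)
  expect_false(none$conserved)

  # nearest site wins; distance ties resolve to the smaller position
  near <- callSiteConservation(40, c(38L, 42L), al, window = 2)
  expect_equal(near$matched_target_position, 38L)
})

test_that("conservation calls agree with the exhaustive oracle on random alignments", {
  set.seed(21)
  for (i in 1:60) {
    ap <- randomAlignmentPair(ncol = sample(15:40, 1))
    n_query <- nchar(gsub("-", "", ap$aligned_query))
    n_target <- nchar(gsub("-", "", ap$aligned_target))
    qpos <- sample(n_query, 1)
    tsites <- sample(n_target, min(n_target, sample(0:4, 1)))
    got <- callSiteConservation(qpos, tsites, ap, window = 2)$conserved
    want <- oracleConservation(qpos, tsites, ap$aligned_query,
                               ap$aligned_target, window = 2)
    expect_equal(got, want, info = paste(i, qpos))
  }
})

test_that("profiles count conserved species per site across the cohort", {
  qseq <- paste0(strrep("A", 9), "S", strrep("A", 10))
  ps <- toySites("P1", 10L)
  maps <- list(sp1 = toyMap("sp1", "P1", "o1", qseq),
               sp2 = toyMap("sp2", "P1", "o2", qseq),
               sp3 = toyMap("sp3", "P1", "o3", qseq))
  # target sites at offsets 0, +2, +3: the first two are in-window
  tsites <- list(sp1 = toySites("o1", 10L, species = "sp1"),
                 sp2 = toySites("o2", 12L, species = "sp2"),
                 sp3 = toySites("o3", 13L, species = "sp3"))
  prof <- buildConservationProfiles(ps, maps, tsites, window = 2)
  expect_equal(prof$degree, 2L)
  expect_equal(prof$conserved_species, "sp1;sp2")

  # removing a species can never increase the degree
  prof2 <- buildConservationProfiles(ps, maps[c("sp1", "sp3")],
                                     tsites[c("sp1", "sp3")], window = 2)
  expect_lte(prof2$degree, prof$degree)

  # a species without an ortholog contributes FALSE
  maps$sp1 <- toyMap("sp1", "OTHER", "o1", qseq)
  prof3 <- buildConservationProfiles(ps, maps, tsites, window = 2)
  expect_equal(prof3$degree, 1L)
})

test_that("degree separates functional from background sites on a synthetic cohort", {
  cfg <- cohortConfig(n_proteins = 80, n_species = 8, seed = 31)
  coh <- generateCohort(cfg)
  prof <- buildConservationProfiles(coh$query_sites,
                                    truthOrthologMaps(coh),
                                    coh$species_sites, window = 2)
  functional <- skey(prof$protein_id, prof$position) %in%
    coh$truth$functional_sites
  expect_gt(mean(prof$degree[functional]), mean(prof$degree[!functional]))
  expect_gte(auroc(prof$degree, functional), 0.75)
})

test_that("enrichment-by-degree tables are monotone and handle empty annotation", {
  prof <- data.frame(protein_id = paste0("P", 1:10), position = 1:10,
                     residue = "S", degree = c(0, 0, 1, 1, 2, 2, 3, 3, 4, 5),
                     stringsAsFactors = FALSE)
  known <- c("P9:9", "P10:10", "P7:7")
  tab <- functionEnrichmentByDegree(prof, known)
  expect_true(all(diff(tab$n_sites) <= 0))
  expect_equal(tab$fraction[tab$min_degree == 0], 0.3)
  expect_equal(tab$fraction[tab$min_degree == 4], 1)

  none <- functionEnrichmentByDegree(prof, character())
  expect_true(all(none$fraction[none$n_sites > 0] == 0))
})

test_that("disorder stratification classifies sites by their own residue call", {
  prof <- data.frame(protein_id = rep("P1", 4), position = c(2L, 4L, 6L, 8L),
                     residue = "S", degree = c(0, 1, 2, 3),
                     stringsAsFactors = FALSE)
  disorder <- list(P1 = rep(c(FALSE, TRUE), each = 5))  # 6, 8 disordered
  tab <- functionEnrichmentByDegree(prof, c("P1:6", "P1:8"),
                                    disorder = disorder)
  ord <- attr(tab, "ordered"); dis <- attr(tab, "disordered")
  expect_equal(ord$n_sites[ord$min_degree == 0], 2L)
  expect_equal(dis$n_sites[dis$min_degree == 0], 2L)
  expect_equal(dis$n_known[dis$min_degree == 0], 2L)
  expect_equal(ord$n_known[ord$min_degree == 0], 0L)
})
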