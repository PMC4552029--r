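# Seeded synthetic multi-species cohorts. The generator emits exactly the
# inputs the pipeline consumes — proteomes with controlled ortholog
# divergence, phosphosite tables with tunable per-species conservation,
# implanted kinase motifs with ground-truth interactions, multi-model RSA
# fixtures with controlled flexibility, disorder tracks and annotation
# sets — so every stage can be tested against known truth without
# downloads.

#' Cohort generator configuration
#'
#' Collects and validates all generator parameters. Defaults describe the
#' standard test cohort: 60 proteins of 150-250 residues across 8 species,
#' 90\% ortholog retention with 5\% per-species residue substitution, two
#' phosphosites per protein, a 30\% functional minority conserved per
#' species with probability 0.9 against a 0.2 background (so site turnover
#' is fast, as in real phosphoproteomes), two kinases with four-residue
#' motifs, and multi-model RSA noise of sd 15 at phosphosites versus sd 3
#' elsewhere.
#'
#' @param n_proteins number of query proteins.
#' @param protein_length length range \code{c(min, max)}.
#' @param n_species number of target species.
#' @param species optional species labels (default \code{sp1..spN}).
#' @param ortholog_probability probability a protein has an ortholog in a
#'   given species.
#' @param substitution_rate per-residue substitution probability applied to
#'   each ortholog.
#' @param site_density phosphosites per query protein.
#' @param functional_fraction fraction of query sites that are functional.
#' @param q_functional,q_background per-species conservation probability of
#'   functional / background sites.
#' @param kinases named list; each element a named character vector mapping
#'   signed window offsets (as names, e.g. \code{"-3"}) to the motif
#'   residue at that offset.
#' @param true_interaction_fraction fraction of proteins that are true
#'   substrates of each kinase.
#' @param w kinase window half-width (15-mer default).
#' @param rsa list with \code{n_models} (range), \code{base_mean},
#'   \code{base_sd} (per-residue baseline RSA), \code{flexible_sd} (per-model
#'   noise sd at phosphosites) and \code{background_sd} (elsewhere).
#' @param seed integer RNG seed; the cohort is a pure function of the
#'   configuration including this seed.
#' @return a validated \code{CohortConfig} list.
#' @export
cohortConfig <- function(n_proteins = 60,
                         protein_length = c(150, 250),
                         n_species = 8,
                         species = NULL,
                         ortholog_probability = 0.9,
                         substitution_rate = 0.05,
                         site_density = 2,
                         functional_fraction = 0.3,
                         q_functional = 0.9,
                         q_background = 0.2,
                         kinases = list(
                           KinA = c(`-3` = "R", `-2` = "R",
                                    `1` = "L", `3` = "F"),
                           KinB = c(`-3` = "L", `-2` = "K",
                                    `1` = "P", `2` = "K")),
                         true_interaction_fraction = 0.25,
                         w = 7,
                         rsa = list(n_models = c(2, 3), base_mean = 40,
                                    base_sd = 20, flexible_sd = 15,
                                    background_sd = 3),
                         seed = 42) {
  cfg <- list(n_proteins = n_proteins, protein_length = protein_length,
              n_species = n_species,
              species = if (is.null(species)) paste0("sp", seq_len(n_species))
                        else species,
              ortholog_probability = ortholog_probability,
              substitution_rate = substitution_rate,
              site_density = site_density,
              functional_fraction = functional_fraction,
              q_functional = q_functional, q_background = q_background,
              kinases = kinases,
              true_interaction_fraction = true_interaction_fraction,
              w = w, rsa = rsa, seed = seed)
  fracs <- c(ortholog_probability, substitution_rate, functional_fraction,
             q_functional, q_background, true_interaction_fraction)
  if (any(fracs < 0 | fracs > 1))
    stop("all probability parameters must lie in [0, 1]", call. = FALSE)
  if (n_species < 1) stop("n_species must be >= 1", call. = FALSE)
  if (length(cfg$species) != n_species)
    stop("species labels must match n_species", call. = FALSE)
  for (k in names(kinases)) {
    off <- as.integer(names(kinases[[k]]))
    if (any(is.na(off)) || any(off == 0L) || any(abs(off) > w))
      stop("motif offsets for ", k, " must be non-zero and within +/-", w,
           call. = FALSE)
  }
  if (2 * w + 1 > protein_length[1])
    stop("kinase window does not fit the shortest protein", call. = FALSE)
  class(cfg) <- "CohortConfig"
  cfg
}

#' Generate a synthetic multi-species phosphoproteomics cohort
#'
#' Builds a query proteome with phosphosites, derives per-species orthologs
#' by seeded per-residue substitution (never touching the window of an
#' implanted motif site, so true kinase interactions survive divergence),
#' propagates sites into orthologs with the configured conservation
#' probabilities and a uniform position jitter on [-2, +2] (exercising the
#' conservation window at its boundary by construction), and implants
#' kinase motifs defining ground-truth kinase-protein interactions.
#'
#' @param cfg a [cohortConfig()] object.
#' @return list of class \code{PhosphoCohort}:
#'   \describe{
#'     \item{query_proteome}{named character vector.}
#'     \item{species_proteomes}{list per species.}
#'     \item{query_sites}{[PhosphoSet-class] for the query species.}
#'     \item{species_sites}{list of [PhosphoSet-class] per species.}
#'     \item{ortholog_truth}{list per species: named map query id ->
#'       ortholog id.}
#'     \item{truth}{ground truth: \code{functional_sites} (site keys),
#'       \code{true_interactions} (\code{data.frame}),
#'       \code{motif_sites}, \code{conserved_site_map} (site key ->
#'       species vector), \code{disorder} (per-protein logical tracks),
#'       \code{annotations} (benchmark sets derived from the truth).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "CohortConfig"))
  withSeed(cfg$seed, .generateCohortImpl(cfg))
}

.generateCohortImpl <- function(cfg) {
  n <- cfg$n_proteins
  ids <- sprintf("P%03d", seq_len(n))
  lens <- sample(seq(cfg$protein_length[1], cfg$protein_length[2]), n,
                 replace = TRUE)
  names(lens) <- ids
  seqs <- lapply(lens, function(L) sample(AA20, L, replace = TRUE))

  # --- query phosphosites -------------------------------------------------
  margin <- cfg$w + 3L
  site_rows <- list()
  for (pid in ids) {
    L <- lens[[pid]]
    # sites are kept >= 2w+1 apart so an implanted motif window can never
    # overwrite a neighbouring site's acceptor residue
    pool <- seq(margin, L - margin)
    pos <- integer()
    while (length(pos) < cfg$site_density && length(pool)) {
      p <- if (length(pool) == 1L) pool else sample(pool, 1L)
      pos <- c(pos, p)
      pool <- pool[abs(pool - p) > 2L * cfg$w]
    }
    pos <- sort(pos)
    res <- sample(ACCEPTORS, length(pos), replace = TRUE,
                  prob = c(0.78, 0.17, 0.05))
    seqs[[pid]][pos] <- res
    site_rows[[pid]] <- data.frame(protein_id = pid, position = pos,
                                   residue = res, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL
  sites$functional <- runif(nrow(sites)) < cfg$functional_fraction

  # --- kinase motif implantation ------------------------------------------
  motif_rows <- list()
  for (ki in seq_along(cfg$kinases)) {
    kname <- names(cfg$kinases)[ki]
    motif <- cfg$kinases[[ki]]
    substrates <- sample(ids, round(cfg$true_interaction_fraction * n))
    for (pid in substrates) {
      psites <- sites[sites$protein_id == pid, ]
      if (nrow(psites) < ki) next  # k-th kinase claims the k-th site
      pos <- psites$position[ki]
      off <- as.integer(names(motif))
      seqs[[pid]][pos + off] <- unname(motif)
      motif_rows[[length(motif_rows) + 1L]] <-
        data.frame(kinase = kname, protein_id = pid, position = pos,
                   stringsAsFactors = FALSE)
    }
  }
  motif_sites <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    data.frame(kinase = character(), protein_id = character(),
               position = integer(), stringsAsFactors = FALSE)
  true_interactions <- unique(motif_sites[c("kinase", "protein_id")])
  rownames(true_interactions) <- NULL

  # residue ranges protected from substitution (motif windows)
  protected <- lapply(setNames(ids, ids), function(pid) {
    ms <- motif_sites[motif_sites$protein_id == pid, ]
    if (!nrow(ms)) return(integer())
    unique(unlist(lapply(ms$position, function(p)
      seq(max(1L, p - cfg$w), min(lens[[pid]], p + cfg$w)))))
  })

  # --- orthologs and per-species sites ------------------------------------
  species_proteomes <- list()
  species_sites <- list()
  ortholog_truth <- list()
  cons_map <- setNames(vector("list", nrow(sites)),
                       siteKey(sites$protein_id, sites$position))
  for (sp in cfg$species) {
    has_orth <- runif(n) < cfg$ortholog_probability
    prot <- list()
    tmap <- character()
    site_acc <- list()
    for (i in seq_len(n)) {
      if (!has_orth[i]) next
      pid <- ids[i]
      oid <- paste0(sp, "_", pid)
      oseq <- seqs[[pid]]
      sub_mask <- runif(lens[[pid]]) < cfg$substitution_rate
      sub_mask[protected[[pid]]] <- FALSE
      if (any(sub_mask)) {
        oseq[sub_mask] <- vapply(oseq[sub_mask], function(orig)
          sample(setdiff(AA20, orig), 1L), "")
      }
      # propagate phosphosites
      psites <- sites[sites$protein_id == pid, ]
      is_motif <- siteKey(psites$protein_id, psites$position) %in%
        siteKey(motif_sites$protein_id, motif_sites$position)[
          motif_sites$protein_id == pid]
      for (j in seq_len(nrow(psites))) {
        p_cons <- if (psites$functional[j]) cfg$q_functional
                  else cfg$q_background
        if (runif(1) >= p_cons) next
        key <- siteKey(pid, psites$position[j])
        if (is_motif[j]) {
          tpos <- psites$position[j]  # motif sites stay put, window intact
        } else {
          tpos <- psites$position[j] + sample(-2:2, 1L)
          tpos <- min(max(1L, tpos), lens[[pid]])
          if (tpos %in% protected[[pid]]) {
            # never rewrite an implanted motif window; keep the site only
            # if an acceptor already sits there
            if (!oseq[tpos] %in% ACCEPTORS) next
          } else if (!oseq[tpos] %in% ACCEPTORS) {
            oseq[tpos] <- "S"
          }
        }
        site_acc[[length(site_acc) + 1L]] <-
          data.frame(protein_id = oid, position = tpos,
                     stringsAsFactors = FALSE)
        cons_map[[key]] <- c(cons_map[[key]], sp)
      }
      prot[[oid]] <- paste(oseq, collapse = "")
      tmap[pid] <- oid
    }
    sdf <- if (length(site_acc)) unique(do.call(rbind, site_acc)) else
      data.frame(protein_id = character(), position = integer(),
                 stringsAsFactors = FALSE)
    if (nrow(sdf)) {
      sdf$residue <- vapply(seq_len(nrow(sdf)), function(r) {
        substr(prot[[sdf$protein_id[r]]], sdf$position[r], sdf$position[r])
      }, "")
      sdf <- sdf[sdf$residue %in% ACCEPTORS, , drop = FALSE]
    } else sdf$residue <- character()
    sdf$sources <- sp
    species_proteomes[[sp]] <- unlist(prot)
    species_sites[[sp]] <- PhosphoSet(sdf, species = sp)
    ortholog_truth[[sp]] <- tmap
  }

  # --- query site scores, disorder, annotations ---------------------------
  slip <- sample(0:7, nrow(sites), replace = TRUE,
                 prob = c(0.1, 0.1, 0.1, 0.25, 0.2, 0.12, 0.08, 0.05))
  evalue <- 10^(-runif(nrow(sites), 1, 8))
  qsites <- data.frame(protein_id = sites$protein_id,
                       position = sites$position, residue = sites$residue,
                       slip_score = slip, evalue = evalue,
                       ambiguous = runif(nrow(sites)) < 0.2,
                       sources = "synthetic_ms", stringsAsFactors = FALSE)
  disorder <- lapply(setNames(ids, ids), function(pid) {
    L <- lens[[pid]]
    state <- logical(L)
    state[1] <- runif(1) < 0.3
    for (i in seq(2, L)) {
      state[i] <- if (runif(1) < 0.95) state[i - 1] else !state[i - 1]
    }
    state
  })
  substrate_ids <- unique(true_interactions$protein_id)
  other_ids <- setdiff(ids, substrate_ids)
  annotations <- list(
    known_function = siteKey(sites$protein_id[sites$functional],
                             sites$position[sites$functional]),
    known_interactions = interactionKey(true_interactions$kinase,
                                        true_interactions$protein_id),
    cellcycle_regulated = c(
      substrate_ids[runif(length(substrate_ids)) < 0.8],
      other_ids[runif(length(other_ids)) < 0.1]),
    phenotype_genes = c(
      substrate_ids[runif(length(substrate_ids)) < 0.5],
      other_ids[runif(length(other_ids)) < 0.15])
  )

  structure(list(
    query_proteome = vapply(seqs, paste, "", collapse = ""),
    species_proteomes = species_proteomes,
    query_sites = PhosphoSet(qsites, species = "query"),
    species_sites = species_sites,
    ortholog_truth = ortholog_truth,
    truth = list(
      functional_sites = annotations$known_function,
      true_interactions = true_interactions,
      motif_sites = motif_sites,
      conserved_site_map = cons_map,
      disorder = disorder,
      annotations = annotations),
    config = cfg
  ), class = "PhosphoCohort")
}

#' Generate multi-model RSA fixtures with controlled flexibility
#'
#' For each query protein, draws a per-residue baseline accessibility and
#' emits several comparative "models" whose values are the baseline plus
#' per-model noise — sd \code{rsa$flexible_sd} at phosphosite positions,
#' sd \code{rsa$background_sd} elsewhere — so phosphosites carry genuine
#' cross-template variability while the rest of the protein stays stable.
#' Model metadata spans the acceptance rule: regular models pass it, and a
#' small constructed set (one violation per criterion) is appended so
#' filtering is exercised.
#'
#' @param cfg the [cohortConfig()] used for the cohort.
#' @param cohort a \code{PhosphoCohort} from [generateCohort()].
#' @return list with \code{rsa} (long per-residue \code{data.frame}:
#'   \code{model_id}, \code{protein_id}, \code{position}, \code{residue},
#'   \code{rsa_all_atom}), \code{meta} (model metadata \code{data.frame}),
#'   and \code{flexible_residues} (site keys generated with extra
#'   variance).
#' @export
generateRSAFixtures <- function(cfg, cohort) {
  withSeed(cfg$seed + 1L, {
    sites <- siteTable(cohort$query_sites)
    rsa_rows <- list(); meta_rows <- list()
    for (pid in names(cohort$query_proteome)) {
      seqc <- strsplit(cohort$query_proteome[[pid]], "")[[1]]
      L <- length(seqc)
      base <- pmin(100, pmax(0, rnorm(L, cfg$rsa$base_mean, cfg$rsa$base_sd)))
      sdv <- rep(cfg$rsa$background_sd, L)
      sdv[sites$position[sites$protein_id == pid]] <- cfg$rsa$flexible_sd
      n_models <- sample(seq(cfg$rsa$n_models[1], cfg$rsa$n_models[2]), 1L)
      for (k in seq_len(n_models)) {
        mid <- paste0(pid, "_m", k)
        cov <- if (k > 1L && runif(1) < 0.3) {
          st <- sample(seq_len(max(1L, L %/% 3L)), 1L)
          c(st, min(L, st + (2L * L) %/% 3L))
        } else c(1L, L)
        vals <- pmax(0, base + rnorm(L, 0, sdv))
        idx <- seq(cov[1], cov[2])
        rsa_rows[[length(rsa_rows) + 1L]] <- data.frame(
          model_id = mid, protein_id = pid, position = idx,
          residue = seqc[idx], rsa_all_atom = round(vals[idx], 2),
          stringsAsFactors = FALSE)
        meta_rows[[length(meta_rows) + 1L]] <- data.frame(
          model_id = mid, protein_id = pid,
          template_identity = round(runif(1, 26, 95), 1),
          coverage_start = cov[1], coverage_end = cov[2],
          no35 = round(runif(1, 40, 80), 1),
          ga341 = round(runif(1, 0.7, 1), 3),
          evalue = 1e-6, zdope = round(runif(1, -2, -0.1), 2),
          stringsAsFactors = FALSE)
      }
    }
    # constructed rejects: each violates the acceptance rule differently
    pid1 <- names(cohort$query_proteome)[1]
    L1 <- nchar(cohort$query_proteome[[pid1]])
    rej <- data.frame(
      model_id = c("REJ_identity", "REJ_quality"),
      protein_id = pid1,
      template_identity = c(20, 30),
      coverage_start = 1L, coverage_end = L1,
      no35 = c(80, 39), ga341 = c(0.9, 0.6),
      evalue = c(1e-6, 1e-3), zdope = c(-1, 0.2),
      stringsAsFactors = FALSE)
    meta <- rbind(do.call(rbind, meta_rows), rej)
    rownames(meta) <- NULL
    rsa <- do.call(rbind, rsa_rows)
    rownames(rsa) <- NULL
    list(rsa = rsa, meta = meta,
         flexible_residues = siteKey(sites$protein_id, sites$position))
  })
}

#' Simulate an interaction-level conservation cohort
#'
#' Direct simulation of the interaction-conservation study design: a set
#' of kinase-protein interactions, a fraction of which are true, where a
#' true interaction is independently predicted in each of \code{n_species}
#' species with probability \code{p_true} and a background interaction
#' with probability \code{p_background}; the conservation degree is the
#' number of species where the prediction fires.
#'
#' @param n_interactions number of interactions.
#' @param n_species number of species.
#' @param p_true,p_background per-species prediction probabilities.
#' @param true_fraction fraction of true interactions.
#' @param seed RNG seed.
#' @return \code{data.frame} with \code{kinase}, \code{protein_id},
#'   \code{n_cons} and \code{label} (logical truth).
#' @export
simulateInteractionCohort <- function(n_interactions = 400, n_species = 8,
                                      p_true = 0.9, p_background = 0.2,
                                      true_fraction = 0.25, seed = 1) {
  withSeed(seed, {
    label <- runif(n_interactions) < true_fraction
    p <- ifelse(label, p_true, p_background)
    n_cons <- stats::rbinom(n_interactions, n_species, p)
    data.frame(kinase = "Kin",
               protein_id = sprintf("I%04d", seq_len(n_interactions)),
               n_cons = n_cons, label = label, stringsAsFactors = FALSE)
  })
}

#' Write a cohort fixture bundle to disk
#'
#' Emits every file class the pipeline consumes — FASTA proteomes,
#' phosphosite TSVs, a kinase-substrate table (windows of the implanted
#' motif sites), per-model .rsa files plus model metadata, disorder
#' tracks, annotation sets, the ground-truth JSON — and a manifest with
#' the seed, a configuration hash and an md5 checksum per file. The bundle
#' is byte-reproducible for a given configuration and seed.
#'
#' @param cohort a \code{PhosphoCohort}.
#' @param rsa_fixtures output of [generateRSAFixtures()] (or \code{NULL} to
#'   skip structural files).
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
writeFixtureBundle <- function(cohort, rsa_fixtures = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "models"), showWarnings = FALSE)
  cfg <- cohort$config
  writeFasta <- function(seqs, path)
    writeXStringSet(AAStringSet(seqs), path, width = 60L)
  writeTsv <- function(d, path)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)

  writeFasta(cohort$query_proteome, file.path(dir, "query.fasta"))
  writeTsv(siteTable(cohort$query_sites), file.path(dir, "query_sites.tsv"))
  for (sp in names(cohort$species_proteomes)) {
    writeFasta(cohort$species_proteomes[[sp]],
               file.path(dir, paste0(sp, ".fasta")))
    writeTsv(siteTable(cohort$species_sites[[sp]]),
             file.path(dir, paste0(sp, "_sites.tsv")))
  }
  # kinase-substrate windows from the implanted motif sites
  ms <- cohort$truth$motif_sites
  if (nrow(ms)) {
    ms$peptide <- vapply(seq_len(nrow(ms)), function(i)
      extractWindow(cohort$query_proteome[[ms$protein_id[i]]],
                    ms$position[i], cfg$w), "")
  } else ms$peptide <- character()
  writeTsv(ms, file.path(dir, "ksr.tsv"))
  # disorder tracks: one 0/1 string per protein
  dis <- data.frame(protein_id = names(cohort$truth$disorder),
                    calls = vapply(cohort$truth$disorder, function(v)
                      paste(as.integer(v), collapse = ""), ""),
                    stringsAsFactors = FALSE)
  writeTsv(dis, file.path(dir, "disorder.tsv"))
  ann <- cohort$truth$annotations
  writeTsv(data.frame(site_key = ann$known_function),
           file.path(dir, "known_function.tsv"))
  writeTsv(data.frame(interaction_key = ann$known_interactions),
           file.path(dir, "known_interactions.tsv"))
  writeTsv(data.frame(protein_id = ann$cellcycle_regulated),
           file.path(dir, "cellcycle_regulated.tsv"))
  writeTsv(data.frame(protein_id = ann$phenotype_genes),
           file.path(dir, "phenotype_genes.tsv"))
  if (!is.null(rsa_fixtures)) {
    writeTsv(rsa_fixtures$meta, file.path(dir, "model_meta.tsv"))
    for (mid in unique(rsa_fixtures$rsa$model_id)) {
      sub <- rsa_fixtures$rsa[rsa_fixtures$rsa$model_id == mid, ]
      writeRSAFile(sub, file.path(dir, "models", paste0(mid, ".rsa")))
    }
  }
  truth_json <- cohort$truth
  truth_json$disorder <- NULL  # carried in disorder.tsv
  truth_json$ortholog_truth <- cohort$ortholog_truth
  jsonlite::write_json(truth_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  files <- sort(files)
  checksums <- vapply(files, function(f)
    unname(tools::md5sum(file.path(dir, f))), "")
  manifest <- list(seed = cfg$seed,
                   config_hash = unclass(objectHash(unclass(cfg))),
                   files = as.list(checksums))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
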