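# Stage orchestration: one entry point that runs the analysis stages over
# a fixture bundle (or equivalently structured real inputs), writing
# TSV/JSON outputs plus run metadata per stage. Stages communicate through
# their on-disk outputs, so any subset can be (re-)run as long as its
# upstream outputs exist.

.PIPELINE_STAGES <- c("compile", "orthology", "conservation", "kinase",
                      "interactions", "structure", "report")

#' Read and validate a pipeline run configuration
#'
#' Accepts a YAML file path or a list. Every analysis constant is a named,
#' documented default: conservation window 2, kinase window half-width 7,
#' CV folds 10 with AROC gate 0.7, RSA low-accessibility threshold 20,
#' network degree 7, RBH minimum score 50, confidence filter E-value 0.001
#' / SLIP 3. Validation reports all problems at once.
#'
#' @param config list or YAML path. Required: \code{bundle_dir},
#'   \code{outdir}. Optional (with defaults as above): \code{species}
#'   (default: inferred from the bundle's FASTA files), \code{window},
#'   \code{w}, \code{min_score}, \code{cv_folds}, \code{aroc_gate},
#'   \code{rsa_threshold}, \code{min_network_degree}, \code{evalue_max},
#'   \code{slip_min}, \code{seed}.
#' @param strict when \code{TRUE}, a missing \code{seed} is an error
#'   instead of defaulting to 1.
#' @return validated config list.
#' @export
readRunConfig <- function(config, strict = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(window = 2, w = 7, min_score = 50, cv_folds = 10,
                   aroc_gate = 0.7, rsa_threshold = 20,
                   min_network_degree = 7, evalue_max = 0.001, slip_min = 3)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  errs <- character()
  if (is.null(config$bundle_dir)) errs <- c(errs, "bundle_dir is required")
  else if (!dir.exists(config$bundle_dir))
    errs <- c(errs, paste("bundle_dir does not exist:", config$bundle_dir))
  if (is.null(config$outdir)) errs <- c(errs, "outdir is required")
  if (is.null(config$seed)) {
    if (strict) errs <- c(errs, "seed is required in strict mode")
    else config$seed <- 1L
  }
  for (nm in names(defaults)) {
    if (!is.numeric(config[[nm]]) || length(config[[nm]]) != 1L)
      errs <- c(errs, paste(nm, "must be a single number"))
  }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  if (is.null(config$species) && !is.null(config$bundle_dir)) {
    fa <- list.files(config$bundle_dir, pattern = "\\.fasta$")
    config$species <- sort(setdiff(sub("\\.fasta$", "", fa), "query"))
  }
  config
}

.stageDeps <- function(outdir) list(
  compile = character(),
  orthology = character(),
  conservation = c(compile = file.path(outdir, "compile", "sites.tsv"),
                   orthology = file.path(outdir, "orthology")),
  kinase = c(compile = file.path(outdir, "compile", "sites.tsv")),
  interactions = c(
    kinase = file.path(outdir, "kinase", "query_predictions.tsv"),
    orthology = file.path(outdir, "orthology")),
  structure = c(compile = file.path(outdir, "compile", "sites.tsv")),
  report = c(compile = file.path(outdir, "compile", "summary.json"),
             conservation = file.path(outdir, "conservation", "summary.json"),
             kinase = file.path(outdir, "kinase", "summary.json"),
             interactions = file.path(outdir, "interactions", "summary.json"),
             structure = file.path(outdir, "structure", "summary.json"))
)

.writeStageMeta <- function(outdir, stage, config) {
  # the hash covers the analysis parameters, not the filesystem locations,
  # so identical runs in different directories stay byte-identical
  hashed <- config[sort(setdiff(names(config), c("outdir", "bundle_dir")))]
  jsonlite::write_json(
    list(stage = stage, seed = config$seed,
         config_hash = unclass(objectHash(hashed))),
    file.path(outdir, stage, "metadata.json"),
    auto_unbox = TRUE, digits = NA)
}

.writeJson <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")

.writeTsv <- function(d, path)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)

.siteDialect <- c(protein = "protein_id", position = "position",
                  residue = "residue", slip = "slip_score",
                  evalue = "evalue", ambiguous = "ambiguous")

#' Run the phosphosite-function inference pipeline
#'
#' Executes the requested stages in canonical order over a fixture bundle
#' (see [writeFixtureBundle()] for the expected file layout). Each stage
#' writes its outputs and a metadata block under
#' \code{<outdir>/<stage>/}; re-running with identical inputs, config and
#' seed reproduces the outputs byte for byte.
#'
#' @param config run configuration (list or YAML path); see
#'   [readRunConfig()].
#' @param stages subset of \code{compile}, \code{orthology},
#'   \code{conservation}, \code{kinase}, \code{interactions},
#'   \code{structure}, \code{report}; default all.
#' @param strict passed to [readRunConfig()].
#' @return the output directory, invisibly.
#' @export
runPipeline <- function(config, stages = .PIPELINE_STAGES, strict = FALSE) {
  config <- readRunConfig(config, strict = strict)
  stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  deps <- .stageDeps(outdir)
  for (st in stages) {
    need <- deps[[st]]
    missing <- need[!file.exists(need)]
    # a dependency satisfied by an earlier stage in this same run is fine
    missing <- missing[!names(missing) %in% stages[seq_len(match(st, stages) - 1L)]]
    if (length(missing))
      stop("stage '", st, "' requires output of stage(s): ",
           paste(names(missing), collapse = ", "),
           " (run them first)", call. = FALSE)
    dir.create(file.path(outdir, st), showWarnings = FALSE)
    switch(st,
      compile = .stageCompile(config),
      orthology = .stageOrthology(config),
      conservation = .stageConservation(config),
      kinase = .stageKinase(config),
      interactions = .stageInteractions(config),
      structure = .stageStructure(config),
      report = .stageReport(config))
    .writeStageMeta(outdir, st, config)
  }
  invisible(outdir)
}

.readCompiledSites <- function(config) {
  d <- read.delim(file.path(config$outdir, "compile", "sites.tsv"),
                  stringsAsFactors = FALSE)
  PhosphoSet(d, species = "query")
}

.stageCompile <- function(config) {
  out <- file.path(config$outdir, "compile")
  parsed <- readPhosphositeTable(
    file.path(config$bundle_dir, "query_sites.tsv"),
    dialect = .siteDialect, source_label = "query")
  ps <- compileNonredundant(list(query = parsed$sites), species = "query")
  hc <- filterHighConfidence(ps, config$evalue_max, config$slip_min)
  .writeTsv(siteTable(ps), file.path(out, "sites.tsv"))
  comp <- residueComposition(ps)
  .writeJson(list(
    n_sites = length(ps), n_rejected_rows = nrow(parsed$rejects),
    n_high_confidence = length(hc),
    provenance = as.list(ps@provenance),
    composition = comp), file.path(out, "summary.json"))
}

.stageOrthology <- function(config) {
  out <- file.path(config$outdir, "orthology")
  query <- readAAStringSet(file.path(config$bundle_dir, "query.fasta"))
  for (sp in config$species) {
    target <- readAAStringSet(file.path(config$bundle_dir,
                                        paste0(sp, ".fasta")))
    om <- reciprocalBestHits(query, target, min_score = config$min_score,
                             species = sp)
    writeOrthologMap(om, file.path(out, paste0(sp, "_orthologs.tsv")))
  }
}

.readOrthologMaps <- function(config) {
  maps <- lapply(config$species, function(sp)
    readOrthologMap(file.path(config$outdir, "orthology",
                              paste0(sp, "_orthologs.tsv"))))
  names(maps) <- config$species
  maps
}

.readSpeciesSites <- function(config) {
  out <- lapply(config$species, function(sp) {
    parsed <- readPhosphositeTable(
      file.path(config$bundle_dir, paste0(sp, "_sites.tsv")),
      dialect = .siteDialect, source_label = sp)
    compileNonredundant(setNames(list(parsed$sites), sp), species = sp)
  })
  names(out) <- config$species
  out
}

.readDisorder <- function(config) {
  path <- file.path(config$bundle_dir, "disorder.tsv")
  if (!file.exists(path)) return(NULL)
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c("character", "character"))
  tracks <- lapply(d$calls, function(s)
    strsplit(s, "", fixed = TRUE)[[1]] == "1")
  names(tracks) <- d$protein_id
  tracks
}

.stageConservation <- function(config) {
  out <- file.path(config$outdir, "conservation")
  ps <- .readCompiledSites(config)
  maps <- .readOrthologMaps(config)
  tsites <- .readSpeciesSites(config)
  profiles <- buildConservationProfiles(ps, maps, tsites,
                                        window = config$window)
  .writeTsv(profiles, file.path(out, "profiles.tsv"))
  known_path <- file.path(config$bundle_dir, "known_function.tsv")
  known <- if (file.exists(known_path))
    read.delim(known_path, stringsAsFactors = FALSE)$site_key else character()
  enr <- functionEnrichmentByDegree(profiles, known,
                                    disorder = .readDisorder(config))
  .writeTsv(enr, file.path(out, "enrichment.tsv"))
  cs <- conservationSummary(profiles)
  .writeJson(list(
    n_sites = nrow(profiles),
    n_conserved = sum(profiles$degree >= 1),
    fraction_conserved = unname(cs$fraction[cs$min_degree == 1]),
    by_degree = cs), file.path(out, "summary.json"))
}

.stageKinase <- function(config) {
  out <- file.path(config$outdir, "kinase")
  ksr <- read.delim(file.path(config$bundle_dir, "ksr.tsv"),
                    stringsAsFactors = FALSE)
  ps <- .readCompiledSites(config)
  query <- readAAStringSet(file.path(config$bundle_dir, "query.fasta"))
  kinases <- sort(unique(ksr$kinase))
  cv_rows <- list(); models <- list(); pred_rows <- list()
  sp_pred_rows <- lapply(config$species, function(sp) list())
  names(sp_pred_rows) <- config$species
  tsites <- .readSpeciesSites(config)
  tseqs <- lapply(config$species, function(sp)
    readAAStringSet(file.path(config$bundle_dir, paste0(sp, ".fasta"))))
  names(tseqs) <- config$species
  empty_pred <- data.frame(kinase = character(), protein_id = character(),
                           position = integer(), residue = character(),
                           peptide = character(), mss = numeric(),
                           stringsAsFactors = FALSE)
  for (kn in kinases) {
    pos <- ksr$peptide[ksr$kinase == kn]
    neg <- ksr$peptide[ksr$kinase != kn]
    cv <- crossValidateKinase(pos, neg, k = config$cv_folds,
                              seed = config$seed, kinase = kn)
    selected <- cv$median_aroc > config$aroc_gate
    cv_rows[[kn]] <- data.frame(kinase = kn,
                                median_aroc = cv$median_aroc,
                                k = cv$k, selected = selected)
    if (!selected) next
    m <- buildPSSM(kn, pos)
    pssmCutoff(m) <- calibrateCutoff(mssScore(m, pos), mssScore(m, neg),
                                     seed = config$seed)
    models[[kn]] <- m
    pred_rows[[kn]] <- predictTargetSites(ps, query, m)
    for (sp in config$species) {
      sp_pred_rows[[sp]][[kn]] <-
        suppressMessages(predictTargetSites(tsites[[sp]], tseqs[[sp]], m))
    }
  }
  .writeTsv(do.call(rbind, cv_rows), file.path(out, "cv.tsv"))
  .writeJson(lapply(models, function(m) list(
    kinase = m@kinase, w = m@w, cutoff = m@cutoff,
    freq = apply(m@freq, 2, function(col) as.list(setNames(col, AA20))))),
    file.path(out, "models.json"))
  qp <- do.call(rbind, c(list(empty_pred), pred_rows))
  .writeTsv(qp, file.path(out, "query_predictions.tsv"))
  for (sp in config$species) {
    .writeTsv(do.call(rbind, c(list(empty_pred), sp_pred_rows[[sp]])),
              file.path(out, paste0(sp, "_predictions.tsv")))
  }
  .writeJson(list(
    kinases_trained = kinases,
    kinases_selected = names(models),
    n_query_predictions = nrow(qp)), file.path(out, "summary.json"))
}

.readAnnotationSets <- function(config) {
  rd <- function(file, col) {
    p <- file.path(config$bundle_dir, file)
    if (file.exists(p)) read.delim(p, stringsAsFactors = FALSE)[[col]]
    else character()
  }
  list(known_interactions = rd("known_interactions.tsv", "interaction_key"),
       cellcycle_regulated = rd("cellcycle_regulated.tsv", "protein_id"),
       phenotype_genes = rd("phenotype_genes.tsv", "protein_id"))
}

.stageInteractions <- function(config) {
  out <- file.path(config$outdir, "interactions")
  qp <- read.delim(file.path(config$outdir, "kinase",
                             "query_predictions.tsv"),
                   stringsAsFactors = FALSE)
  maps <- .readOrthologMaps(config)
  sp_int <- lapply(config$species, function(sp) {
    d <- read.delim(file.path(config$outdir, "kinase",
                              paste0(sp, "_predictions.tsv")),
                    stringsAsFactors = FALSE)
    predictInteractions(d)
  })
  names(sp_int) <- config$species
  ints <- interactionConservation(predictInteractions(qp), maps, sp_int)
  .writeTsv(ints, file.path(out, "interactions.tsv"))
  ann <- .readAnnotationSets(config)
  labels <- interactionKey(ints$kinase, ints$protein_id) %in%
    ann$known_interactions
  summ <- list(n_interactions = nrow(ints),
               min_network_degree = config$min_network_degree)
  if (any(labels) && !all(labels)) {
    roc <- rankInteractionsROC(ints, labels)
    summ$aroc_known_interactions <- roc$aroc
    .writeTsv(roc$curve, file.path(out, "roc_curve.tsv"))
  }
  folds <- list()
  for (nm in names(ann)) {
    keys <- if (nm == "known_interactions")
      interactionKey(ints$kinase, ints$protein_id) else ints$protein_id
    ok <- length(ann[[nm]]) > 0 && any(keys %in% ann[[nm]]) &&
      any(ints$n_cons >= config$min_network_degree)
    folds[[nm]] <- if (ok)
      enrichmentFold(ints, ann[[nm]], config$min_network_degree,
                     by = if (nm == "known_interactions") "interaction"
                          else "protein")
    else NA_real_
  }
  summ$enrichment_folds <- folds
  net <- exportNetwork(ints, ann, min_degree = config$min_network_degree,
                       path = file.path(out, "network"))
  summ$n_network_edges <- nrow(net)
  .writeJson(summ, file.path(out, "summary.json"))
}

.stageStructure <- function(config) {
  out <- file.path(config$outdir, "structure")
  meta <- read.delim(file.path(config$bundle_dir, "model_meta.tsv"),
                     stringsAsFactors = FALSE)
  model_dir <- file.path(config$bundle_dir, "models")
  rsa <- do.call(rbind, lapply(list.files(model_dir, pattern = "\\.rsa$",
                                          full.names = TRUE), function(f) {
    d <- readRSAFile(f)
    d$protein_id <- meta$protein_id[match(d$model_id[1], meta$model_id)]
    d
  }))
  ps <- .readCompiledSites(config)
  acc <- siteAccessibility(ps, rsa, meta, threshold = config$rsa_threshold)
  .writeTsv(acc, file.path(out, "accessibility.tsv"))
  classes <- list(phosphosite = siteKeys(ps))
  prof_path <- file.path(config$outdir, "conservation", "profiles.tsv")
  if (file.exists(prof_path)) {
    prof <- read.delim(prof_path, stringsAsFactors = FALSE)
    classes$conserved_phosphosite <-
      siteKey(prof$protein_id, prof$position)[prof$degree >= 1]
  }
  disorder <- .readDisorder(config)
  if (!is.null(disorder)) {
    st <- siteTable(ps)
    dis <- vapply(seq_len(nrow(st)), function(i) {
      trk <- disorder[[st$protein_id[i]]]
      !is.null(trk) && st$position[i] <= length(trk) &&
        trk[st$position[i]]
    }, logical(1))
    classes$disordered <- siteKey(st$protein_id, st$position)[dis]
    classes$ordered <- siteKey(st$protein_id, st$position)[!dis]
  }
  flex <- flexibilityAnalysis(rsa, meta, site_classes = classes)
  ks <- ksTwoSample(flex$deltas$phosphosite, flex$deltas$acceptor)
  .writeJson(list(
    n_sites_with_model = nrow(acc),
    fraction_low_accessibility = if (nrow(acc)) mean(acc$low_accessibility)
                                 else NA,
    rsa_correlation = flex$correlation,
    median_abs_delta = as.list(flex$medians),
    ks_phospho_vs_acceptor = ks), file.path(out, "summary.json"))
}

.stageReport <- function(config) {
  out <- file.path(config$outdir, "report")
  stages <- c("compile", "conservation", "kinase", "interactions",
              "structure")
  report <- lapply(stages, function(st)
    jsonlite::read_json(file.path(config$outdir, st, "summary.json")))
  names(report) <- stages
  .writeJson(report, file.path(out, "report.json"))
}
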