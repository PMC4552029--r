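# Solvent-accessibility analysis across comparative structure models:
# parsing per-residue RSA output, model acceptance, low-accessibility
# classification, and cross-template flexibility statistics.

#' Read a per-residue relative-accessibility (.rsa) file
#'
#' Parses the per-residue records ("RES" lines) of the .rsa dialect:
#' residue name, chain, residue number, then absolute / relative
#' accessibility column pairs, the all-atom relative value being the
#' second numeric column. Malformed RES lines are collected in the
#' \code{"rejects"} attribute instead of aborting the parse.
#'
#' @param path .rsa file path.
#' @param model_id model identifier recorded per record; defaults to the
#'   file base name.
#' @return \code{data.frame} with columns \code{model_id}, \code{position},
#'   \code{residue} (one-letter), \code{rsa_all_atom}.
#' @export
readRSAFile <- function(path, model_id = NULL) {
  if (is.null(model_id)) model_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  res <- grep("^RES ", lines, value = TRUE)
  if (!length(res)) stop("no RES records in ", path, call. = FALSE)
  rows <- vector("list", length(res))
  rejects <- character()
  for (i in seq_along(res)) {
    tok <- strsplit(trimws(res[i]), "\\s+")[[1]]
    # RES <aa3> [chain] <resnum> <abs> <rel> ...
    k <- 3L
    if (length(tok) >= 3L && grepl("^[0-9]+$", tok[3])) k <- 2L  # no chain
    num <- suppressWarnings(as.integer(tok[k + 1L]))
    rel <- suppressWarnings(as.numeric(tok[k + 3L]))
    aa <- AA3TO1[toupper(tok[2])]
    if (length(tok) < k + 3L || is.na(num) || is.na(rel) || is.na(aa)) {
      rejects <- c(rejects, res[i])
      next
    }
    rows[[i]] <- data.frame(model_id = model_id, position = num,
                            residue = unname(aa), rsa_all_atom = rel,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no parsable RES records in ", path, call. = FALSE)
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Write per-residue RSA records in the .rsa dialect
#'
#' Emits RES lines compatible with [readRSAFile()]; used by the synthetic
#' fixture generator.
#'
#' @param df \code{data.frame} with \code{position}, \code{residue}
#'   (one-letter) and \code{rsa_all_atom} columns.
#' @param path output path.
#' @param chain chain identifier (default "A").
#' @return \code{path}, invisibly.
#' @export
writeRSAFile <- function(df, path, chain = "A") {
  aa3 <- AA1TO3[df$residue]
  aa3[is.na(aa3)] <- "UNK"
  lines <- sprintf("RES %s %s %4d  %7.2f %6.2f", aa3, chain,
                   as.integer(df$position),
                   df$rsa_all_atom * 1.2,  # nominal absolute column
                   df$rsa_all_atom)
  writeLines(c("REM Relative accessibilities read from synthetic generator",
               "REM RES _ NUM  All-atoms(ABS REL)", lines), path)
  invisible(path)
}

#' Comparative-model acceptance rule
#'
#' A model is acceptable when its template sequence identity is at least
#' 25\% and it meets at least one quality criterion: TSVMod NO35 >= 40\%,
#' GA341 >= 0.7, E-value < 0.0001, or zDOPE < 0. Absent criterion fields
#' count as not satisfied.
#'
#' @param meta \code{data.frame} of model metadata with columns
#'   \code{template_identity} and (optionally \code{NA}) \code{no35},
#'   \code{ga341}, \code{evalue}, \code{zdope}.
#' @return logical vector, one per row.
#' @export
acceptModel <- function(meta) {
  get0 <- function(nm) if (is.null(meta[[nm]])) rep(NA_real_, nrow(meta))
                       else meta[[nm]]
  crit <- function(x) !is.na(x)
  no35 <- get0("no35"); ga341 <- get0("ga341")
  evalue <- get0("evalue"); zdope <- get0("zdope")
  ident_ok <- !is.na(meta$template_identity) & meta$template_identity >= 25
  quality <- (crit(no35) & no35 >= 40) |
    (crit(ga341) & ga341 >= 0.7) |
    (crit(evalue) & evalue < 0.0001) |
    (crit(zdope) & zdope < 0)
  ident_ok & quality
}

#' Select the largest model covering a site
#'
#' When several accepted models cover the same phosphosite-containing
#' region the largest model (most covered residues) is used; ties go to
#' the lowest zDOPE, then to the lexicographically smallest model id.
#'
#' @param meta \code{data.frame} of accepted models covering the site, with
#'   columns \code{model_id}, \code{coverage_start}, \code{coverage_end}
#'   and optionally \code{zdope}.
#' @return the selected row of \code{meta}.
#' @export
selectLargestModel <- function(meta) {
  if (!nrow(meta)) stop("no model covers the site", call. = FALSE)
  size <- meta$coverage_end - meta$coverage_start + 1L
  zd <- if (is.null(meta$zdope)) rep(Inf, nrow(meta)) else
    ifelse(is.na(meta$zdope), Inf, meta$zdope)
  ord <- order(-size, zd, meta$model_id)
  meta[ord[1], , drop = FALSE]
}

#' Low-accessibility classification
#'
#' A residue is solvent-inaccessible when its all-atom relative surface
#' accessibility is strictly below the threshold (default 20\%).
#'
#' @param rsa numeric RSA percent value(s), >= 0.
#' @param threshold percent threshold (default 20; strict \code{<}).
#' @return logical vector.
#' @export
classifyLowAccessibility <- function(rsa, threshold = 20) {
  stopifnot(all(rsa >= 0))
  rsa < threshold
}

#' Per-phosphosite accessibility across accepted models
#'
#' For each site, collects its RSA in every accepted model covering it,
#' applies the largest-model rule to pick the representative value, and
#' flags low accessibility on that value.
#'
#' @param sites site \code{data.frame} (or [PhosphoSet-class]) with
#'   \code{protein_id}, \code{position}.
#' @param rsa long \code{data.frame} of per-residue RSA (columns
#'   \code{model_id}, \code{protein_id}, \code{position},
#'   \code{rsa_all_atom}).
#' @param meta model metadata with \code{model_id}, \code{protein_id},
#'   \code{template_identity}, \code{coverage_start}, \code{coverage_end}
#'   and quality columns (see [acceptModel()]).
#' @param threshold low-accessibility RSA threshold (default 20).
#' @return \code{data.frame}: one row per site covered by at least one
#'   accepted model, with \code{selected_model}, \code{rsa},
#'   \code{low_accessibility}, \code{n_models}.
#' @export
siteAccessibility <- function(sites, rsa, meta, threshold = 20) {
  if (is(sites, "PhosphoSet")) sites <- siteTable(sites)
  meta <- meta[acceptModel(meta), , drop = FALSE]
  out <- lapply(seq_len(nrow(sites)), function(i) {
    pid <- sites$protein_id[i]; pos <- sites$position[i]
    mm <- meta[meta$protein_id == pid & meta$coverage_start <= pos &
                 meta$coverage_end >= pos, , drop = FALSE]
    rr <- rsa[rsa$protein_id == pid & rsa$position == pos &
                rsa$model_id %in% mm$model_id, , drop = FALSE]
    mm <- mm[mm$model_id %in% rr$model_id, , drop = FALSE]
    if (!nrow(mm)) return(NULL)
    sel <- selectLargestModel(mm)
    val <- rr$rsa_all_atom[match(sel$model_id, rr$model_id)]
    data.frame(protein_id = pid, position = pos,
               selected_model = sel$model_id, rsa = val,
               low_accessibility = classifyLowAccessibility(val, threshold),
               n_models = nrow(mm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(protein_id = character(), position = integer(),
                      selected_model = character(), rsa = numeric(),
                      low_accessibility = logical(), n_models = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cross-template accessibility variability of phospho-acceptor residues
#'
#' For every protein with at least two accepted models and every unordered
#' model pair, pairs the RSA values of all shared serine/threonine/tyrosine
#' residues and records the absolute difference |dRSA|. Residue classes
#' (e.g. plain acceptor background, phosphosite, conserved phosphosite,
#' ordered/disordered) are scored on the pooled |dRSA| observations; a
#' residue may belong to several classes. Also reports the Pearson
#' correlation of the paired RSA values — high overall correlation with a
#' heavy |dRSA| tail for phosphosites is the signature of sites in
#' conformationally flexible positions.
#'
#' @param rsa long per-residue RSA \code{data.frame} (\code{model_id},
#'   \code{protein_id}, \code{position}, \code{residue},
#'   \code{rsa_all_atom}).
#' @param meta model metadata (see [acceptModel()]); only accepted models
#'   enter the analysis.
#' @param site_classes named list: class label -> character vector of site
#'   keys (\code{"protein:position"}). The class \code{"acceptor"} (all
#'   shared S/T/Y residues) is always included.
#' @param summary \code{"pool"} (default) pools |dRSA| over all model
#'   pairs; \code{"max"} keeps one observation per residue, its maximum
#'   |dRSA| over pairs.
#' @return list with \code{pairs} (per-observation \code{data.frame}),
#'   \code{correlation} (Pearson r over all paired values),
#'   \code{deltas} (named list of |dRSA| vectors per class) and
#'   \code{medians} (named numeric).
#' @export
flexibilityAnalysis <- function(rsa, meta, site_classes = list(),
                                summary = c("pool", "max")) {
  summary <- match.arg(summary)
  meta <- meta[acceptModel(meta), , drop = FALSE]
  rsa <- rsa[rsa$model_id %in% meta$model_id, , drop = FALSE]
  rsa <- rsa[rsa$residue %in% ACCEPTORS, , drop = FALSE]
  obs <- list()
  for (pid in unique(rsa$protein_id)) {
    sub <- rsa[rsa$protein_id == pid, , drop = FALSE]
    models <- sort(unique(sub$model_id))
    if (length(models) < 2L) next
    by_model <- split(sub, sub$model_id)
    for (a in seq_len(length(models) - 1L)) {
      for (b in seq((a + 1L), length(models))) {
        ma <- by_model[[models[a]]]; mb <- by_model[[models[b]]]
        shared <- intersect(ma$position, mb$position)
        if (!length(shared)) next
        ia <- match(shared, ma$position); ib <- match(shared, mb$position)
        obs[[length(obs) + 1L]] <- data.frame(
          protein_id = pid, position = shared,
          residue = ma$residue[ia],
          model_a = models[a], model_b = models[b],
          rsa_a = ma$rsa_all_atom[ia], rsa_b = mb$rsa_all_atom[ib],
          delta = abs(ma$rsa_all_atom[ia] - mb$rsa_all_atom[ib]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(obs))
    stop("no protein has >= 2 accepted models sharing an S/T/Y residue",
         call. = FALSE)
  pairs <- do.call(rbind, obs)
  rownames(pairs) <- NULL
  r <- stats::cor(pairs$rsa_a, pairs$rsa_b, method = "pearson")

  keyed <- siteKey(pairs$protein_id, pairs$position)
  classes <- c(list(acceptor = unique(keyed)), site_classes)
  deltas <- lapply(classes, function(keys) {
    sel <- pairs[keyed %in% keys, , drop = FALSE]
    if (summary == "pool") sel$delta
    else as.numeric(tapply(sel$delta,
                           siteKey(sel$protein_id, sel$position), max))
  })
  list(pairs = pairs, correlation = r, deltas = deltas,
       medians = vapply(deltas, function(d)
         if (length(d)) median(d) else NA_real_, numeric(1)))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' is asymptotic by default with an exact small-sample option.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact logical or \code{NULL} (let [stats::ks.test()] decide).
#' @return list with \code{D} and \code{p.value}.
#' @export
ksTwoSample <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(D = unname(kt$statistic), p.value = kt$p.value)
}
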