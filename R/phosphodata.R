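# Phosphosite dataset ingestion, compilation and confidence filtering.

#' Read a phosphosite table
#'
#' Parses a TSV of phosphosites (one row per site observation). Column names
#' are resolved through a `dialect` map so tables from different sources can
#' be read without renaming. Rows whose residue is not a phospho-acceptor
#' (S/T/Y) or whose position does not parse as a positive integer are
#' excluded and reported, not fatal.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect named character vector mapping the canonical field names
#'   \code{protein}, \code{position}, \code{residue} (required) and
#'   \code{slip}, \code{evalue}, \code{ambiguous} (optional) to the column
#'   names used in the file.
#' @param source_label dataset label recorded in the \code{sources} field of
#'   every accepted row; defaults to the file base name.
#' @return list with \code{sites} (a site \code{data.frame} as used by
#'   [PhosphoSet()]) and \code{rejects} (a \code{data.frame} of excluded rows
#'   with a \code{reason} column).
#' @export
readPhosphositeTable <- function(path,
                                 dialect = c(protein = "protein",
                                             position = "position",
                                             residue = "residue",
                                             slip = "slip_score",
                                             evalue = "evalue",
                                             ambiguous = "ambiguous"),
                                 source_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(source_label))
    source_label <- sub("\\.[^.]*$", "", basename(path))
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lookup <- function(field)
    if (field %in% names(dialect)) dialect[[field]] else NA_character_
  for (field in c("protein", "position", "residue")) {
    col <- lookup(field)
    if (is.na(col) || !col %in% names(raw))
      stop("required column for '", field, "' (", col,
           ") not found in ", path, call. = FALSE)
  }
  getcol <- function(field) {
    col <- lookup(field)
    if (!is.na(col) && col %in% names(raw)) raw[[col]] else NULL
  }
  protein <- as.character(getcol("protein"))
  pos_raw <- getcol("position")
  residue <- toupper(as.character(getcol("residue")))
  position <- suppressWarnings(as.integer(pos_raw))

  bad_pos <- is.na(position) | position < 1L
  bad_res <- !residue %in% ACCEPTORS
  reason <- rep(NA_character_, nrow(raw))
  reason[bad_res] <- "residue not in {S,T,Y}"
  reason[bad_pos] <- ifelse(is.na(reason[bad_pos]), "unparsable position",
                            paste(reason[bad_pos], "+ unparsable position"))
  keep <- !(bad_pos | bad_res)

  slip <- getcol("slip")
  evalue <- getcol("evalue")
  ambiguous <- getcol("ambiguous")
  sites <- data.frame(
    protein_id = protein[keep],
    position = position[keep],
    residue = residue[keep],
    slip_score = if (is.null(slip)) NA_real_
                 else suppressWarnings(as.numeric(slip[keep])),
    evalue = if (is.null(evalue)) NA_real_
             else suppressWarnings(as.numeric(evalue[keep])),
    ambiguous = if (is.null(ambiguous)) FALSE
                else as.logical(ambiguous[keep]),
    sources = source_label,
    stringsAsFactors = FALSE
  )
  rejects <- cbind(raw[!keep, , drop = FALSE],
                   reason = reason[!keep])
  rownames(rejects) <- NULL
  list(sites = sites, rejects = rejects)
}

#' Compile a non-redundant phosphosite set from several datasets
#'
#' Merges site lists from multiple datasets into one [PhosphoSet-class],
#' deduplicating on the \code{(protein_id, position)} key. When the same
#' site occurs in several datasets the merged record keeps the maximum SLIP
#' score, the minimum expectation value, the union of source labels, and is
#' flagged ambiguous only if every contributing record was. The operation is
#' idempotent and independent of dataset order.
#'
#' Two records that disagree on the residue letter at the same key indicate
#' corrupt inputs and raise an error listing the offenders.
#'
#' @param datasets named list of site \code{data.frame}s (as produced by
#'   [readPhosphositeTable()]); names are used as dataset labels when a
#'   record has no \code{sources} field.
#' @param species species label for the compilation.
#' @return a [PhosphoSet-class].
#' @export
compileNonredundant <- function(datasets, species = NA_character_) {
  stopifnot(is.list(datasets))
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  all <- do.call(rbind, lapply(names(datasets), function(label) {
    d <- datasets[[label]]
    if (is(d, "PhosphoSet")) d <- siteTable(d)
    d <- as.data.frame(d, stringsAsFactors = FALSE)
    if (!nrow(d)) return(NULL)
    if (is.null(d$sources) || all(is.na(d$sources))) d$sources <- label
    if (is.null(d$slip_score)) d$slip_score <- NA_real_
    if (is.null(d$evalue)) d$evalue <- NA_real_
    if (is.null(d$ambiguous)) d$ambiguous <- FALSE
    d[c("protein_id", "position", "residue", "slip_score", "evalue",
        "ambiguous", "sources")]
  }))
  if (is.null(all) || !nrow(all))
    return(PhosphoSet(data.frame(), species = species,
                      provenance = integer()))
  all$position <- as.integer(all$position)
  key <- siteKey(all$protein_id, all$position)

  residues_per_key <- tapply(all$residue, key, function(r) length(unique(r)))
  if (any(residues_per_key > 1L)) {
    bad <- names(residues_per_key)[residues_per_key > 1L]
    stop("conflicting residue letters at site(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  ord <- order(all$protein_id, all$position)
  all <- all[ord, ]
  key <- key[ord]
  idx <- split(seq_len(nrow(all)), factor(key, levels = unique(key)))
  merged <- do.call(rbind, lapply(idx, function(i) {
    slip <- all$slip_score[i]
    ev <- all$evalue[i]
    srcs <- sort(unique(unlist(strsplit(all$sources[i], ";", fixed = TRUE))))
    data.frame(
      protein_id = all$protein_id[i[1]],
      position = all$position[i[1]],
      residue = all$residue[i[1]],
      slip_score = if (all(is.na(slip))) NA_real_ else max(slip, na.rm = TRUE),
      evalue = if (all(is.na(ev))) NA_real_ else min(ev, na.rm = TRUE),
      ambiguous = all(all$ambiguous[i]),
      sources = paste(srcs, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(merged) <- NULL
  prov <- vapply(names(datasets), function(label) {
    d <- datasets[[label]]
    if (is(d, "PhosphoSet")) d <- siteTable(d)
    nrow(as.data.frame(d))
  }, integer(1))
  PhosphoSet(merged, species = species, provenance = prov)
}

#' Filter to high-confidence, well-localized phosphosites
#'
#' Retains sites with expectation value strictly below \code{evalue_max} and
#' SLIP localization score at least \code{slip_min} (inclusive). Sites
#' lacking either score are dropped: the confidence filter presupposes both
#' scores, so an unscored site cannot pass it.
#'
#' @param x a [PhosphoSet-class].
#' @param evalue_max expectation-value bound (strict \code{<}); default 0.001.
#' @param slip_min minimum SLIP score (inclusive \code{>=}); default 3.
#' @return a filtered [PhosphoSet-class] (subset of the input).
#' @export
filterHighConfidence <- function(x, evalue_max = 0.001, slip_min = 3) {
  s <- siteTable(x)
  keep <- !is.na(s$evalue) & !is.na(s$slip_score) &
    s$evalue < evalue_max & s$slip_score >= slip_min
  PhosphoSet(s[keep, , drop = FALSE], species = x@species,
             provenance = x@provenance)
}

#' Residue composition of a phosphosite set
#'
#' Counts phospho-serines, -threonines and -tyrosines and reports each as a
#' whole-number percent of the total (truncated, so the conventional
#' "78\%/17\%/4\%"-style breakdown is reproduced).
#'
#' @param x a [PhosphoSet-class].
#' @return \code{data.frame} with columns \code{residue}, \code{count},
#'   \code{percent}; one row per acceptor residue (S, T, Y).
#' @export
residueComposition <- function(x) {
  s <- siteTable(x)
  counts <- table(factor(s$residue, levels = ACCEPTORS))
  total <- sum(counts)
  pct <- if (total == 0) rep(0, length(counts)) else
    floor(100 * as.numeric(counts) / total)
  data.frame(residue = ACCEPTORS, count = as.integer(counts),
             percent = as.numeric(pct), stringsAsFactors = FALSE)
}

#' Estimate the well-localized fraction from SLIP-score bins
#'
#' Given bins of sites grouped by SLIP score, each with a local false
#' localization rate (FLR) from benchmark data, estimates the overall
#' fraction of sites that are correctly localized as the count-weighted
#' mean of \eqn{1 - \mathrm{FLR}}:
#' \deqn{\hat{p} = \sum_i n_i (1 - \mathrm{FLR}_i) / \sum_i n_i.}
#'
#' @param bins \code{data.frame} with columns \code{count} (non-negative
#'   integers) and \code{local_flr} (fractions in [0, 1]); an optional
#'   \code{label} column is ignored.
#' @return estimated well-localized fraction in [0, 1].
#' @export
estimateLocalizationRate <- function(bins) {
  stopifnot(is.data.frame(bins), all(c("count", "local_flr") %in% names(bins)))
  if (any(bins$count < 0)) stop("bin counts must be non-negative", call. = FALSE)
  if (any(bins$local_flr < 0 | bins$local_flr > 1))
    stop("local FLR values must lie in [0, 1]", call. = FALSE)
  n <- sum(bins$count)
  if (n == 0) stop("all bin counts are zero; estimate undefined", call. = FALSE)
  sum(bins$count * (1 - bins$local_flr)) / n
}
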