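#' PhosphoSet: a non-redundant compilation of phosphosites for one species
#'
#' Container for a set of experimentally observed phosphorylation sites on a
#' single proteome namespace. Each site is one modified serine, threonine or
#' tyrosine, keyed by \code{(protein_id, position)}; the key is unique within
#' a set. Confidence scores (SLIP localization score, search-engine
#' expectation value) and dataset provenance are carried per site.
#'
#' @slot species single species label.
#' @slot sites \code{data.frame} with columns \code{protein_id} (character),
#'   \code{position} (integer, 1-based), \code{residue} (one of S/T/Y),
#'   \code{slip_score} (numeric, \code{NA} when unscored), \code{evalue}
#'   (numeric, \code{NA} when unscored), \code{ambiguous} (logical: site came
#'   from a peptide with more than one candidate acceptor), \code{sources}
#'   (character, \code{";"}-separated dataset labels).
#' @slot provenance named integer vector, dataset label to record count.
#'
#' @seealso [compileNonredundant()], [filterHighConfidence()],
#'   [residueComposition()]
#' @export
setClass("PhosphoSet",
  representation(
    species = "character",
    sites = "data.frame",
    provenance = "integer"
  ),
  prototype(
    species = NA_character_,
    sites = data.frame(
      protein_id = character(), position = integer(), residue = character(),
      slip_score = numeric(), evalue = numeric(), ambiguous = logical(),
      sources = character(), stringsAsFactors = FALSE
    ),
    provenance = integer()
  )
)

setValidity("PhosphoSet", function(object) {
  s <- object@sites
  msgs <- character()
  need <- c("protein_id", "position", "residue", "slip_score", "evalue",
            "ambiguous", "sources")
  if (!all(need %in% names(s)))
    return(paste("sites must have columns:", paste(need, collapse = ", ")))
  if (nrow(s)) {
    if (any(!s$residue %in% ACCEPTORS))
      msgs <- c(msgs, "residue must be one of S, T, Y")
    if (any(s$position < 1L))
      msgs <- c(msgs, "positions must be >= 1")
    keys <- siteKey(s$protein_id, s$position)
    if (anyDuplicated(keys))
      msgs <- c(msgs, "duplicate (protein_id, position) keys")
    if (any(!nzchar(s$sources)))
      msgs <- c(msgs, "every site must have a non-empty source set")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a PhosphoSet
#'
#' @param sites site \code{data.frame}; see the class documentation for the
#'   required columns. Missing score columns are filled with \code{NA},
#'   a missing \code{ambiguous} column with \code{FALSE}.
#' @param species species label.
#' @param provenance named integer vector of per-dataset record counts;
#'   computed from \code{sources} when omitted.
#' @return A [PhosphoSet-class] object.
#' @export
PhosphoSet <- function(sites, species = NA_character_, provenance = NULL) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (!nrow(sites) && !length(sites)) {
    sites <- new("PhosphoSet")@sites
  }
  if (is.null(sites$slip_score)) sites$slip_score <- NA_real_
  if (is.null(sites$evalue)) sites$evalue <- NA_real_
  if (is.null(sites$ambiguous)) sites$ambiguous <- FALSE
  if (is.null(sites$sources)) sites$sources <- "unspecified"
  sites$position <- as.integer(sites$position)
  sites$slip_score <- as.numeric(sites$slip_score)
  sites$evalue <- as.numeric(sites$evalue)
  rownames(sites) <- NULL
  if (is.null(provenance)) {
    labels <- unlist(strsplit(sites$sources, ";", fixed = TRUE))
    provenance <- if (length(labels)) table(labels) else integer()
    provenance <- setNames(as.integer(provenance), names(provenance))
  }
  new("PhosphoSet", species = species,
      sites = sites[c("protein_id", "position", "residue", "slip_score",
                      "evalue", "ambiguous", "sources")],
      provenance = provenance)
}

#' @describeIn PhosphoSet-class number of sites in the set.
#' @param x a \code{PhosphoSet}.
#' @export
setMethod("length", "PhosphoSet", function(x) nrow(x@sites))

setMethod("show", "PhosphoSet", function(object) {
  cat("PhosphoSet (", object@species, "): ", nrow(object@sites),
      " sites on ", length(unique(object@sites$protein_id)),
      " proteins\n", sep = "")
  if (length(object@provenance)) {
    cat("  provenance:",
        paste(names(object@provenance), object@provenance,
              sep = "=", collapse = ", "), "\n")
  }
  comp <- table(factor(object@sites$residue, levels = ACCEPTORS))
  cat("  residues: S=", comp[["S"]], " T=", comp[["T"]],
      " Y=", comp[["Y"]], "\n", sep = "")
})

#' Site table accessor
#'
#' @param x a [PhosphoSet-class].
#' @return The underlying site \code{data.frame}.
#' @export
siteTable <- function(x) {
  stopifnot(is(x, "PhosphoSet"))
  x@sites
}

#' Species label accessor
#' @param x a [PhosphoSet-class] or [OrthologMap-class].
#' @return species label (character).
#' @export
speciesLabel <- function(x) x@species

#' Canonical site keys
#'
#' @param x a [PhosphoSet-class].
#' @return character vector \code{"<protein>:<position>"}, one per site.
#' @export
siteKeys <- function(x) {
  s <- siteTable(x)
  siteKey(s$protein_id, s$position)
}

#' OrthologMap: reciprocal-best-hit orthologs against one target species
#'
#' A partial bijection from query proteins to target-species proteins
#' together with the stored global alignment of each pair, used downstream
#' to map phosphosite positions between the two proteomes.
#'
#' @slot species target species label.
#' @slot pairs \code{data.frame} with columns \code{query_id},
#'   \code{target_id}, \code{score} (local alignment score that supported the
#'   reciprocal best hit).
#' @slot alignments named list (by \code{query_id}); each element a list with
#'   \code{aligned_query}, \code{aligned_target} (equal-length gapped
#'   strings) and \code{score} (global alignment score).
#' @seealso [reciprocalBestHits()], [mapAlignedPosition()]
#' @export
setClass("OrthologMap",
  representation(species = "character", pairs = "data.frame",
                 alignments = "list"),
  prototype(species = NA_character_,
            pairs = data.frame(query_id = character(),
                               target_id = character(),
                               score = numeric(), stringsAsFactors = FALSE),
            alignments = list())
)

setValidity("OrthologMap", function(object) {
  p <- object@pairs
  msgs <- character()
  if (anyDuplicated(p$query_id))
    msgs <- c(msgs, "query ids must be unique (partial bijection)")
  if (anyDuplicated(p$target_id))
    msgs <- c(msgs, "target ids must be unique (partial bijection)")
  if (!setequal(names(object@alignments), p$query_id))
    msgs <- c(msgs, "alignments must be keyed by exactly the query ids")
  for (q in names(object@alignments)) {
    al <- object@alignments[[q]]
    if (nchar(al$aligned_query) != nchar(al$aligned_target)) {
      msgs <- c(msgs, paste0("alignment for ", q, " has unequal lengths"))
      break
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "OrthologMap", function(object) {
  cat("OrthologMap to ", object@species, ": ", nrow(object@pairs),
      " reciprocal best-hit pairs\n", sep = "")
})

#' @describeIn OrthologMap-class number of ortholog pairs.
#' @param x an \code{OrthologMap}.
#' @export
setMethod("length", "OrthologMap", function(x) nrow(x@pairs))

#' Ortholog pair table accessor
#' @param x an [OrthologMap-class].
#' @return \code{data.frame} of (query_id, target_id, score).
#' @export
orthologPairs <- function(x) {
  stopifnot(is(x, "OrthologMap"))
  x@pairs
}

#' Look up the ortholog of a query protein
#' @param x an [OrthologMap-class].
#' @param query_id query protein id.
#' @return target protein id, or \code{NA} if the query has no ortholog.
#' @export
orthologOf <- function(x, query_id) {
  i <- match(query_id, x@pairs$query_id)
  if (is.na(i)) NA_character_ else x@pairs$target_id[i]
}

#' Stored query-ortholog alignment accessor
#' @param x an [OrthologMap-class].
#' @param query_id query protein id.
#' @return list with \code{aligned_query}, \code{aligned_target},
#'   \code{score}, or \code{NULL} when the query has no ortholog.
#' @export
orthologAlignment <- function(x, query_id) {
  x@alignments[[query_id]]
}

#' KinasePSSM: kinase specificity model with Matrix Similarity Score support
#'
#' Position-specific scoring matrix describing a kinase's sequence
#' preference in a window around the phospho-acceptor. Frequencies are held
#' for every flanking position \code{-w..-1, +1..+w} (the constant acceptor
#' position is excluded) over the 20 standard residues. The per-position
#' information weight is \eqn{I(i) = \sum_b f(i,b)\,\ln(20 f(i,b))}
#' (natural log, 20-letter uniform background), and the score bounds
#' \eqn{\sum_i I(i) \min_b f(i,b)} and \eqn{\sum_i I(i) \max_b f(i,b)}
#' min-max-normalize the Matrix Similarity Score into [0, 1].
#'
#' @slot kinase kinase name.
#' @slot w window half-width (model covers a \code{2w+1}-mer).
#' @slot freq 20 x 2w matrix of residue frequencies; rows named by residue,
#'   columns by signed position ("-w"... "-1", "1"..."w"); columns sum to 1.
#' @slot info per-position information weights (length 2w, non-negative).
#' @slot scoreMin,scoreMax Matrix Similarity Score normalization bounds.
#' @slot cutoff calibrated MSS decision threshold (\code{NA} until set).
#' @seealso [buildPSSM()], [mssScore()], [calibrateCutoff()]
#' @export
setClass("KinasePSSM",
  representation(kinase = "character", w = "integer", freq = "matrix",
                 info = "numeric", scoreMin = "numeric", scoreMax = "numeric",
                 cutoff = "numeric")
)

setValidity("KinasePSSM", function(object) {
  msgs <- character()
  f <- object@freq
  if (!identical(rownames(f), AA20))
    msgs <- c(msgs, "freq rows must be the 20 standard residues")
  if (ncol(f) != 2L * object@w)
    msgs <- c(msgs, "freq must have 2w columns (acceptor position excluded)")
  csum <- colSums(f)
  if (any(abs(csum - 1) > 1e-9))
    msgs <- c(msgs, "freq columns must each sum to 1")
  if (any(object@info < -1e-12))
    msgs <- c(msgs, "information weights must be non-negative")
  if (object@scoreMin > object@scoreMax + 1e-12)
    msgs <- c(msgs, "scoreMin must not exceed scoreMax")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "KinasePSSM", function(object) {
  cat("KinasePSSM ", object@kinase, ": ", 2L * object@w + 1L,
      "-mer window, cutoff ",
      if (is.na(object@cutoff)) "unset" else format(object@cutoff),
      "\n", sep = "")
  top <- apply(object@freq, 2, function(col) rownames(object@freq)[which.max(col)])
  cat("  consensus flank: ", paste(top, collapse = ""), "\n", sep = "")
})

#' MSS cutoff accessor
#' @param x a [KinasePSSM-class].
#' @return the calibrated cutoff (may be \code{NA}).
#' @export
pssmCutoff <- function(x) x@cutoff

#' Set the MSS cutoff
#' @param x a [KinasePSSM-class].
#' @param value new cutoff in [0, 1].
#' @return the updated model.
#' @export
`pssmCutoff<-` <- function(x, value) {
  x@cutoff <- as.numeric(value)
  validObject(x)
  x
}
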