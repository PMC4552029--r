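# Reciprocal-best-hit orthology over exact affine-gap pairwise alignment.
#
# Local alignment scores drive the hit search (as a deterministic stand-in
# for a heuristic search), and the stored per-pair alignment used for
# position mapping is global.

#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject
#'   AAString AAStringSet readAAStringSet writeXStringSet
#' @importFrom BiocGenerics score width
NULL

.substMatrix <- function(name) {
  ok <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
          "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!name %in% ok)
    stop("unknown substitution matrix: ", name, call. = FALSE)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Optimal pairwise alignment of two protein sequences
#'
#' Computes the optimal affine-gap alignment (global Needleman-Wunsch or
#' local Smith-Waterman) under a standard substitution matrix. A gap of
#' length L costs \code{gap_open + L * gap_extend}.
#'
#' @param query,target protein sequences as single character strings (or
#'   length-1 \code{AAString}s).
#' @param mode \code{"global"} or \code{"local"}.
#' @param substitution_matrix name of a standard matrix (default
#'   \code{"BLOSUM62"}).
#' @param gap_open,gap_extend affine gap penalties (positive costs);
#'   defaults 11 and 1.
#' @param query_id,target_id optional sequence ids carried into the result.
#' @return list with \code{query_id}, \code{target_id}, \code{aligned_query},
#'   \code{aligned_target} (equal-length gapped strings) and \code{score}.
#' @export
alignPair <- function(query, target, mode = c("global", "local"),
                      substitution_matrix = "BLOSUM62",
                      gap_open = 11, gap_extend = 1,
                      query_id = NA_character_, target_id = NA_character_) {
  mode <- match.arg(mode)
  query <- as.character(query); target <- as.character(target)
  if (!nzchar(query) || !nzchar(target))
    stop("sequences must be non-empty", call. = FALSE)
  mat <- .substMatrix(substitution_matrix)
  pa <- pairwiseAlignment(AAString(query), AAString(target),
                          type = mode, substitutionMatrix = mat,
                          gapOpening = gap_open, gapExtension = gap_extend)
  list(query_id = query_id, target_id = target_id,
       aligned_query = as.character(alignedPattern(pa)),
       aligned_target = as.character(alignedSubject(pa)),
       score = score(pa))
}

# Local-alignment score matrix: queries in rows, targets in columns.
# pairwiseAlignment vectorizes over patterns, so loop over targets only.
.scoreMatrix <- function(queries, targets, substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  mat <- .substMatrix(substitution_matrix)
  out <- matrix(NA_real_, nrow = length(queries), ncol = length(targets),
                dimnames = list(names(queries), names(targets)))
  qset <- AAStringSet(queries)
  for (j in seq_along(targets)) {
    out[, j] <- pairwiseAlignment(qset, AAString(as.character(targets[[j]])),
                                  type = "local", substitutionMatrix = mat,
                                  gapOpening = gap_open,
                                  gapExtension = gap_extend,
                                  scoreOnly = TRUE)
  }
  out
}

.bestFromScores <- function(scores, min_score) {
  # per row: best column >= min_score, ties to lexicographically smallest id
  hits <- character(0)
  ids <- colnames(scores)
  for (i in seq_len(nrow(scores))) {
    best <- max(scores[i, ])
    if (best >= min_score) {
      cand <- sort(ids[scores[i, ] == best])
      hits[rownames(scores)[i]] <- cand[1]
    }
  }
  hits
}

#' Best hit per query protein
#'
#' For each query protein, finds the target protein with maximal local
#' alignment score, provided that score reaches \code{min_score}. Ties are
#' broken deterministically toward the lexicographically smallest target id.
#' Queries with no qualifying hit are absent from the result.
#'
#' @param query_proteome,target_proteome named character vectors or
#'   \code{AAStringSet}s of protein sequences.
#' @param min_score minimum local alignment score for a hit (default 50).
#' @inheritParams alignPair
#' @return named character vector: query id -> best target id.
#' @export
bestHits <- function(query_proteome, target_proteome, min_score = 50,
                     substitution_matrix = "BLOSUM62",
                     gap_open = 11, gap_extend = 1) {
  q <- setNames(as.character(query_proteome), names(query_proteome))
  t <- setNames(as.character(target_proteome), names(target_proteome))
  stopifnot(length(q) > 0, length(t) > 0)
  sc <- .scoreMatrix(q, t, substitution_matrix, gap_open, gap_extend)
  .bestFromScores(sc, min_score)
}

#' Reciprocal best-hit ortholog prediction
#'
#' Predicts one-to-one orthologs between a query and a target proteome: a
#' pair (q, t) is kept iff t is q's best hit and q is t's best hit. Because
#' the local-alignment score is symmetric under a symmetric substitution
#' matrix, the all-vs-all score matrix is computed once and reused for both
#' directions. For every kept pair the global query-target alignment is
#' computed and stored for downstream position mapping.
#'
#' @inheritParams bestHits
#' @param species target species label recorded in the result.
#' @return an [OrthologMap-class].
#' @export
reciprocalBestHits <- function(query_proteome, target_proteome,
                               min_score = 50, species = NA_character_,
                               substitution_matrix = "BLOSUM62",
                               gap_open = 11, gap_extend = 1) {
  q <- setNames(as.character(query_proteome), names(query_proteome))
  t <- setNames(as.character(target_proteome), names(target_proteome))
  stopifnot(length(q) > 0, length(t) > 0)
  if (is.null(names(q)) || is.null(names(t)))
    stop("proteomes must be named", call. = FALSE)
  sc <- .scoreMatrix(q, t, substitution_matrix, gap_open, gap_extend)
  fwd <- .bestFromScores(sc, min_score)
  rev <- .bestFromScores(t(sc), min_score)
  keep_q <- names(fwd)[!is.na(rev[fwd]) & rev[fwd] == names(fwd)]
  keep_q <- sort(keep_q)
  pairs <- data.frame(query_id = keep_q,
                      target_id = unname(fwd[keep_q]),
                      score = vapply(keep_q,
                                     function(qq) sc[qq, fwd[[qq]]],
                                     numeric(1)),
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  alignments <- lapply(keep_q, function(qq) {
    al <- alignPair(q[[qq]], t[[fwd[[qq]]]], mode = "global",
                    substitution_matrix = substitution_matrix,
                    gap_open = gap_open, gap_extend = gap_extend,
                    query_id = qq, target_id = fwd[[qq]])
    al[c("aligned_query", "aligned_target", "score")]
  })
  names(alignments) <- keep_q
  new("OrthologMap", species = species, pairs = pairs,
      alignments = alignments)
}

#' Write an ortholog map to TSV
#'
#' Exports (species, query, target, score) rows; the stored alignments are
#' written alongside as two extra gapped-string columns so a map can be
#' round-tripped without recomputing alignments.
#'
#' @param x an [OrthologMap-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeOrthologMap <- function(x, path) {
  p <- orthologPairs(x)
  p$species <- x@species
  p$aligned_query <- vapply(p$query_id,
                            function(q) x@alignments[[q]]$aligned_query, "")
  p$aligned_target <- vapply(p$query_id,
                             function(q) x@alignments[[q]]$aligned_target, "")
  write.table(p[c("species", "query_id", "target_id", "score",
                  "aligned_query", "aligned_target")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog map written by [writeOrthologMap()]
#' @param path TSV path.
#' @return an [OrthologMap-class].
#' @export
readOrthologMap <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  alignments <- lapply(seq_len(nrow(d)), function(i) {
    list(aligned_query = d$aligned_query[i],
         aligned_target = d$aligned_target[i], score = d$score[i])
  })
  names(alignments) <- d$query_id
  new("OrthologMap",
      species = if (nrow(d)) d$species[1] else NA_character_,
      pairs = d[c("query_id", "target_id", "score")],
      alignments = alignments)
}
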