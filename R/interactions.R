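# Kinase-protein interaction prediction and cross-species conservation
# ranking. Conservation of an interaction is position-independent: an
# ortholog only needs *some* predicted target site of the same kinase.

#' Collapse predicted target sites into kinase-protein interactions
#'
#' A protein is predicted to be regulated by a kinase if at least one of
#' its phosphosites is a predicted target of that kinase.
#'
#' @param scored_sites \code{data.frame} of predicted target sites (rows
#'   from [predictTargetSites()], possibly concatenated across kinases).
#' @return \code{data.frame} with one row per (kinase, protein):
#'   \code{kinase}, \code{protein_id}, \code{n_sites},
#'   \code{supporting_sites} (\code{";"}-joined \code{pos(mss)} entries),
#'   \code{max_mss}, and \code{n_cons} (\code{NA} until
#'   [interactionConservation()] is applied).
#' @export
predictInteractions <- function(scored_sites) {
  empty <- data.frame(kinase = character(), protein_id = character(),
                      n_sites = integer(), supporting_sites = character(),
                      max_mss = numeric(), n_cons = integer(),
                      conserved_species = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(scored_sites)) return(empty)
  key <- paste(scored_sites$kinase, scored_sites$protein_id, sep = "\r")
  idx <- split(seq_len(nrow(scored_sites)),
               factor(key, levels = sort(unique(key))))
  out <- do.call(rbind, lapply(idx, function(i) {
    i <- i[order(scored_sites$position[i])]
    data.frame(
      kinase = scored_sites$kinase[i[1]],
      protein_id = scored_sites$protein_id[i[1]],
      n_sites = length(i),
      supporting_sites = paste0(scored_sites$position[i], "(",
                                round(scored_sites$mss[i], 4), ")",
                                collapse = ";"),
      max_mss = max(scored_sites$mss[i]),
      n_cons = NA_integer_,
      conserved_species = NA_character_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Score cross-species conservation of predicted interactions
#'
#' An interaction (kinase, protein) is conserved in a target species when
#' the protein has a reciprocal-best-hit ortholog there *and* that ortholog
#' is itself predicted to be regulated by the same kinase model. Site
#' positions are never compared — the regulatory relationship may survive
#' even when the phosphosite has moved within the protein. Species with an
#' ortholog but no phosphorylation data simply count as non-conserved,
#' which makes the degree a conservative (under-) estimate.
#'
#' @param interactions \code{data.frame} from [predictInteractions()]
#'   (query species).
#' @param maps named list of [OrthologMap-class] per target species.
#' @param per_species_interactions named list (same species names) of
#'   interaction \code{data.frame}s predicted in each target species with
#'   the same kinase models and cutoffs.
#' @return the input with \code{conserved_species} and \code{n_cons}
#'   filled in.
#' @export
interactionConservation <- function(interactions, maps,
                                    per_species_interactions) {
  stopifnot(setequal(names(maps), names(per_species_interactions)))
  species <- names(maps)
  spec_keys <- lapply(per_species_interactions, function(d)
    paste(d$kinase, d$protein_id, sep = "\r"))
  cons <- vapply(seq_len(nrow(interactions)), function(i) {
    hit <- vapply(species, function(sp) {
      tid <- orthologOf(maps[[sp]], interactions$protein_id[i])
      !is.na(tid) &&
        paste(interactions$kinase[i], tid, sep = "\r") %in% spec_keys[[sp]]
    }, logical(1))
    paste(species[hit], collapse = ";")
  }, "")
  interactions$conserved_species <- cons
  interactions$n_cons <- vapply(strsplit(cons, ";", fixed = TRUE),
                                function(v) sum(nzchar(v)), integer(1))
  interactions
}

#' ROC of conservation degree against an interaction label
#'
#' Ranks interactions by \code{n_cons} and evaluates the ranking against a
#' binary label. Degrees are small integers, so ties dominate; the AROC
#' uses midrank tie handling and the returned curve has one point per
#' distinct degree (descending thresholds).
#'
#' @param interactions \code{data.frame} with an \code{n_cons} column.
#' @param labels logical vector, one per interaction.
#' @return list with \code{aroc} and \code{curve} (a \code{data.frame} of
#'   \code{min_degree}, \code{tpr}, \code{fpr}).
#' @export
rankInteractionsROC <- function(interactions, labels) {
  labels <- as.logical(labels)
  stopifnot(nrow(interactions) == length(labels))
  a <- auroc(interactions$n_cons, labels)
  degs <- sort(unique(interactions$n_cons), decreasing = TRUE)
  np <- sum(labels); nn <- sum(!labels)
  curve <- data.frame(
    min_degree = degs,
    tpr = vapply(degs, function(d)
      sum(labels & interactions$n_cons >= d) / np, numeric(1)),
    fpr = vapply(degs, function(d)
      sum(!labels & interactions$n_cons >= d) / nn, numeric(1))
  )
  list(aroc = a, curve = curve)
}

#' Enrichment fold of an annotation among highly conserved interactions
#'
#' Ratio of the positive fraction among interactions with
#' \code{n_cons >= min_degree} to the positive fraction among all
#' interactions. At \code{min_degree = 0} the subset is the whole set and
#' the fold is exactly 1.
#'
#' @param interactions \code{data.frame} with \code{kinase},
#'   \code{protein_id} and \code{n_cons} columns.
#' @param positive_set character vector of positive keys; either
#'   \code{"kinase\%protein"} pairs (use [interactionKey()]) or bare protein
#'   ids, matched per \code{by}.
#' @param min_degree conservation-degree threshold defining the subset.
#' @param by \code{"interaction"} (kinase-protein pairs) or
#'   \code{"protein"}.
#' @return the enrichment fold (a number).
#' @export
enrichmentFold <- function(interactions, positive_set, min_degree,
                           by = c("interaction", "protein")) {
  by <- match.arg(by)
  if (!nrow(interactions))
    stop("no interactions supplied", call. = FALSE)
  keys <- if (by == "interaction")
    interactionKey(interactions$kinase, interactions$protein_id)
  else interactions$protein_id
  pos <- keys %in% positive_set
  sub <- interactions$n_cons >= min_degree
  if (!any(sub))
    stop("no interaction reaches conservation degree ", min_degree,
         call. = FALSE)
  base_frac <- mean(pos)
  if (base_frac == 0)
    stop("positive set does not intersect the interactions; fold undefined",
         call. = FALSE)
  mean(pos[sub]) / base_frac
}

#' Canonical interaction key
#' @param kinase,protein_id character vectors.
#' @return \code{"kinase\%protein"} keys.
#' @export
interactionKey <- function(kinase, protein_id) {
  paste(kinase, protein_id, sep = "%")
}

#' Drop phosphosites identical to known kinase target peptides
#'
#' Control for circularity in interaction benchmarking: removes every
#' compiled site whose sequence window is 100\% identical to a known
#' target-site window of the kinase, so that re-running the conservation
#' ranking cannot be driven by sites that literally are the training data.
#'
#' @param x a [PhosphoSet-class].
#' @param seqs named proteome (character vector or \code{AAStringSet}).
#' @param known_windows character vector of known target windows (same
#'   half-width as used for prediction).
#' @param w window half-width.
#' @return a filtered [PhosphoSet-class].
#' @export
excludeIdenticalPeptides <- function(x, seqs, known_windows, w) {
  seqs <- setNames(as.character(seqs), names(seqs))
  s <- siteTable(x)
  if (!nrow(s)) return(x)
  win <- vapply(seq_len(nrow(s)), function(i) {
    if (!s$protein_id[i] %in% names(seqs)) return(NA_character_)
    extractWindow(seqs[[s$protein_id[i]]], s$position[i], w)
  }, "")
  keep <- is.na(win) | !win %in% known_windows
  PhosphoSet(s[keep, , drop = FALSE], species = x@species,
             provenance = x@provenance)
}

#' Export the high-conservation interaction network
#'
#' Filters interactions to a minimum conservation degree and annotates each
#' edge with membership in the benchmark sets. Optionally writes a TSV and
#' a SIF (\code{kinase phosphorylates protein}) file.
#'
#' @param interactions conserved interaction \code{data.frame}
#'   (see [interactionConservation()]).
#' @param annotations list with character-vector elements
#'   \code{known_interactions} (\code{"kinase\%protein"} keys),
#'   \code{cellcycle_regulated} and \code{phenotype_genes} (protein ids).
#'   Missing elements are treated as empty.
#' @param min_degree minimum \code{n_cons} (default 7).
#' @param path optional output stem; writes \code{<path>.tsv} and
#'   \code{<path>.sif}.
#' @return \code{data.frame} with columns \code{kinase}, \code{protein_id},
#'   \code{n_cons}, \code{known_interaction}, \code{cellcycle_regulated},
#'   \code{phenotype} (edge weight = \code{n_cons}).
#' @export
exportNetwork <- function(interactions, annotations = list(),
                          min_degree = 7, path = NULL) {
  ann <- function(nm) if (is.null(annotations[[nm]])) character()
                      else annotations[[nm]]
  net <- interactions[interactions$n_cons >= min_degree, , drop = FALSE]
  out <- data.frame(
    kinase = net$kinase,
    protein_id = net$protein_id,
    n_cons = net$n_cons,
    known_interaction = interactionKey(net$kinase, net$protein_id) %in%
      ann("known_interactions"),
    cellcycle_regulated = net$protein_id %in% ann("cellcycle_regulated"),
    phenotype = net$protein_id %in% ann("phenotype_genes"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    sif <- paste(out$kinase, "phosphorylates", out$protein_id)
    writeLines(sif, paste0(path, ".sif"))
  }
  out
}
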