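# Cross-species phosphosite conservation calling and enrichment-by-degree.
#
# A query site is conserved in a target species when the ortholog is known
# to be phosphorylated within +/- `window` residues of the aligned
# position. The window absorbs both alignment uncertainty and the
# within-peptide ambiguity of phosphosite localization.

#' Map a query position through an alignment
#'
#' Returns the 1-based target-sequence index of the residue aligned to a
#' query position. When the query residue sits over a gap in the target,
#' the index of the nearest preceding non-gap target residue is returned
#' (deterministic, and never further than the window the caller applies);
#' \code{NA} when no target residue precedes the column.
#'
#' @param alignment a pair alignment: list with \code{aligned_query} and
#'   \code{aligned_target} equal-length gapped strings (as produced by
#'   [alignPair()] or stored in an [OrthologMap-class]).
#' @param query_pos 1-based position in the ungapped query sequence.
#' @return integer target position, or \code{NA_integer_}.
#' @export
mapAlignedPosition <- function(alignment, query_pos) {
  qc <- strsplit(alignment$aligned_query, "", fixed = TRUE)[[1]]
  tc <- strsplit(alignment$aligned_target, "", fixed = TRUE)[[1]]
  stopifnot(length(qc) == length(tc))
  qidx <- cumsum(qc != "-")
  n_query <- qidx[length(qidx)]
  if (query_pos < 1L || query_pos > n_query)
    stop("query position ", query_pos, " out of range 1..", n_query,
         call. = FALSE)
  col <- which(qidx == query_pos & qc != "-")[1]
  tidx <- cumsum(tc != "-")
  # tidx[col] is the target index at the column, or the index of the nearest
  # preceding non-gap target residue when the column is a target gap.
  out <- tidx[col]
  if (out == 0L) NA_integer_ else as.integer(out)
}

#' Call conservation of one site in one target species
#'
#' @param query_pos 1-based site position on the query protein.
#' @param ortholog_sites integer vector of phosphorylated positions on the
#'   ortholog (target species).
#' @param alignment query-ortholog alignment (see [mapAlignedPosition()]).
#' @param window half-width in target-sequence residues (default 2).
#' @return list with \code{conserved} (logical),
#'   \code{matched_target_position} (integer or \code{NA}; the nearest
#'   in-window target site, ties resolved to the smaller position) and
#'   \code{mapped_position}.
#' @export
callSiteConservation <- function(query_pos, ortholog_sites, alignment,
                                 window = 2) {
  mapped <- mapAlignedPosition(alignment, query_pos)
  if (is.na(mapped) || length(ortholog_sites) == 0L)
    return(list(conserved = FALSE, matched_target_position = NA_integer_,
                mapped_position = mapped))
  d <- abs(ortholog_sites - mapped)
  in_win <- d <= window
  if (!any(in_win))
    return(list(conserved = FALSE, matched_target_position = NA_integer_,
                mapped_position = mapped))
  cand <- ortholog_sites[in_win]
  cand <- cand[order(abs(cand - mapped), cand)]
  list(conserved = TRUE, matched_target_position = as.integer(cand[1]),
       mapped_position = mapped)
}

#' Build per-site conservation profiles across species
#'
#' For every site in the query compilation, calls conservation in each
#' target species (species without an ortholog for the site's protein
#' contribute \code{FALSE}) and records the conservation degree — the
#' number of species in which the site is conserved.
#'
#' @param x query-species [PhosphoSet-class].
#' @param maps named list of [OrthologMap-class], one per target species.
#' @param target_sites named list of [PhosphoSet-class], one per target
#'   species (same names as \code{maps}).
#' @param window conservation window half-width (default 2).
#' @return \code{data.frame} with one row per query site: \code{protein_id},
#'   \code{position}, \code{residue}, \code{degree}, and
#'   \code{conserved_species} (\code{";"}-joined labels). The per-species
#'   call table is attached as attribute \code{"calls"} (site key x species
#'   logical matrix).
#' @export
buildConservationProfiles <- function(x, maps, target_sites, window = 2) {
  stopifnot(setequal(names(maps), names(target_sites)))
  species <- names(maps)
  s <- siteTable(x)
  calls <- matrix(FALSE, nrow = nrow(s), ncol = length(species),
                  dimnames = list(siteKey(s$protein_id, s$position), species))
  for (sp in species) {
    map <- maps[[sp]]
    tsites <- siteTable(target_sites[[sp]])
    tsite_by_protein <- split(tsites$position, tsites$protein_id)
    for (i in seq_len(nrow(s))) {
      tid <- orthologOf(map, s$protein_id[i])
      if (is.na(tid)) next
      al <- orthologAlignment(map, s$protein_id[i])
      osites <- tsite_by_protein[[tid]]
      if (is.null(osites)) osites <- integer()
      calls[i, sp] <- callSiteConservation(s$position[i], osites, al,
                                           window = window)$conserved
    }
  }
  degree <- rowSums(calls)
  conserved_species <- apply(calls, 1, function(r)
    paste(species[r], collapse = ";"))
  out <- data.frame(protein_id = s$protein_id, position = s$position,
                    residue = s$residue, degree = as.integer(degree),
                    conserved_species = unname(conserved_species),
                    stringsAsFactors = FALSE)
  attr(out, "calls") <- calls
  out
}

#' Summarize conservation by degree threshold
#'
#' @param profiles profile \code{data.frame} from
#'   [buildConservationProfiles()].
#' @return \code{data.frame} with one row per degree threshold t = 0..max:
#'   \code{min_degree}, \code{n_sites} (sites with degree >= t),
#'   \code{fraction} of all sites, \code{percent} (one decimal).
#' @export
conservationSummary <- function(profiles) {
  total <- nrow(profiles)
  ts <- 0:max(c(profiles$degree, 0L))
  n <- vapply(ts, function(t) sum(profiles$degree >= t), integer(1))
  data.frame(min_degree = ts, n_sites = n,
             fraction = if (total) n / total else rep(NA_real_, length(ts)),
             percent = if (total) round(100 * n / total, 1)
                       else rep(NA_real_, length(ts)))
}

#' Known-function enrichment as a function of conservation degree
#'
#' Tabulates, for increasing conservation-degree thresholds, how many sites
#' remain and what fraction of them carry a known function. With an
#' \code{anchor_species}, only sites conserved in that species are
#' considered and the degree counts species *beyond* the anchor — the
#' question becomes "among sites shared with the anchor, does conservation
#' in additional species enrich for function annotated in the anchor?".
#' With a disorder track set the same table is also computed separately for
#' sites in ordered and in disordered regions (classified by the call at
#' the site's own residue).
#'
#' @param profiles profile \code{data.frame} from
#'   [buildConservationProfiles()] (its \code{"calls"} attribute is required
#'   when \code{anchor_species} is given).
#' @param known_function character vector of site keys
#'   (\code{"protein:position"}) with known function.
#' @param anchor_species optional species label.
#' @param disorder optional named list, protein id -> per-residue logical
#'   vector (\code{TRUE} = disordered).
#' @return \code{data.frame} with columns \code{min_degree}, \code{n_sites},
#'   \code{n_known}, \code{fraction}, \code{percent} (one decimal;
#'   \code{NA} when no sites remain). When \code{disorder} is supplied, the
#'   ordered/disordered tables are attached as attributes \code{"ordered"}
#'   and \code{"disordered"}.
#' @export
functionEnrichmentByDegree <- function(profiles, known_function,
                                       anchor_species = NULL,
                                       disorder = NULL) {
  p <- profiles
  degree <- p$degree
  if (!is.null(anchor_species)) {
    calls <- attr(profiles, "calls")
    if (is.null(calls) || !anchor_species %in% colnames(calls))
      stop("profiles lack per-species calls for anchor species ",
           anchor_species, call. = FALSE)
    in_anchor <- calls[, anchor_species]
    p <- p[in_anchor, , drop = FALSE]
    degree <- p$degree - 1L  # species beyond the anchor
  }
  keys <- siteKey(p$protein_id, p$position)
  known <- keys %in% known_function

  tab <- function(sel) {
    d <- degree[sel]; k <- known[sel]
    ts <- 0:max(c(d, 0L))
    n <- vapply(ts, function(t) sum(d >= t), integer(1))
    nk <- vapply(ts, function(t) sum(k[d >= t]), integer(1))
    frac <- ifelse(n > 0, nk / n, NA_real_)
    data.frame(min_degree = ts, n_sites = n, n_known = nk,
               fraction = frac, percent = round(100 * frac, 1))
  }
  out <- tab(rep(TRUE, nrow(p)))
  if (!is.null(disorder)) {
    dis_call <- vapply(seq_len(nrow(p)), function(i) {
      trk <- disorder[[p$protein_id[i]]]
      if (is.null(trk) || p$position[i] > length(trk)) NA
      else trk[p$position[i]]
    }, logical(1))
    attr(out, "ordered") <- tab(!is.na(dis_call) & !dis_call)
    attr(out, "disordered") <- tab(!is.na(dis_call) & dis_call)
  }
  out
}
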