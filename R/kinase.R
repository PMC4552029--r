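# Kinase specificity models: PSSM training, Matrix Similarity Score,
# cross-validated AROC benchmarking, and MSS cutoff calibration.

#' Extract the sequence window around a phospho-acceptor
#'
#' Returns the \code{2w+1}-mer centered on \code{pos}, padded with
#' \code{"-"} where the window overhangs the sequence ends.
#'
#' @param seq protein sequence (single character string or \code{AAString}).
#' @param pos 1-based acceptor position; the residue there must be S, T or Y.
#' @param w window half-width.
#' @return character string of length \code{2w+1}.
#' @export
extractWindow <- function(seq, pos, w) {
  seq <- as.character(seq)
  n <- nchar(seq)
  if (pos < 1L || pos > n)
    stop("position ", pos, " out of range 1..", n, call. = FALSE)
  center <- substr(seq, pos, pos)
  if (!center %in% ACCEPTORS)
    stop("residue at position ", pos, " is '", center,
         "', not a phospho-acceptor (S/T/Y)", call. = FALSE)
  padded <- paste0(strrep("-", w), seq, strrep("-", w))
  substr(padded, pos, pos + 2L * w)
}

# Split peptides into an n x (2w+1) character matrix.
.peptideMatrix <- function(peptides) {
  lens <- nchar(peptides)
  if (length(unique(lens)) != 1L)
    stop("peptides must share one window length", call. = FALSE)
  if (lens[1] %% 2L == 0L)
    stop("window length must be odd", call. = FALSE)
  matrix(unlist(strsplit(toupper(peptides), "", fixed = TRUE)),
         nrow = length(peptides), byrow = TRUE)
}

#' Train a position-specific scoring matrix for a kinase
#'
#' Builds per-position residue frequencies from known substrate windows.
#' At flanking position i, with \eqn{N_i} non-pad standard residues
#' observed and count(i, b) occurrences of residue b,
#' \deqn{f(i,b) = \frac{\mathrm{count}(i,b) + \beta/20}{N_i + \beta}}
#' with pseudocount weight \eqn{\beta} spread over a uniform 20-letter
#' background. The acceptor position itself is excluded: it is constant
#' within a kinase's positive set and carries no discriminative
#' information. Information weights and MSS score bounds are derived as
#' described in [KinasePSSM-class].
#'
#' @param kinase kinase name.
#' @param positives character vector of substrate windows (odd, equal
#'   length, \code{"-"}-padded).
#' @param pseudocount_weight \eqn{\beta}; default 1.
#' @return a [KinasePSSM-class] (cutoff unset).
#' @export
buildPSSM <- function(kinase, positives, pseudocount_weight = 1) {
  if (length(positives) < 1L)
    stop("at least one positive window is required", call. = FALSE)
  pm <- .peptideMatrix(positives)
  w <- (ncol(pm) - 1L) %/% 2L
  flank_cols <- setdiff(seq_len(ncol(pm)), w + 1L)
  beta <- pseudocount_weight
  freq <- matrix(0, nrow = 20L, ncol = length(flank_cols),
                 dimnames = list(AA20, as.character(c(-w:-1, 1:w))))
  for (j in seq_along(flank_cols)) {
    obs <- pm[, flank_cols[j]]
    obs <- obs[obs %in% AA20]
    n_i <- length(obs)
    if (n_i + beta <= 0)
      stop("degenerate column at position ", colnames(freq)[j],
           ": no usable residues and no pseudocount", call. = FALSE)
    counts <- table(factor(obs, levels = AA20))
    freq[, j] <- (as.numeric(counts) + beta / 20) / (n_i + beta)
  }
  .pssmFromFreq(kinase, w, freq)
}

# Assemble a KinasePSSM from a finished frequency matrix.
.pssmFromFreq <- function(kinase, w, freq, cutoff = NA_real_) {
  info <- apply(freq, 2, function(f) {
    pos <- f > 0
    sum(f[pos] * log(20 * f[pos]))
  })
  score_min <- sum(info * apply(freq, 2, min))
  score_max <- sum(info * apply(freq, 2, max))
  new("KinasePSSM", kinase = kinase, w = as.integer(w), freq = freq,
      info = setNames(as.numeric(info), colnames(freq)),
      scoreMin = score_min, scoreMax = score_max,
      cutoff = as.numeric(cutoff))
}

#' Construct a KinasePSSM directly from a frequency matrix
#'
#' Mainly useful for analytic checks and for loading serialized models.
#' Rows not supplied are filled with zero frequency.
#'
#' @param kinase kinase name.
#' @param freq frequency matrix with residue rownames (subset of the 20
#'   standard residues) and one column per flanking position, each summing
#'   to 1. Column names, when given, must be the signed positions
#'   \code{-w..-1, 1..w}.
#' @param cutoff optional MSS cutoff.
#' @return a [KinasePSSM-class].
#' @export
kinasePSSM <- function(kinase, freq, cutoff = NA_real_) {
  stopifnot(is.matrix(freq), !is.null(rownames(freq)))
  if (ncol(freq) %% 2L != 0L)
    stop("freq must have an even number of flanking positions", call. = FALSE)
  w <- ncol(freq) %/% 2L
  full <- matrix(0, nrow = 20L, ncol = ncol(freq),
                 dimnames = list(AA20, as.character(c(-w:-1, 1:w))))
  bad <- setdiff(rownames(freq), AA20)
  if (length(bad))
    stop("unknown residues in freq: ", paste(bad, collapse = ", "),
         call. = FALSE)
  full[rownames(freq), ] <- freq
  .pssmFromFreq(kinase, w, full, cutoff)
}

#' Matrix Similarity Score of peptide windows against a kinase PSSM
#'
#' For a window s, \eqn{Current = \sum_{i \neq 0} I(i) f(i, s_i)}; the MSS
#' is \eqn{(Current - Min)/(Max - Min)} with the bounds stored in the
#' model, so the consensus window scores 1 and the anti-consensus 0. Pad
#' (\code{"-"}) or non-standard residues contribute a neutral frequency of
#' 1/20, clamped into the column's observed frequency range so the score
#' stays within [0, 1].
#'
#' @param m a [KinasePSSM-class].
#' @param peptides character vector of windows with the model's half-width.
#' @return numeric vector of scores in [0, 1].
#' @export
mssScore <- function(m, peptides) {
  if (m@scoreMax - m@scoreMin <= 0)
    stop("degenerate matrix: score bounds coincide", call. = FALSE)
  pm <- .peptideMatrix(peptides)
  if ((ncol(pm) - 1L) %/% 2L != m@w)
    stop("peptide half-width does not match the model", call. = FALSE)
  flank_cols <- setdiff(seq_len(ncol(pm)), m@w + 1L)
  current <- numeric(nrow(pm))
  for (j in seq_along(flank_cols)) {
    col <- m@freq[, j]
    rows <- match(pm[, flank_cols[j]], AA20)
    vals <- col[rows]
    neutral <- min(max(1 / 20, min(col)), max(col))
    vals[is.na(rows)] <- neutral
    current <- current + m@info[j] * vals
  }
  unname((current - m@scoreMin) / (m@scoreMax - m@scoreMin))
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney statistic with midrank tie
#' handling: the probability that a random positive outscores a random
#' negative, counting ties as one half.
#'
#' @param scores numeric scores.
#' @param labels logical labels (\code{TRUE} = positive).
#' @return AROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    stop("AROC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validated AROC benchmark of a kinase model
#'
#' Stratified k-fold cross-validation: positives and negatives are each
#' split into k folds (seeded); for each fold a PSSM is trained on the
#' remaining positives and the held-out positives are scored against the
#' held-out negatives. Reports per-fold AROCs and their median, the
#' statistic used to gate kinase selection (median AROC > 0.7).
#'
#' @param positives,negatives character vectors of substrate / non-substrate
#'   windows (equal, odd length).
#' @param k number of folds (default 10); reduced with a message when a
#'   class has fewer members than k.
#' @param pseudocount_weight passed to [buildPSSM()].
#' @param seed RNG seed for the fold assignment.
#' @param kinase kinase name carried into the result.
#' @return list with \code{kinase}, \code{fold_arocs}, \code{median_aroc},
#'   \code{k} (folds actually used) and \code{selected}
#'   (\code{median_aroc > 0.7}).
#' @export
crossValidateKinase <- function(positives, negatives, k = 10,
                                pseudocount_weight = 1, seed = 1,
                                kinase = "kinase") {
  np <- length(positives); nn <- length(negatives)
  if (np < 2L)
    stop("cannot cross-validate with fewer than 2 positives", call. = FALSE)
  if (nn < 2L)
    stop("cannot cross-validate with fewer than 2 negatives", call. = FALSE)
  k_eff <- min(k, np, nn)
  if (k_eff < k)
    message("reducing folds from ", k, " to ", k_eff,
            " (limited by class size)")
  folds <- withSeed(seed, list(
    pos = sample(rep_len(seq_len(k_eff), np)),
    neg = sample(rep_len(seq_len(k_eff), nn))
  ))
  arocs <- vapply(seq_len(k_eff), function(i) {
    train_pos <- positives[folds$pos != i]
    test_pos <- positives[folds$pos == i]
    test_neg <- negatives[folds$neg == i]
    m <- buildPSSM(kinase, train_pos, pseudocount_weight)
    sc <- mssScore(m, c(test_pos, test_neg))
    auroc(sc, c(rep(TRUE, length(test_pos)), rep(FALSE, length(test_neg))))
  }, numeric(1))
  list(kinase = kinase, fold_arocs = arocs, median_aroc = median(arocs),
       k = k_eff, selected = median(arocs) > 0.7)
}

#' Calibrate the MSS decision cutoff for a kinase
#'
#' Chooses the threshold that maximizes classification accuracy over the
#' model's scored positive and negative sets. Because accuracy is
#' meaningful only for comparable class sizes, the smaller positive set is
#' first up-sampled with replacement (seeded) to the size of the negative
#' set. Candidate thresholds are the midpoints between consecutive sorted
#' unique pooled scores; a score predicts positive when it is \code{>=} the
#' threshold, and the smallest maximizing candidate (the most sensitive
#' one) is returned.
#'
#' @param pos_scores,neg_scores numeric MSS scores of the positive and
#'   negative sets.
#' @param seed RNG seed for the up-sampling.
#' @return the calibrated threshold.
#' @export
calibrateCutoff <- function(pos_scores, neg_scores, seed = 1) {
  stopifnot(length(pos_scores) > 0, length(neg_scores) > 0)
  if (length(pos_scores) < length(neg_scores)) {
    pos_scores <- withSeed(seed,
      sample(pos_scores, length(neg_scores), replace = TRUE))
  }
  u <- sort(unique(c(pos_scores, neg_scores)))
  cands <- if (length(u) == 1L) u else (u[-1] + u[-length(u)]) / 2
  acc <- vapply(cands, function(th) {
    (sum(pos_scores >= th) + sum(neg_scores < th)) /
      (length(pos_scores) + length(neg_scores))
  }, numeric(1))
  cands[which.max(acc)]  # which.max takes the first, i.e. smallest, maximizer
}

#' Published per-kinase MSS cutoffs
#'
#' Decision thresholds calibrated on the curated kinase-substrate sets for
#' the ten cell-cycle kinases whose cross-validated models passed the
#' AROC > 0.7 gate. Shipped as named constants so predictions can be made
#' without retraining.
#'
#' @return named numeric vector of MSS cutoffs.
#' @export
defaultKinaseCutoffs <- function() {
  c(Plk1 = 0.436, Plk3 = 0.386, Chk1 = 0.236, Cdk1 = 0.929, Cdk2 = 0.126,
    Cdk3 = 0.455, AurB = 0.14, Atr = 0.932, Akt = 0.662, Nek6 = 0.402)
}

#' Predict a kinase's target sites in a phosphosite set
#'
#' Scores the window around every compiled phosphosite with the kinase's
#' PSSM and keeps sites whose MSS reaches the model cutoff. Sites on
#' proteins missing from the supplied proteome are skipped (reported via a
#' message and the \code{"skipped"} attribute).
#'
#' @param x a [PhosphoSet-class].
#' @param seqs named character vector or \code{AAStringSet}: the proteome
#'   the site positions refer to.
#' @param m a [KinasePSSM-class] with a cutoff set (or supply
#'   \code{cutoff}).
#' @param cutoff MSS threshold; defaults to the model's calibrated cutoff.
#' @return \code{data.frame} of predicted target sites: \code{kinase},
#'   \code{protein_id}, \code{position}, \code{residue}, \code{peptide},
#'   \code{mss}.
#' @export
predictTargetSites <- function(x, seqs, m, cutoff = pssmCutoff(m)) {
  if (is.na(cutoff))
    stop("no MSS cutoff set for kinase ", m@kinase, call. = FALSE)
  seqs <- setNames(as.character(seqs), names(seqs))
  s <- siteTable(x)
  have <- s$protein_id %in% names(seqs)
  if (any(!have)) {
    message("skipping ", sum(!have), " site(s) on proteins without sequence")
  }
  s2 <- s[have, , drop = FALSE]
  empty <- data.frame(kinase = character(), protein_id = character(),
                      position = integer(), residue = character(),
                      peptide = character(), mss = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(s2)) {
    attr(empty, "skipped") <- s[!have, , drop = FALSE]
    return(empty)
  }
  peptides <- vapply(seq_len(nrow(s2)), function(i)
    extractWindow(seqs[[s2$protein_id[i]]], s2$position[i], m@w), "")
  mss <- mssScore(m, peptides)
  keep <- mss >= cutoff
  out <- data.frame(kinase = rep(m@kinase, sum(keep)),
                    protein_id = s2$protein_id[keep],
                    position = s2$position[keep],
                    residue = s2$residue[keep],
                    peptide = peptides[keep],
                    mss = mss[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- s[!have, , drop = FALSE]
  out
}
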