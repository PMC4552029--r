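# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately naive (quadratic loops, explicit DP)
# and shares no code with the package internals it checks.

AA20_T <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Gotoh affine-gap DP, scores only. A gap of length L costs
# gap_open + L * gap_extend (first gap residue pays open + extend).
oracleAlignScore <- function(a, b, mode = "global", mat = .blosum62,
                             gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in a gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in a gap in a (b consumed)
  local_mode <- mode == "local"
  M[1, 1] <- 0
  for (i in seq_len(n) + 1) {
    X[i, 1] <- -(gap_open + (i - 1) * gap_extend)
    if (local_mode) X[i, 1] <- max(X[i, 1], NEG)
  }
  for (j in seq_len(m) + 1) {
    Y[1, j] <- -(gap_open + (j - 1) * gap_extend)
  }
  best_local <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      if (local_mode) M[i, j] <- max(M[i, j], s)
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      if (local_mode) best_local <- max(best_local, M[i, j])
    }
  }
  if (local_mode) best_local else max(M[n + 1, m + 1], X[n + 1, m + 1],
                                      Y[n + 1, m + 1])
}

# AROC by explicit pair counting, ties worth one half.
oracleAuroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive conservation call: walk alignment columns one by one to map
# the query position, then scan every target site against the window.
oracleConservation <- function(query_pos, target_sites, aligned_query,
                               aligned_target, window) {
  qc <- strsplit(aligned_query, "")[[1]]
  tc <- strsplit(aligned_target, "")[[1]]
  qi <- 0; ti <- 0; mapped <- NA
  for (k in seq_along(qc)) {
    if (tc[k] != "-") ti <- ti + 1
    if (qc[k] != "-") {
      qi <- qi + 1
      if (qi == query_pos) {
        mapped <- if (ti >= 1) ti else NA
        break
      }
    }
  }
  if (is.na(mapped)) return(FALSE)
  any(vapply(target_sites, function(p) abs(p - mapped) <= window,
             logical(1)))
}

randomProtein <- function(n) paste(sample(AA20_T, n, replace = TRUE),
                                   collapse = "")

skey <- function(protein_id, position) paste0(protein_id, ":", position)

# Random gapped alignment pair with no all-gap columns.
randomAlignmentPair <- function(ncol = 20, gap_prob = 0.2) {
  repeat {
    q <- sample(c(AA20_T, "-"), ncol, replace = TRUE,
                prob = c(rep((1 - gap_prob) / 20, 20), gap_prob))
    t <- sample(c(AA20_T, "-"), ncol, replace = TRUE,
                prob = c(rep((1 - gap_prob) / 20, 20), gap_prob))
    both <- q == "-" & t == "-"
    q <- q[!both]; t <- t[!both]
    if (sum(q != "-") >= 3 && sum(t != "-") >= 1) {
      return(list(aligned_query = paste(q, collapse = ""),
                  aligned_target = paste(t, collapse = "")))
    }
  }
}

# Acceptor-centered random window of half-width w.
randomWindow <- function(w) {
  paste0(paste(sample(AA20_T, w, replace = TRUE), collapse = ""),
         sample(c("S", "T", "Y"), 1),
         paste(sample(AA20_T, w, replace = TRUE), collapse = ""))
}

# Random window with fixed motif residues at the given signed offsets.
motifWindow <- function(w, motif) {
  win <- strsplit(randomWindow(w), "")[[1]]
  for (nm in names(motif)) win[w + 1 + as.integer(nm)] <- motif[[nm]]
  paste(win, collapse = "")
}

# Ungapped ortholog maps straight from a synthetic cohort's ground truth
# (the generator introduces no indels, so the alignment is the identity).
truthOrthologMaps <- function(cohort) {
  maps <- lapply(names(cohort$ortholog_truth), function(sp) {
    tmap <- cohort$ortholog_truth[[sp]]
    alignments <- lapply(names(tmap), function(q) {
      list(aligned_query = cohort$query_proteome[[q]],
           aligned_target = cohort$species_proteomes[[sp]][[tmap[[q]]]],
           score = NA_real_)
    })
    names(alignments) <- names(tmap)
    new("OrthologMap", species = sp,
        pairs = data.frame(query_id = names(tmap),
                           target_id = unname(tmap),
                           score = NA_real_, stringsAsFactors = FALSE),
        alignments = alignments)
  })
  names(maps) <- names(cohort$ortholog_truth)
  maps
}

# Minimal ungapped single-pair ortholog map for toy conservation tests.
toyMap <- function(species, query_id, target_id, query_seq,
                   target_seq = query_seq) {
  new("OrthologMap", species = species,
      pairs = data.frame(query_id = query_id, target_id = target_id,
                         score = NA_real_, stringsAsFactors = FALSE),
      alignments = setNames(list(list(aligned_query = query_seq,
                                      aligned_target = target_seq,
                                      score = NA_real_)), query_id))
}

toySites <- function(protein_id, positions, residues = "S",
                     species = "toy", ...) {
  PhosphoSet(data.frame(protein_id = protein_id, position = positions,
                        residue = residues, sources = species,
                        stringsAsFactors = FALSE, ...),
             species = species)
}
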