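# Internal helpers shared across modules.

#' @importFrom methods new validObject is slot
#' @importFrom stats median rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

# The 20 standard amino acids, in the conventional one-letter order used by
# substitution matrices.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

ACCEPTORS <- c("S", "T", "Y")

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            UNK = "X")

AA1TO3 <- setNames(names(AA3TO1), AA3TO1)

# Canonical site key: "<protein_id>:<position>".
siteKey <- function(protein_id, position) {
  paste0(protein_id, ":", as.integer(position))
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# random stream.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# md5 of an arbitrary R object through its canonical JSON serialization
# (used for config hashes in run metadata; stable across sessions).
objectHash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

stopifnot_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single non-missing number", call. = FALSE)
}
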