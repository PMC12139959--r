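`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Reverse complement of read-oriented DNA strings (vectorised).
revcomp <- function(x) {
  out <- x
  ok <- !is.na(x) & nzchar(x)
  if (any(ok))
    out[ok] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x[ok])))
  out
}

# 5' nucleotide of a read-oriented sequence, RNA alphabet (T reported as U).
first_nt_of <- function(seq) {
  nt <- chartr("T", "U", toupper(substr(seq, 1L, 1L)))
  nt[!(nt %in% c("A", "C", "G", "U")) | is.na(seq)] <- "N"
  nt
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
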