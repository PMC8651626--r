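# Internal helpers: seeded RNG scoping, sequence utilities, TSV/FASTA I/O.

`%||%` <- function(a, b) if (is.null(a)) b else a

# make data.table's `[` semantics available without importing its namespace
.datatable.aware <- TRUE

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not perturb the
#' caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Deterministic sub-seed for a named stage; result stays below 2^31 - 1.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647L)
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

# Point-substitute a single sequence at per-base rate `rate`.
mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) chars[i] <- sample(setdiff(bases, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# IUPAC code -> one concrete expansion (first listed base), vectorised over chars.
iupac_realize <- function(x) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "A", Y = "C", S = "C",
           W = "A", K = "G", M = "A", B = "C", D = "A", H = "A", V = "A", N = "A")
  vapply(strsplit(toupper(x), "", fixed = TRUE), function(ch) {
    paste(map[ch], collapse = "")
  }, character(1))
}

iupac_expand <- function(code) {
  switch(toupper(code),
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
    D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T"),
    stop("invalid IUPAC code: ", code))
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  colClasses = NULL, data.table = FALSE, ...))
}

write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 100L)
  invisible(path)
}

read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}
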