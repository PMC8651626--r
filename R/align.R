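# Semi-global alignment scoring used as the local stand-in for BLAST.
#
# Queries (OTU centroids) are aligned end-to-end against each reference with
# free end gaps on the reference ("global-local"), scoring match +2,
# mismatch -3, gap open -5, gap extend -2.  Identity is matches / alignment
# columns spanning the query (gap columns count as mismatches); coverage is
# the fraction of query bases aligned.  Users with real BLAST tabular output
# can bypass this entirely via [read_hit_table()].

ALIGN_MATCH <- 2
ALIGN_MISMATCH <- -3
ALIGN_GAP_OPEN <- 5
ALIGN_GAP_EXTEND <- 2

.align_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = ALIGN_MATCH,
                                           mismatch = ALIGN_MISMATCH,
                                           baseOnly = TRUE)
}

#' Align a query against a reference and report identity, coverage, score
#'
#' Semi-global alignment: the query aligns end-to-end, end gaps on the
#' reference are free.  With this convention coverage is 100 whenever the
#' aligner is used directly; sub-100 coverages arise from externally
#' supplied hit tables ([read_hit_table()]).
#'
#' @param query,reference DNA sequences (character, ACGT)
#' @return `list(identity =, coverage =, score =)`; identity and coverage in
#'   percent.
#' @examples
#' align_identity("AAAATTTT", "AAAACCTTTT") # identity 80, one 2-base gap
#' @export
align_identity <- function(query, reference) {
  if (!nzchar(query) || !nzchar(reference)) stop("empty sequence")
  h <- align_hits(query, reference)
  list(identity = h$identity, coverage = h$coverage, score = h$score)
}

# Vectorised workhorse: aligns every query against every reference record.
# Returns a data.frame with one row per (query, reference) pair.
align_hits <- function(queries, references, query_ids = NULL, ref_ids = NULL) {
  queries <- as.character(queries)
  references <- as.character(references)
  query_ids <- query_ids %||% names(queries) %||% as.character(seq_along(queries))
  ref_ids <- ref_ids %||% names(references) %||% as.character(seq_along(references))
  qset <- Biostrings::DNAStringSet(queries)
  sm <- .align_submat()
  out <- vector("list", length(references))
  for (j in seq_along(references)) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = qset, subject = Biostrings::DNAString(references[j]),
      type = "global-local", substitutionMatrix = sm,
      gapOpening = ALIGN_GAP_OPEN, gapExtension = ALIGN_GAP_EXTEND)
    # PID1 = 100 * matches / (aligned columns incl. internal gaps): exactly
    # the "gap columns count as mismatches over the query span" convention.
    idy <- Biostrings::pid(pa, type = "PID1")
    cov <- rep(100, length(idy)) # query is global in this alignment type
    out[[j]] <- data.frame(query = query_ids, subject = ref_ids[j],
                           identity = idy, coverage = cov,
                           score = Biostrings::score(pa),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Hits of a set of queries against a ref_db, as a hit table.
db_hits <- function(queries, db, query_ids = NULL) {
  align_hits(queries, db$sequences, query_ids = query_ids, ref_ids = db$ids)
}

#' Read a BLAST outfmt-6-style hit table
#'
#' Expected columns (TSV, with header): `query`, `subject`, `identity`,
#' `coverage`, `score`.  This is the alternative input path for users with
#' real BLAST output; identities/coverages are percentages in \[0, 100\].
#'
#' @param path TSV file
#' @return data.frame of hits
#' @export
read_hit_table <- function(path) {
  h <- read_tsv(path)
  need <- c("query", "subject", "identity", "coverage", "score")
  if (!all(need %in% names(h))) {
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(h$identity < 0 | h$identity > 100) ||
      any(h$coverage < 0 | h$coverage > 100)) {
    stop("identity and coverage must be in [0, 100]")
  }
  h[, need]
}
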