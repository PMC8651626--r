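# Amplicon processing: pair merging, primer trimming, dereplication and
# unoise-style denoising into zero-radius OTUs.  These natively re-implement
# the documented behaviour of the usual external tools (FLASH-style merging,
# cutadapt-style linked-primer trimming, vsearch dereplication, usearch
# unoise3 clustering) at the parameters used for airborne pollen amplicons.

#' Merge a read pair by overlap
#'
#' The reverse read is reverse-complemented; among candidate overlaps of at
#' least `min_overlap` bases with mismatch ratio at most
#' `max_mismatch_ratio`, the longest is chosen.  Overlap mismatches are
#' resolved toward the base with the higher quality; ties (or absent
#' qualities) go to the forward read.  `N` matches any base.
#'
#' @param fwd,rev reads over ACGTN (reverse read in sequencing orientation)
#' @param fwd_qual,rev_qual optional integer vectors of per-base qualities
#' @param min_overlap minimum overlap length in bases (default 10)
#' @param max_mismatch_ratio maximum mismatches / overlap length (default 0.25)
#' @return merged read (character) or `NULL` when no acceptable overlap
#'   exists (rejection is a normal outcome)
#' @export
merge_pairs <- function(fwd, rev, fwd_qual = NULL, rev_qual = NULL,
                        min_overlap = 10, max_mismatch_ratio = 0.25) {
  stopifnot(grepl("^[ACGTN]*$", fwd), grepl("^[ACGTN]*$", rev))
  rc <- revcomp(rev)
  f <- strsplit(fwd, "", fixed = TRUE)[[1]]
  r <- strsplit(rc, "", fixed = TRUE)[[1]]
  rq <- if (!is.null(rev_qual)) base::rev(rev_qual) else NULL
  lf <- length(f); lr <- length(r)
  for (ov in seq(min(lf, lr), min_overlap)) {
    a <- f[(lf - ov + 1):lf]
    b <- r[seq_len(ov)]
    mm <- a != b & a != "N" & b != "N"
    if (sum(mm) / ov <= max_mismatch_ratio) {
      cons <- a
      if (any(mm)) {
        qa <- if (!is.null(fwd_qual)) fwd_qual[(lf - ov + 1):lf] else rep(0, ov)
        qb <- if (!is.null(rq)) rq[seq_len(ov)] else rep(0, ov)
        use_b <- mm & (qb > qa | (a == "N" & b != "N"))
        cons[use_b] <- b[use_b]
      }
      cons[cons == "N" & b != "N"] <- b[cons == "N" & b != "N"]
      return(paste(c(f[seq_len(lf - ov)], cons, r[(ov + 1):lr][seq_len(lr - ov)]),
                   collapse = ""))
    }
  }
  NULL
}

# Locate the best (fewest-mismatch) occurrence of an IUPAC primer in each
# read, substitution mismatches only, with at most `max_mm` mismatches.
# Returns a data.frame(start, end, mismatches) with NA where absent.
# side = "left" prefers the leftmost best hit, "right" the rightmost.
.find_primer <- function(reads, primer, max_mm, side = c("left", "right")) {
  side <- match.arg(side)
  res <- data.frame(start = rep(NA_integer_, length(reads)),
                    end = NA_integer_, mismatches = NA_integer_)
  plen <- nchar(primer)
  # fast path: an exact primer occurrence anchored at the read end is
  # provably the best-scoring (0 mismatches) and most-terminal hit
  cls <- vapply(strsplit(toupper(primer), "", fixed = TRUE)[[1]], function(ch) {
    e <- iupac_expand(ch)
    if (length(e) == 1) e else paste0("[", paste(e, collapse = ""), "]")
  }, character(1))
  rx <- paste(cls, collapse = "")
  if (side == "left") {
    hit0 <- grepl(paste0("^", rx), reads)
    res$start[hit0] <- 1L
    res$end[hit0] <- plen
  } else {
    hit0 <- grepl(paste0(rx, "$"), reads)
    L <- nchar(reads[hit0])
    res$start[hit0] <- L - plen + 1L
    res$end[hit0] <- L
  }
  res$mismatches[hit0] <- 0L
  remaining <- which(!hit0)
  if (!length(remaining)) return(res)
  subj <- Biostrings::DNAStringSet(reads)
  # pass with increasing allowed mismatches: first hit at the lowest budget
  # is the best-scoring occurrence
  for (mm in 0:max_mm) {
    if (!length(remaining)) break
    m <- Biostrings::vmatchPattern(primer, subj[remaining], max.mismatch = mm,
                                   with.indels = FALSE, fixed = "subject")
    hit_n <- S4Vectors::elementNROWS(m)
    hit <- which(hit_n > 0)
    if (length(hit)) {
      for (k in hit) {
        ir <- m[[k]]
        pick <- if (side == "left") which.min(BiocGenerics::start(ir))
                else which.max(BiocGenerics::start(ir))
        i <- remaining[k]
        res$start[i] <- BiocGenerics::start(ir)[pick]
        res$end[i] <- BiocGenerics::end(ir)[pick]
        res$mismatches[i] <- mm
      }
      remaining <- remaining[-hit]
    }
  }
  res
}

#' Trim forward and reverse primers from merged reads
#'
#' Both primers must be present (the reverse primer is searched as its
#' reverse complement near the 3' end), each allowing a mismatch budget of
#' `floor(max_mismatch_frac * primer length)` substitutions; IUPAC codes in
#' the primers match their expansions.  Reads missing either primer, or
#' whose insert is shorter than `min_len`, are rejected.
#'
#' @param reads character vector of merged reads
#' @param fwd_primer,rev_primer primer sequences (IUPAC; `rev_primer` given
#'   in primer orientation, as for the wet-lab protocol)
#' @param max_mismatch_frac maximum mismatch fraction per primer (default 0.2)
#' @param min_len minimum insert length in bp (marker-specific: 8 for a
#'   trnL-like marker, 150 for an nrITS2-like marker)
#' @return list with `insert` (character vector of retained inserts),
#'   `kept` (logical index into `reads`) and `reject_reason` (character:
#'   `""`, `"no_fwd_primer"`, `"no_rev_primer"`, `"too_short"`)
#' @export
trim_primers <- function(reads, fwd_primer, rev_primer,
                         max_mismatch_frac = 0.2, min_len = 8) {
  if (!length(reads)) {
    return(list(insert = character(0), kept = logical(0),
                reject_reason = character(0)))
  }
  fwd_mm <- floor(max_mismatch_frac * nchar(fwd_primer))
  rev_mm <- floor(max_mismatch_frac * nchar(rev_primer))
  rev_rc <- revcomp(rev_primer)
  fhit <- .find_primer(reads, fwd_primer, fwd_mm, side = "left")
  rhit <- .find_primer(reads, rev_rc, rev_mm, side = "right")
  reason <- rep("", length(reads))
  reason[is.na(fhit$start)] <- "no_fwd_primer"
  reason[reason == "" & is.na(rhit$start)] <- "no_rev_primer"
  ins_start <- fhit$end + 1L
  ins_end <- rhit$start - 1L
  len <- ins_end - ins_start + 1L
  reason[reason == "" & (len < min_len | rhit$start <= fhit$end)] <- "too_short"
  kept <- reason == ""
  insert <- substr(reads[kept], ins_start[kept], ins_end[kept])
  list(insert = insert, kept = kept, reject_reason = reason)
}

#' Dereplicate reads into unique sequences with per-occurrence counts
#'
#' Exact-sequence grouping; output is sorted by decreasing total abundance
#' with ties broken lexicographically by sequence for determinism.
#'
#' @param reads_by_occurrence named list: occurrence id -> character vector
#'   of reads
#' @return object of class `unique_seqs`: list with `sequence` (character),
#'   `abundance` (total reads per unique) and `counts` (uniques x
#'   occurrences integer matrix)
#' @export
dereplicate <- function(reads_by_occurrence) {
  occ_ids <- names(reads_by_occurrence)
  if (is.null(occ_ids)) stop("reads_by_occurrence must be a named list")
  dt <- data.table::rbindlist(lapply(occ_ids, function(o) {
    r <- reads_by_occurrence[[o]]
    if (!length(r)) return(NULL)
    data.table::data.table(seq = as.character(r), occ = o)
  }))
  if (is.null(dt) || nrow(dt) == 0) {
    return(structure(list(sequence = character(0), abundance = integer(0),
                          counts = matrix(0L, 0, length(occ_ids),
                                          dimnames = list(NULL, occ_ids))),
                     class = "unique_seqs"))
  }
  seq <- occ <- N <- NULL # data.table NSE bindings
  agg <- dt[, .N, by = list(seq, occ)]
  tot <- agg[, list(abundance = sum(N)), by = seq]
  data.table::setorder(tot, -abundance, seq)
  counts <- matrix(0L, nrow(tot), length(occ_ids),
                   dimnames = list(NULL, occ_ids))
  counts[cbind(match(agg$seq, tot$seq), match(agg$occ, occ_ids))] <- agg$N
  structure(list(sequence = tot$seq, abundance = tot$abundance,
                 counts = counts),
            class = "unique_seqs")
}

#' @export
print.unique_seqs <- function(x, ...) {
  cat(sprintf("<unique_seqs n=%d reads=%d occurrences=%d>\n",
              length(x$sequence), sum(x$abundance), ncol(x$counts)))
  invisible(x)
}

# unoise beta(d) = 1 / 2^(alpha * d + 1): maximum abundance skew at which a
# variant at edit distance d is considered an error of a centroid.
unoise_beta <- function(d, alpha = 2) 1 / 2^(alpha * d + 1)

#' Denoise unique sequences into zero-radius OTUs (unoise-style)
#'
#' Uniques with total abundance below `min_abundance` are discarded before
#' clustering (removing singletons and rare errors).  Remaining uniques are
#' processed in decreasing-abundance order: a unique at Levenshtein distance
#' `d >= 1` from an existing centroid `C` is merged into `C` when
#' `abundance(unique) / abundance(C) <= beta(d) = 1 / 2^(alpha d + 1)`,
#' choosing among qualifying centroids the one with the smallest `d`
#' (i.e. the most permissive test), ties going to the most abundant;
#' otherwise the unique founds a new centroid.  Per-occurrence counts of
#' members are added to their centroid.
#'
#' @param uniques a `unique_seqs` object sorted by decreasing abundance
#'   (as produced by [dereplicate()]); unsorted input is rejected
#' @param alpha unoise alpha (default 2.0, the usual default)
#' @param min_abundance minimum total abundance before clustering (default 10)
#' @param detect_chimeras flag centroids whose sequence is an exact
#'   two-segment concatenation of a prefix and a suffix of two more-abundant
#'   centroids (off by default; flagged, not removed)
#' @return object of class `otu_set`: list with `otu` (data.frame: otu_id,
#'   centroid sequence, abundance, chimera flag), `counts` (OTUs x
#'   occurrences matrix) and `members` (list of member unique sequences)
#' @export
denoise_unoise <- function(uniques, alpha = 2, min_abundance = 10,
                           detect_chimeras = FALSE) {
  stopifnot(inherits(uniques, "unique_seqs"))
  if (is.unsorted(rev(uniques$abundance))) {
    stop("uniques must be sorted by decreasing abundance")
  }
  keep <- uniques$abundance >= min_abundance
  seqs <- uniques$sequence[keep]
  ab <- uniques$abundance[keep]
  cnt <- uniques$counts[keep, , drop = FALSE]

  cent_idx <- integer(0)           # indices (into seqs) of centroids
  assign_to <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    merged <- FALSE
    if (length(cent_idx)) {
      # a centroid can only absorb the variant if the skew test holds for
      # some d >= 1; beta(d) is maximal at d = 1, so centroids with
      # ab < ab_i * 2^(alpha + 1) can be skipped without computing distances
      cand_c <- cent_idx[ab[cent_idx] >= ab[i] / unoise_beta(1, alpha)]
      d_all <- rep(NA_integer_, length(cent_idx))
      if (length(cand_c)) {
        d_all[match(cand_c, cent_idx)] <-
          as.integer(utils::adist(seqs[i], seqs[cand_c]))
      }
      d <- d_all
      ok <- !is.na(d) & d >= 1 & (ab[i] / ab[cent_idx]) <= unoise_beta(d, alpha)
      ok[is.na(ok)] <- FALSE
      if (any(ok)) {
        cand <- which(ok)
        cand <- cand[d[cand] == min(d[cand])]
        # ties -> most abundant centroid = earliest in processing order
        best <- cand[which.max(ab[cent_idx[cand]])]
        assign_to[i] <- cent_idx[best]
        merged <- TRUE
      }
    }
    if (!merged) {
      cent_idx <- c(cent_idx, i)
      assign_to[i] <- i
    }
  }

  otu_counts <- rowsum(cnt, group = assign_to, reorder = FALSE)
  ord <- match(as.character(cent_idx), rownames(otu_counts))
  otu_counts <- otu_counts[ord, , drop = FALSE]
  otu_ab <- vapply(cent_idx, function(ci) sum(ab[assign_to == ci]), numeric(1))
  otu_id <- sprintf("OTU_%04d", seq_along(cent_idx))
  rownames(otu_counts) <- otu_id

  chim <- rep(FALSE, length(cent_idx))
  if (detect_chimeras && length(cent_idx) > 2) {
    cs <- seqs[cent_idx]
    is_chimera <- function(i) {
      n <- nchar(cs[i])
      for (a in seq_len(i - 1L)) for (b in seq_len(i - 1L)) {
        if (a == b || cs[i] == cs[a] || cs[i] == cs[b]) next
        for (k in seq_len(n - 1L)) {
          if (startsWith(cs[a], substr(cs[i], 1, k)) &&
              endsWith(cs[b], substr(cs[i], k + 1, n))) return(TRUE)
        }
      }
      FALSE
    }
    for (i in 3:length(cs)) chim[i] <- is_chimera(i)
  }

  structure(list(
    otu = data.frame(otu_id = otu_id, centroid = seqs[cent_idx],
                     abundance = as.numeric(otu_ab), chimera = chim,
                     stringsAsFactors = FALSE),
    counts = otu_counts,
    members = lapply(cent_idx, function(ci) seqs[assign_to == ci])),
    class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat(sprintf("<otu_set otus=%d reads=%.0f>\n", nrow(x$otu), sum(x$counts)))
  invisible(x)
}

#' Process raw reads of one marker into an OTU table
#'
#' Convenience composition used by the pipeline: primer trimming (reads are
#' assumed merged; see [merge_pairs()] for pair merging), dereplication and
#' denoising.
#'
#' @param reads_by_occurrence named list: occurrence id -> reads
#' @param marker a [marker_params()] list
#' @param alpha,min_abundance denoising parameters
#' @return list with `otus` (an `otu_set`), `trim_stats` (reads kept /
#'   rejected per occurrence) and `uniques`
#' @export
process_occurrences <- function(reads_by_occurrence, marker, alpha = 2,
                                min_abundance = 10) {
  trimmed <- list()
  stats <- list()
  for (occ in names(reads_by_occurrence)) {
    tr <- trim_primers(reads_by_occurrence[[occ]], marker$fwd_primer,
                       marker$rev_primer, min_len = marker$min_insert)
    trimmed[[occ]] <- tr$insert
    stats[[occ]] <- data.frame(occurrence_id = occ,
                               input = length(tr$kept),
                               kept = sum(tr$kept),
                               stringsAsFactors = FALSE)
  }
  uniq <- dereplicate(trimmed)
  otus <- denoise_unoise(uniq, alpha = alpha, min_abundance = min_abundance)
  list(otus = otus, trim_stats = do.call(rbind, stats), uniques = uniq)
}
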