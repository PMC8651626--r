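# Contamination filter cascade (steps a-f) with a data-driven tag-jump
# leakage threshold, mirroring the blank-based decontamination used in
# airborne pollen metabarcoding:
#   a) drop OTUs more abundant in blanks/negatives than in real occurrences
#   b) zero cells with < min_reads_per_repeat reads
#   c) solve the leakage threshold on the blanks and apply it everywhere
#   d) drop PCR replicates with < min_repeat_depth reads (a sample is lost
#      when no replicate survives); blank and control occurrences are exempt
#   e) drop OTUs assigned to excluded clades (fungi, bryophytes, green
#      algae) and to listed contaminant taxa
#   f) within each sample with >= 2 surviving replicates, zero OTUs present
#      in fewer than min_replicates_present of them; single-replicate
#      samples skip this step and are flagged

#' Default filter cascade parameters
#'
#' @return named list: `min_reads_per_repeat` (10), `min_repeat_depth`
#'   (3000), `min_replicates_present` (2), `excluded_clades` (fungi,
#'   bryophytes, green algae), `contaminants` (none),
#'   `leakage_denominator` (`"otu_total"`)
#' @export
filter_params <- function(min_reads_per_repeat = 10, min_repeat_depth = 3000,
                          min_replicates_present = 2,
                          excluded_clades = c("fungi", "bryophytes",
                                              "green_algae"),
                          contaminants = character(0),
                          leakage_denominator = c("otu_total",
                                                  "occurrence_total")) {
  list(min_reads_per_repeat = min_reads_per_repeat,
       min_repeat_depth = min_repeat_depth,
       min_replicates_present = min_replicates_present,
       excluded_clades = excluded_clades,
       contaminants = contaminants,
       leakage_denominator = match.arg(leakage_denominator))
}

#' Remove OTUs dominated by blank/negative occurrences (step a)
#'
#' An OTU is removed entirely when its maximum count over extraction-blank
#' and PCR-negative occurrences strictly exceeds its maximum count over all
#' non-blank occurrences (samples and positive controls); ties keep the
#' OTU.
#'
#' @param tab an `occ_table`
#' @return filtered `occ_table`
#' @export
remove_blank_dominant <- function(tab) {
  bl <- blank_ids(tab)
  if (!length(bl)) {
    warning("no blank/negative occurrences: step (a) is the identity")
    return(tab)
  }
  other <- setdiff(colnames(tab$counts), bl)
  bmax <- apply(tab$counts[, bl, drop = FALSE], 1, max)
  smax <- if (length(other)) apply(tab$counts[, other, drop = FALSE], 1, max)
          else rep(0, nrow(tab$counts))
  keep <- !(bmax > smax)
  occurrence_table(tab$counts[keep, , drop = FALSE], tab$sheet)
}

#' Solve the leakage (tag-jump) filtering threshold (step c)
#'
#' Finds the smallest threshold `t*` such that zeroing every count
#' `c <= t * T` removes all reads from blank and negative occurrences.
#' With the per-OTU denominator (`T` = the OTU's total reads across all
#' occurrences) this is `t* = max over (OTU, blank) of c / T`; with the
#' per-occurrence denominator `T` is the occurrence's total reads.
#' `t* = 0` when the blanks are already empty.
#'
#' OTUs whose reads sit entirely in blanks would force `t* = 1` (zeroing
#' everything); they are expected to have been removed by
#' [remove_blank_dominant()] first and trigger a warning.
#'
#' @param tab an `occ_table`
#' @param denominator `"otu_total"` (default, tag-jump convention) or
#'   `"occurrence_total"`
#' @return threshold `t*` (a fraction), with attribute `"flagged"` listing
#'   blank-only OTUs
#' @export
solve_leakage_threshold <- function(tab,
                                    denominator = c("otu_total",
                                                    "occurrence_total")) {
  denominator <- match.arg(denominator)
  bl <- blank_ids(tab)
  if (!length(bl)) stop("table has no blank/negative occurrences")
  bc <- tab$counts[, bl, drop = FALSE]
  if (all(bc == 0)) return(structure(0, flagged = character(0)))
  if (denominator == "otu_total") {
    tot <- rowSums(tab$counts)
    ratio <- bc / tot # tot > 0 wherever bc > 0
  } else {
    occ_tot <- colSums(tab$counts)[bl]
    ratio <- sweep(bc, 2, pmax(occ_tot, 1), "/")
  }
  ratio[bc == 0] <- 0
  flagged <- rownames(tab$counts)[rowSums(tab$counts) > 0 &
                                    rowSums(bc) == rowSums(tab$counts)]
  if (length(flagged)) {
    warning("OTU(s) found entirely in blanks (should have been removed by ",
            "step a): ", paste(flagged, collapse = ", "))
  }
  structure(max(ratio), flagged = flagged)
}

#' Apply a leakage threshold to an occurrence table
#'
#' Zeroes every count `c` with `c <= t * T` where `T` is the OTU's total
#' (or the occurrence's total, depending on `denominator`).
#'
#' @param tab an `occ_table`
#' @param t threshold fraction (as from [solve_leakage_threshold()])
#' @param denominator as in [solve_leakage_threshold()]
#' @return filtered `occ_table`
#' @export
apply_leakage_threshold <- function(tab, t,
                                    denominator = c("otu_total",
                                                    "occurrence_total")) {
  denominator <- match.arg(denominator)
  cnt <- tab$counts
  if (t > 0) {
    # the rule "c <= t * T" is evaluated as "c / T <= t": identical in exact
    # arithmetic and exactly consistent with how t* is solved in floating
    # point (t* is itself a ratio c / T)
    ratio <- if (denominator == "otu_total") {
      cnt / pmax(rowSums(cnt), 1)
    } else {
      sweep(cnt, 2, pmax(colSums(cnt), 1), "/")
    }
    cnt[ratio <= t] <- 0
  }
  occurrence_table(cnt, tab$sheet)
}

#' Run the full contamination filter cascade (steps a-f)
#'
#' @param tab an `occ_table` of OTU (or taxon) counts including blank,
#'   negative and positive-control occurrences
#' @param taxa optional data.frame describing the rows of `tab` (as from
#'   [aggregate_by_assignment()], or an [assign_taxonomy()] result with
#'   `query` matching rownames): needed for step (e); when `NULL`, step (e)
#'   is skipped with a note in the report
#' @param params a [filter_params()] list
#' @return list with `table` (filtered `occ_table`), `report` (a
#'   `filter_report` data.frame: one row per step with OTUs/reads/replicates/
#'   samples removed and the parameters used), `leakage_threshold`, and
#'   `single_replicate_samples` (samples flagged because only one replicate
#'   survived)
#' @export
run_filter_cascade <- function(tab, taxa = NULL, params = filter_params()) {
  report <- list()
  note <- function(step, before, after, extra = "") {
    data.frame(step = step,
               otus_removed = nrow(before$counts) - nrow(after$counts),
               reads_removed = sum(before$counts) - sum(after$counts),
               replicates_removed = ncol(before$counts) - ncol(after$counts),
               samples_removed =
                 length(unique(before$sheet$sample_id[before$sheet$role == "sample"])) -
                 length(unique(after$sheet$sample_id[after$sheet$role == "sample"])),
               parameters = extra, stringsAsFactors = FALSE)
  }
  drop_empty <- function(x) {
    keep <- rowSums(x$counts) > 0
    if (all(keep)) x else occurrence_table(x$counts[keep, , drop = FALSE], x$sheet)
  }

  # (a) blank-dominant OTUs
  before <- tab
  tab <- remove_blank_dominant(tab)
  report$a <- note("a_blank_dominant", before, tab)

  # (b) low-count cells
  before <- tab
  cnt <- tab$counts
  cnt[cnt < params$min_reads_per_repeat] <- 0
  tab <- drop_empty(occurrence_table(cnt, tab$sheet))
  report$b <- note("b_min_reads_per_repeat", before, tab,
                   sprintf("min_reads_per_repeat=%d", params$min_reads_per_repeat))

  # (c) leakage threshold
  before <- tab
  thr <- solve_leakage_threshold(tab, params$leakage_denominator)
  tab <- drop_empty(apply_leakage_threshold(tab, as.numeric(thr),
                                            params$leakage_denominator))
  report$c <- note("c_leakage_threshold", before, tab,
                   sprintf("t=%.3g denominator=%s", as.numeric(thr),
                           params$leakage_denominator))

  # (d) shallow replicates (samples only; blanks/controls exempt)
  before <- tab
  depth <- colSums(tab$counts)
  is_sample <- tab$sheet$role == "sample"
  keep_col <- !is_sample | depth >= params$min_repeat_depth
  tab <- occ_subset_cols(tab, keep_col)
  report$d <- note("d_min_repeat_depth", before, tab,
                   sprintf("min_repeat_depth=%d", params$min_repeat_depth))

  # (e) excluded clades and contaminant taxa
  before <- tab
  if (!is.null(taxa)) {
    # rows of `tab` may be keyed by aggregation key, by OTU id, or by taxon
    idx <- rep(NA_integer_, nrow(tab$counts))
    for (col in c("key", "query", "taxon")) {
      if (!is.null(taxa[[col]]) && anyNA(idx)) {
        miss <- is.na(idx)
        idx[miss] <- match(rownames(tab$counts)[miss], taxa[[col]])
      }
    }
    ti <- taxa[idx, , drop = FALSE]
    bad_clade <- ti$clade %in% params$excluded_clades
    bad_contam <- (ti$species %in% params$contaminants) |
      (ti$genus %in% params$contaminants)
    if (!is.null(ti$taxon)) {
      bad_contam <- bad_contam | ti$taxon %in% params$contaminants
    }
    bad <- bad_clade | bad_contam
    bad[is.na(bad)] <- FALSE
    tab <- occurrence_table(tab$counts[!bad, , drop = FALSE], tab$sheet)
    report$e <- note("e_excluded_taxa", before, tab,
                     sprintf("clades={%s} contaminants=%d",
                             paste(params$excluded_clades, collapse = ","),
                             length(params$contaminants)))
  } else {
    report$e <- note("e_excluded_taxa", before, tab, "skipped: no taxa table")
  }

  # (f) replicate-consensus: OTU must appear in >= min_replicates_present
  # replicates of a sample
  before <- tab
  single_rep <- character(0)
  cnt <- tab$counts
  for (sid in unique(tab$sheet$sample_id[tab$sheet$role == "sample"])) {
    cols <- tab$sheet$occurrence_id[tab$sheet$sample_id == sid &
                                      tab$sheet$role == "sample"]
    if (length(cols) < 2) {
      single_rep <- c(single_rep, sid)
      next
    }
    pres <- rowSums(cnt[, cols, drop = FALSE] > 0)
    zero <- pres > 0 & pres < params$min_replicates_present
    cnt[zero, cols] <- 0
  }
  tab <- drop_empty(occurrence_table(cnt, tab$sheet))
  report$f <- note("f_replicate_consensus", before, tab,
                   sprintf("min_replicates_present=%d%s",
                           params$min_replicates_present,
                           if (length(single_rep))
                             paste0(" single_replicate_samples=",
                                    paste(single_rep, collapse = ","))
                           else ""))

  rep_df <- do.call(rbind, report)
  rownames(rep_df) <- NULL
  class(rep_df) <- c("filter_report", class(rep_df))
  list(table = tab, report = rep_df,
       leakage_threshold = as.numeric(thr),
       single_replicate_samples = single_rep)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Contamination filter cascade report\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Check the positive-control occurrences
#'
#' Passes when the control taxon strictly dominates every positive-control
#' occurrence (> 50% of its reads) and never exceeds the leakage threshold
#' share elsewhere.
#'
#' @param tab an `occ_table` whose rows include the control taxon
#' @param control_taxon row name (taxon or OTU id) of the control
#' @param leakage_threshold threshold fraction used for the "elsewhere"
#'   check (default 0: any control-taxon read outside the controls fails)
#' @return list with `pass` (logical) and `details` (per-occurrence control
#'   fraction data.frame)
#' @export
check_positive_controls <- function(tab, control_taxon,
                                    leakage_threshold = 0) {
  pos <- occ_ids_by_role(tab, "positive_control")
  if (!length(pos)) {
    warning("no positive-control occurrences: check skipped")
    return(list(pass = NA, details = NULL))
  }
  in_rows <- control_taxon %in% rownames(tab$counts)
  ctrl_row <- if (in_rows) tab$counts[control_taxon, ] else
    setNames(rep(0, ncol(tab$counts)), colnames(tab$counts))
  tot <- colSums(tab$counts)
  frac <- ifelse(tot > 0, ctrl_row / tot, 0)
  dominate <- all(frac[pos] > 0.5) && all(tot[pos] > 0)
  ctrl_total <- sum(ctrl_row)
  elsewhere_ok <- all(ctrl_row[setdiff(names(ctrl_row), pos)] <=
                        leakage_threshold * ctrl_total)
  details <- data.frame(occurrence_id = colnames(tab$counts),
                        role = tab$sheet$role,
                        control_fraction = as.numeric(frac),
                        stringsAsFactors = FALSE)
  list(pass = isTRUE(dominate && elsewhere_ok), details = details)
}
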