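# The central data container: integer read counts of features (OTUs or
# aggregated taxa) x occurrences, where an occurrence is one PCR replicate
# of a sample or a control, labelled with a role.

OCCURRENCE_ROLES <- c("sample", "extraction_blank", "pcr_negative",
                      "positive_control")

#' Construct an occurrence table
#'
#' @param counts integer matrix, rows = features (OTUs or taxa, rownames
#'   required), columns = occurrences (colnames required, matching the
#'   sample sheet)
#' @param sheet data.frame sample sheet with columns `occurrence_id`,
#'   `sample_id`, `replicate`, `role` (one of sample / extraction_blank /
#'   pcr_negative / positive_control) and optionally `site`, `season`,
#'   `date`
#' @return object of class `occ_table`
#' @export
occurrence_table <- function(counts, sheet) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double" # integer-valued; double avoids overflow
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts needs row and column names")
  }
  need <- c("occurrence_id", "sample_id", "replicate", "role")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(sheet$occurrence_id)) stop("occurrence ids must be unique")
  bad <- setdiff(unique(sheet$role), OCCURRENCE_ROLES)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (!setequal(colnames(counts), sheet$occurrence_id)) {
    stop("counts columns and sample sheet occurrence ids must match")
  }
  sheet <- sheet[match(colnames(counts), sheet$occurrence_id), , drop = FALSE]
  rownames(sheet) <- NULL
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, sheet = sheet), class = "occ_table")
}

#' @export
print.occ_table <- function(x, ...) {
  cat(sprintf("<occ_table features=%d occurrences=%d samples=%d reads=%.0f>\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$sheet$sample_id[x$sheet$role == "sample"])),
              sum(x$counts)))
  invisible(x)
}

#' @export
dim.occ_table <- function(x) dim(x$counts)

# Column subset that keeps counts and sheet in step.
occ_subset_cols <- function(tab, keep) {
  occurrence_table(tab$counts[, keep, drop = FALSE],
                   tab$sheet[tab$sheet$occurrence_id %in%
                               colnames(tab$counts[, keep, drop = FALSE]), ,
                             drop = FALSE])
}

# Occurrence ids by role.
occ_ids_by_role <- function(tab, roles) {
  tab$sheet$occurrence_id[tab$sheet$role %in% roles]
}

blank_ids <- function(tab) {
  occ_ids_by_role(tab, c("extraction_blank", "pcr_negative"))
}

#' Write / read an occurrence table (counts TSV + sample sheet TSV)
#'
#' @param tab an `occ_table`
#' @param counts_tsv,sheet_tsv file paths
#' @return paths invisibly / an `occ_table`
#' @export
write_occurrence_table <- function(tab, counts_tsv, sheet_tsv) {
  df <- data.frame(feature_id = rownames(tab$counts), tab$counts,
                   check.names = FALSE)
  write_tsv(df, counts_tsv)
  write_tsv(tab$sheet, sheet_tsv)
  invisible(c(counts = counts_tsv, sheet = sheet_tsv))
}

#' @rdname write_occurrence_table
#' @export
read_occurrence_table <- function(counts_tsv, sheet_tsv) {
  df <- read_tsv(counts_tsv)
  if (names(df)[1] != "feature_id") stop("first column must be feature_id")
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$feature_id
  occurrence_table(counts, read_tsv(sheet_tsv))
}
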