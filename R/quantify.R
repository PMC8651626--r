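# Semi-quantitative comparison of relative read abundances (RRA) against
# microscopic pollen concentrations: replicate averaging, normalisation,
# morphotype mapping and least-squares regression per target taxon plus a
# combined fit over all abundant morphotypes.

#' Convert a cleaned occurrence table to relative read abundances
#'
#' Per sample: counts are averaged across the surviving PCR replicates of
#' that sample, then divided by the sample's total mean count.  Only
#' occurrences with role `"sample"` enter; blanks and controls are dropped
#' before normalisation.  Samples with zero total are dropped with a
#' warning.
#'
#' @param tab an `occ_table`
#' @return matrix of RRA values, rows = samples, columns = features; every
#'   row sums to 1
#' @export
to_rra <- function(tab) {
  sam <- tab$sheet[tab$sheet$role == "sample", , drop = FALSE]
  if (!nrow(sam)) stop("no sample occurrences")
  ids <- unique(sam$sample_id)
  out <- matrix(0, length(ids), nrow(tab$counts),
                dimnames = list(ids, rownames(tab$counts)))
  for (i in seq_along(ids)) {
    cols <- sam$occurrence_id[sam$sample_id == ids[i]]
    out[i, ] <- rowMeans(tab$counts[, cols, drop = FALSE])
  }
  tot <- rowSums(out)
  if (any(tot == 0)) {
    warning("dropping sample(s) with zero reads: ",
            paste(ids[tot == 0], collapse = ", "))
    out <- out[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  sweep(out, 1, tot, "/")
}

#' Sum RRA columns into microscope morphotypes
#'
#' Every column of `rra` must be covered by the map (possibly mapping to
#' `"other"`); row sums are preserved exactly.
#'
#' @param rra samples x taxa matrix (as from [to_rra()])
#' @param map data.frame with columns `taxon`, `morphotype`
#' @return samples x morphotypes matrix
#' @export
map_to_morphotypes <- function(rra, map) {
  m <- setNames(map$morphotype, map$taxon)
  cols <- colnames(rra)
  # unassigned rows ("unassigned:<id>") fall back to "other" only if the
  # map carries an explicit "other" convention; otherwise reject
  mt <- m[cols]
  unk <- is.na(mt) & startsWith(cols, "unassigned:")
  mt[unk] <- "other"
  if (anyNA(mt)) {
    stop("morphotype map is not total; unmapped taxa: ",
         paste(cols[is.na(mt)], collapse = ", "))
  }
  t(rowsum(t(rra), group = as.character(mt), reorder = TRUE))
}

#' Ordinary least-squares fit of paired relative abundances
#'
#' Fits `y ~ x` (with intercept) and reports slope, intercept, R-squared and
#' the two-sided p-value of the slope from its t statistic on n - 2 degrees
#' of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`
#' @export
least_squares_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("zero variance in x: slope undefined")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit)) # exact fits warn inside summary.lm
  if (stats::var(y) == 0) { # constant response: slope 0, no variance explained
    return(list(slope = 0, intercept = unname(mean(y)), r_squared = 0,
                p_value = 1, n = n))
  }
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]), n = n)
}

# Microscope long table -> samples x morphotypes relative-abundance matrix.
microscope_relabund <- function(microscope) {
  need <- c("sample_id", "morphotype", "concentration")
  if (!all(need %in% names(microscope))) {
    stop("microscope table needs columns: ", paste(need, collapse = ", "))
  }
  wide <- tapply(microscope$concentration,
                 list(microscope$sample_id, microscope$morphotype), sum)
  wide[is.na(wide)] <- 0
  tot <- rowSums(wide)
  if (any(tot == 0)) wide <- wide[tot > 0, , drop = FALSE]
  sweep(wide, 1, rowSums(wide), "/")
}

#' Regression report: RRA versus microscopic relative abundances
#'
#' Microscope concentrations are converted to per-sample relative
#' abundances; molecular RRA tables (one per marker) are mapped to
#' morphotypes.  For each target morphotype and marker, paired
#' (microscope relabund, RRA) points across shared samples are fitted with
#' [least_squares_fit()].  The combined fit pools, per marker, all
#' (sample, morphotype) points whose microscope relative abundance exceeds
#' `combined_min_frac`.
#'
#' @param rra_by_marker named list of RRA matrices (samples x taxa), one per
#'   marker
#' @param microscope long data.frame (`sample_id`, `morphotype`,
#'   `concentration`)
#' @param map morphotype map data.frame (`taxon`, `morphotype`)
#' @param targets character vector of target morphotypes; default: all
#'   morphotypes reaching `combined_min_frac` in some sample
#' @param combined_min_frac microscope relative-abundance cut for the
#'   combined fit (default 0.05, i.e. the "> 5%" rule)
#' @return data.frame with one row per (target or "combined", marker):
#'   `target`, `marker`, `slope`, `intercept`, `r_squared`, `p_value`, `n`
#' @export
quantification_report <- function(rra_by_marker, microscope, map,
                                  targets = NULL, combined_min_frac = 0.05) {
  micro <- microscope_relabund(microscope)
  rows <- list()
  for (mk in names(rra_by_marker)) {
    rra_mt <- map_to_morphotypes(rra_by_marker[[mk]], map)
    shared <- intersect(rownames(rra_mt), rownames(micro))
    if (!length(shared)) stop("no shared samples between RRA and microscope")
    mts <- union(colnames(rra_mt), colnames(micro))
    X <- matrix(0, length(shared), length(mts), dimnames = list(shared, mts))
    Y <- X
    X[, colnames(micro)] <- micro[shared, , drop = FALSE]
    Y[, colnames(rra_mt)] <- rra_mt[shared, , drop = FALSE]
    tg <- targets %||% setdiff(colnames(X)[apply(X, 2, max) > combined_min_frac],
                               "other")
    for (t in tg) {
      if (!t %in% colnames(X)) next
      f <- try(least_squares_fit(X[, t], Y[, t]), silent = TRUE)
      if (inherits(f, "try-error")) next
      rows[[length(rows) + 1L]] <- data.frame(
        target = t, marker = mk, slope = f$slope, intercept = f$intercept,
        r_squared = f$r_squared, p_value = f$p_value, n = f$n,
        stringsAsFactors = FALSE)
    }
    sel <- which(X > combined_min_frac, arr.ind = TRUE)
    sel <- sel[colnames(X)[sel[, 2]] != "other", , drop = FALSE]
    if (nrow(sel) >= 3) {
      f <- least_squares_fit(X[sel], Y[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        target = "combined", marker = mk, slope = f$slope,
        intercept = f$intercept, r_squared = f$r_squared,
        p_value = f$p_value, n = f$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
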