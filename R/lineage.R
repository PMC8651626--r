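# Ranked lineages and the lowest-common-ancestor operation.
#
# A lineage is a row with four ranks (clade, family, genus, species); empty
# strings mark unresolved ranks.  Non-empty ranks must form a prefix: a
# species implies a genus, which implies a family, which implies a clade.

LINEAGE_RANKS <- c("clade", "family", "genus", "species")

#' Construct a table of ranked lineages
#'
#' @param clade,family,genus,species character vectors (recycled); use `""`
#'   for unresolved ranks.  Non-empty ranks must form a prefix from clade
#'   downwards.
#' @return a `data.frame` with columns `clade`, `family`, `genus`, `species`.
#' @examples
#' lineage("seed_plants", "Betulaceae", "Alnus", "Alnus glutinosa")
#' @export
lineage <- function(clade = "", family = "", genus = "", species = "") {
  out <- data.frame(clade = as.character(clade), family = as.character(family),
                    genus = as.character(genus), species = as.character(species),
                    stringsAsFactors = FALSE)
  validate_lineage(out)
  out
}

validate_lineage <- function(lin) {
  stopifnot(all(LINEAGE_RANKS %in% names(lin)))
  m <- as.matrix(lin[, LINEAGE_RANKS]) != ""
  # non-empty ranks must be a prefix: no TRUE after a FALSE
  ok <- apply(m, 1, function(r) !any(diff(as.integer(r)) > 0))
  if (!all(ok)) {
    stop("invalid lineage: non-empty ranks must form a prefix (rows ",
         paste(which(!ok), collapse = ", "), ")")
  }
  invisible(lin)
}

#' Depth of a lineage (number of resolved ranks)
#'
#' @param lin lineage data.frame
#' @return integer vector: 0 (unresolved) to 4 (species level)
#' @export
lineage_depth <- function(lin) {
  rowSums(as.matrix(lin[, LINEAGE_RANKS, drop = FALSE]) != "")
}

#' Truncate lineages at a given rank
#'
#' @param lin lineage data.frame
#' @param rank one of `"clade"`, `"family"`, `"genus"`, `"species"`, or
#'   `"unassigned"` (blanks everything)
#' @return lineage data.frame with ranks below `rank` set to `""`
#' @export
truncate_lineage <- function(lin, rank) {
  out <- lin
  keep <- if (identical(rank, "unassigned")) 0L else match(rank, LINEAGE_RANKS)
  if (is.na(keep)) stop("unknown rank: ", rank)
  drop <- LINEAGE_RANKS[seq_along(LINEAGE_RANKS) > keep]
  out[, drop] <- ""
  out
}

#' Lowest common ancestor of a set of lineages
#'
#' Returns the deepest-rank lineage on which all inputs agree; ranks below
#' the first disagreement (or first unresolved rank) are emptied.
#' Disagreement already at the clade level yields a fully empty lineage,
#' which downstream code treats as unassigned.
#'
#' @param lineages data.frame of lineages (one per row); must be non-empty
#' @return a single-row lineage data.frame
#' @examples
#' lca(rbind(
#'   lineage("seed_plants", "Betulaceae", "Alnus", "Alnus glutinosa"),
#'   lineage("seed_plants", "Betulaceae", "Alnus", "Alnus incana")))
#' @export
lca <- function(lineages) {
  if (nrow(lineages) == 0L) stop("lca() needs at least one lineage")
  out <- lineage("", "", "", "")
  for (rank in LINEAGE_RANKS) {
    vals <- unique(lineages[[rank]])
    if (length(vals) == 1L && nzchar(vals)) out[[rank]] <- vals else break
  }
  out
}

# Single string key for a (rank-truncated) lineage, used for aggregation.
lineage_key <- function(lin) {
  apply(as.matrix(lin[, LINEAGE_RANKS, drop = FALSE]), 1, function(r) {
    paste(r[nzchar(r)], collapse = ";")
  })
}

# Deepest resolved taxon name (or "" when fully unresolved).
lineage_label <- function(lin) {
  m <- as.matrix(lin[, LINEAGE_RANKS, drop = FALSE])
  apply(m, 1, function(r) {
    nz <- r[nzchar(r)]
    if (length(nz)) nz[length(nz)] else ""
  })
}
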