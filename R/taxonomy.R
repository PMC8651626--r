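# Dual-database taxonomic assignment: local-priority hit filtering,
# tied-max-score lowest common ancestor, identity-tier rank capping, and
# aggregation of OTUs sharing an assignment.
#
# Identity tiers follow common metabarcoding practice: >= 97% identity may
# support a species-level call, >= 90% genus, >= 80% family; hits below 80%
# are discarded.  Coverage gates are marker-specific: a short trnL-like
# marker requires exact 100% query cover, an nrITS2-like marker accepts
# >= 90% (tolerating partial reference records).

TIER_SPECIES <- 97
TIER_GENUS <- 90
TIER_FAMILY <- 80

# Deepest rank allowed by a percent identity.
identity_tier_rank <- function(identity) {
  ifelse(identity >= TIER_SPECIES, "species",
         ifelse(identity >= TIER_GENUS, "genus",
                ifelse(identity >= TIER_FAMILY, "family", "unassigned")))
}

rank_depth <- function(rank) {
  d <- match(rank, LINEAGE_RANKS)
  d[is.na(d)] <- 0L
  d
}

# Filter a hit table by the marker coverage gate and the family identity
# floor.  coverage_min == 100 is an exact gate (coverage must equal 100).
filter_hits <- function(hits, coverage_min) {
  if (coverage_min >= 100) keep <- hits$coverage >= 100
  else keep <- hits$coverage >= coverage_min
  keep <- keep & hits$identity >= TIER_FAMILY
  hits[keep, , drop = FALSE]
}

# Assignment for one query from its (already computed) hit tables.
.assign_one <- function(hits_local, hits_global, db_local, db_global,
                        coverage_min) {
  unassigned <- data.frame(lineage(), rank = "unassigned",
                           best_identity = NA_real_, db_scope = "",
                           stringsAsFactors = FALSE)
  pick <- function(hits, db, scope) {
    hits <- filter_hits(hits, coverage_min)
    if (!nrow(hits)) return(NULL)
    top <- hits[hits$score == max(hits$score), , drop = FALSE]
    lin <- db$lineage[match(top$subject, db$ids), , drop = FALSE]
    if (anyNA(lin$species)) stop("hit subject absent from reference database")
    anc <- lca(lin)
    best_id <- max(top$identity)
    cap <- identity_tier_rank(best_id)
    depth <- min(lineage_depth(anc), rank_depth(cap))
    rank <- if (depth == 0L) "unassigned" else LINEAGE_RANKS[depth]
    out <- truncate_lineage(anc, if (depth == 0L) "unassigned"
                            else LINEAGE_RANKS[depth])
    data.frame(out, rank = rank, best_identity = best_id, db_scope = scope,
               stringsAsFactors = FALSE)
  }
  res <- pick(hits_local, db_local, "local")
  if (is.null(res) && !is.null(db_global)) {
    res <- pick(hits_global, db_global, "global")
  }
  res %||% unassigned
}

#' Assign taxonomy to query sequences against local and global databases
#'
#' Hits are computed against the local database first ([align_identity()]
#' scoring); hits failing the marker coverage gate or below 80% identity are
#' dropped.  If any local hit survives, the global database is ignored
#' (local priority); otherwise the identical procedure runs on the global
#' database.  Among surviving hits, those sharing the maximum alignment
#' score form the candidate set; their lowest common ancestor is computed
#' and the final rank is the shallower of the LCA depth and the tier allowed
#' by the best candidate identity (>= 97 species, >= 90 genus, >= 80
#' family).  Queries with no surviving hit in either database are
#' `unassigned`.
#'
#' @param queries character vector of OTU centroid sequences (named with
#'   OTU ids, or ids supplied via `query_ids`)
#' @param local_db,global_db [ref_db] objects (`global_db` may be `NULL`)
#' @param marker a [marker_params()] list (only `coverage_min` is used here)
#' @param query_ids optional query identifiers
#' @return data.frame of assignments: one row per query with columns
#'   `query`, `clade`, `family`, `genus`, `species`, `rank`,
#'   `best_identity`, `db_scope`
#' @export
assign_taxonomy <- function(queries, local_db, global_db = NULL, marker,
                            query_ids = NULL) {
  if (length(local_db) == 0L) stop("local database is empty")
  query_ids <- query_ids %||% names(queries) %||%
    sprintf("Q%04d", seq_along(queries))
  hl <- db_hits(queries, local_db, query_ids = query_ids)
  hg <- if (!is.null(global_db)) db_hits(queries, global_db,
                                         query_ids = query_ids) else NULL
  assign_from_hits(query_ids, hl, hg, local_db, global_db, marker)
}

#' Assign taxonomy from precomputed hit tables
#'
#' The alternative input path for users with real BLAST tabular output
#' (see [read_hit_table()]).  Semantics are identical to
#' [assign_taxonomy()].
#'
#' @param query_ids character vector of query ids to assign
#' @param hits_local,hits_global hit data.frames (`query`, `subject`,
#'   `identity`, `coverage`, `score`)
#' @param local_db,global_db [ref_db] objects supplying lineages
#' @param marker a [marker_params()] list
#' @return as [assign_taxonomy()]
#' @export
assign_from_hits <- function(query_ids, hits_local, hits_global = NULL,
                             local_db, global_db = NULL, marker) {
  out <- lapply(query_ids, function(q) {
    hl <- hits_local[hits_local$query == q, , drop = FALSE]
    hg <- if (!is.null(hits_global)) {
      hits_global[hits_global$query == q, , drop = FALSE]
    } else hits_local[0, , drop = FALSE]
    .assign_one(hl, hg, local_db, global_db, marker$coverage_min)
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(query = query_ids, stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}

#' Aggregate OTU counts by shared taxonomic assignment
#'
#' Rows (OTUs) sharing the same truncated lineage and rank are summed per
#' occurrence; unassigned OTUs are kept as individual rows flagged
#' `unassigned:<otu id>`.  Aggregation conserves per-occurrence totals
#' exactly.
#'
#' @param counts OTU x occurrence count matrix (rownames = OTU ids)
#' @param assignments data.frame from [assign_taxonomy()] with `query`
#'   matching the rownames of `counts`
#' @return list with `counts` (taxon x occurrence matrix, rownames =
#'   lineage keys) and `taxa` (data.frame describing each row)
#' @export
aggregate_by_assignment <- function(counts, assignments) {
  idx <- match(rownames(counts), assignments$query)
  if (anyNA(idx)) stop("every OTU needs an assignment")
  asg <- assignments[idx, , drop = FALSE]
  key <- ifelse(asg$rank == "unassigned",
                paste0("unassigned:", asg$query),
                lineage_key(asg))
  agg <- rowsum(counts, group = key, reorder = TRUE)
  first <- asg[!duplicated(key), , drop = FALSE]
  first_key <- key[!duplicated(key)]
  taxa <- first[match(rownames(agg), first_key), , drop = FALSE]
  taxa$taxon <- ifelse(taxa$rank == "unassigned",
                       paste0("unassigned:", taxa$query),
                       lineage_label(taxa))
  taxa$key <- rownames(agg)
  rownames(taxa) <- NULL
  list(counts = agg, taxa = taxa)
}
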