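# Synthetic reference databases with hierarchical sequence divergence.
#
# Emulates the study design of a local (country-level) reference database
# plus a broader global one: sequences are generated by mutating a shared
# root per family, per genus and per species so that expected pairwise
# identities fall into the bands used by the identity-tier assignment rules
# (within-genus >= 97%, between genera within a family 90-96%, between
# families 80-89%).

#' Reference database constructor
#'
#' @param ids character record ids (unique)
#' @param lineage data.frame of full species-level lineages, one per record
#' @param sequences character DNA sequences over ACGT
#' @param scope `"local"` or `"global"`
#' @return an object of class `ref_db`
#' @export
ref_db <- function(ids, lineage, sequences, scope = c("local", "global")) {
  scope <- match.arg(scope)
  stopifnot(length(ids) == nrow(lineage), length(ids) == length(sequences))
  if (anyDuplicated(ids)) stop("reference record ids must be unique")
  if (!all(lineage_depth(lineage) == 4L)) {
    stop("every reference record needs a full species-level lineage")
  }
  structure(list(ids = as.character(ids), lineage = lineage,
                 sequences = as.character(sequences), scope = scope),
            class = "ref_db")
}

#' @export
print.ref_db <- function(x, ...) {
  cat(sprintf("<ref_db scope=%s records=%d families=%d genera=%d species=%d>\n",
              x$scope, length(x$ids), length(unique(x$lineage$family)),
              length(unique(x$lineage$genus)), length(unique(x$lineage$species))))
  invisible(x)
}

#' @export
length.ref_db <- function(x) length(x$ids)

#' Generate a matched local/global reference database pair
#'
#' Sequences are produced by mutating a single root sequence along a
#' family -> genus -> species hierarchy.  Default divergence rates are
#' calibrated (see the methods vignette) so that at `seq_length >= 300`
#' within-genus species pairs sit at ~99% identity (band >= 97%), congeneric
#' genera at ~93% (band 90-96%) and families at ~84.5% (band 80-89%).
#' The global database is the local one plus taxa absent locally: one extra
#' species per genus, one extra family, and (optionally) a few non-seed-plant
#' taxa (fungi, bryophytes, green algae) that exercise the clade exclusion
#' filter.
#'
#' @param n_families,n_genera_per_family,n_species_per_genus positive counts
#' @param seq_length sequence length in bp (>= 60)
#' @param seed integer seed; the same seed reproduces the databases exactly
#' @param divergence named numeric: per-base substitution probability applied
#'   at the `family`, `genus` and `species` branching steps.  Must be strictly
#'   decreasing family > genus > species, otherwise the identity bands are
#'   impossible and the call is rejected.
#' @param include_nontarget add fungal/bryophyte/green-algal records to the
#'   global database
#' @return `list(local =, global =)` of [ref_db] objects
#' @examples
#' dbs <- generate_reference_sets(2, 2, 2, seq_length = 300, seed = 7)
#' dbs$local
#' @export
generate_reference_sets <- function(n_families, n_genera_per_family,
                                    n_species_per_genus, seq_length = 300,
                                    seed = 1,
                                    divergence = c(family = 0.047,
                                                   genus = 0.030,
                                                   species = 0.005),
                                    include_nontarget = TRUE) {
  stopifnot(n_families >= 1, n_genera_per_family >= 1, n_species_per_genus >= 1)
  if (seq_length < 60) {
    stop("seq_length must be >= 60: identity bands are impossible for ",
         "shorter sequences")
  }
  dv <- divergence[c("family", "genus", "species")]
  if (anyNA(dv) || any(dv < 0)) stop("divergence needs family/genus/species rates")
  if (!(dv[["family"]] > dv[["genus"]] && dv[["genus"]] > dv[["species"]])) {
    stop("impossible band configuration: divergence must decrease ",
         "family > genus > species")
  }

  with_seed(seed, {
    root <- random_dna(1, seq_length)
    build <- function(fam_idx, gen_range, sp_range, clade = "seed_plants",
                      fam_name = NULL) {
      recs <- list()
      for (fi in fam_idx) {
        fam <- fam_name %||% sprintf("Family%02d", fi)
        fam_seq <- mutate_seq(root, dv[["family"]])
        for (gi in gen_range) {
          gen <- sprintf("%s_Genus%02d", fam, gi)
          gen_seq <- mutate_seq(fam_seq, dv[["genus"]])
          for (si in sp_range) {
            sp <- sprintf("%s sp%02d", gen, si)
            recs[[length(recs) + 1L]] <- list(
              id = gsub("[^A-Za-z0-9_]", "_", sp),
              lin = lineage(clade, fam, gen, sp),
              seq = mutate_seq(gen_seq, dv[["species"]]))
          }
        }
      }
      recs
    }

    # local database: the full crossed design
    local_recs <- build(seq_len(n_families), seq_len(n_genera_per_family),
                        seq_len(n_species_per_genus))

    # global extras: one additional species per genus and one extra family.
    # The extra species must branch from each genus root; regenerate the
    # hierarchy deterministically by reusing the same stream is not possible,
    # so extras get their own family/genus roots for the extra family and,
    # for per-genus extras, a sibling derived from an existing species by a
    # genus-level mutation away from it (stays within the genus band).
    extra_recs <- list()
    for (r in local_recs) {
      if (endsWith(r$lin$species, "sp01")) { # one extra per genus
        sp <- sub("sp01$", sprintf("sp%02d", n_species_per_genus + 1L),
                  r$lin$species)
        extra_recs[[length(extra_recs) + 1L]] <- list(
          id = gsub("[^A-Za-z0-9_]", "_", sp),
          lin = lineage(r$lin$clade, r$lin$family, r$lin$genus, sp),
          seq = mutate_seq(r$seq, 2 * dv[["species"]]))
      }
    }
    extra_recs <- c(extra_recs,
                    build(n_families + 1L, 1L, seq_len(min(2L, n_species_per_genus))))

    if (include_nontarget) {
      for (cl in c("fungi", "bryophytes", "green_algae")) {
        nt_root <- random_dna(1, seq_length) # unrelated to the plant root
        fam <- sprintf("%s_Fam01", cl)
        gen <- sprintf("%s_Genus01", fam)
        sp <- sprintf("%s sp01", gen)
        extra_recs[[length(extra_recs) + 1L]] <- list(
          id = gsub("[^A-Za-z0-9_]", "_", sp),
          lin = lineage(cl, fam, gen, sp),
          seq = mutate_seq(nt_root, dv[["species"]]))
      }
    }

    to_db <- function(recs, scope) {
      ref_db(ids = vapply(recs, `[[`, character(1), "id"),
             lineage = do.call(rbind, lapply(recs, `[[`, "lin")),
             sequences = vapply(recs, `[[`, character(1), "seq"),
             scope = scope)
    }
    list(local = to_db(local_recs, "local"),
         global = to_db(c(local_recs, extra_recs), "global"))
  })
}

#' Write / read a reference database as FASTA + lineage TSV
#'
#' @param db a [ref_db]
#' @param fasta,lineage_tsv file paths
#' @return `write_ref_db()` returns the paths invisibly; `read_ref_db()`
#'   returns a [ref_db].
#' @export
write_ref_db <- function(db, fasta, lineage_tsv) {
  write_fasta(setNames(db$sequences, db$ids), fasta)
  write_tsv(cbind(data.frame(record_id = db$ids), db$lineage), lineage_tsv)
  invisible(c(fasta = fasta, lineage = lineage_tsv))
}

#' @rdname write_ref_db
#' @param scope database scope for the object read back
#' @export
read_ref_db <- function(fasta, lineage_tsv, scope = "local") {
  seqs <- read_fasta(fasta)
  lin <- read_tsv(lineage_tsv)
  need <- c("record_id", LINEAGE_RANKS)
  if (!all(need %in% names(lin))) {
    stop("lineage TSV must have columns: ", paste(need, collapse = ", "))
  }
  lin <- lin[match(names(seqs), lin$record_id), , drop = FALSE]
  if (anyNA(lin$record_id)) stop("lineage TSV is missing records present in FASTA")
  for (r in LINEAGE_RANKS) lin[[r]][is.na(lin[[r]])] <- ""
  ref_db(names(seqs), lin[, LINEAGE_RANKS], unname(seqs), scope = scope)
}
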