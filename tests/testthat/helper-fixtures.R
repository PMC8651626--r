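# Shared fixtures and independent brute-force oracles.  Oracles re-derive
# every decision from scratch (no shared code paths with the greedy /
# vectorised implementations they check).

# A small hand-written reference database with real-world-style lineages.
tiny_db <- function(scope = "local") {
  lin <- rbind(
    lineage("seed_plants", "Betulaceae", "Alnus", "Alnus glutinosa"),
    lineage("seed_plants", "Betulaceae", "Alnus", "Alnus incana"),
    lineage("seed_plants", "Cupressaceae", "Cupressus", "Cupressus arizonica"),
    lineage("seed_plants", "Cupressaceae", "Juniperus", "Juniperus communis"),
    lineage("seed_plants", "Urticaceae", "Urtica", "Urtica dioica"))
  seqs <- with_seed_helper(42, {
    base <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    vapply(c(0, 2, 12, 14, 30), function(k) mutate_n(base, k), character(1))
  })
  ref_db(ids = paste0("ref", seq_len(5)), lineage = lin, sequences = seqs,
         scope = scope)
}

with_seed_helper <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

# Substitute exactly k distinct positions of a sequence.
mutate_n <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Random occurrence table with blanks carrying small "leaked" counts.
random_occ_table <- function(seed, n_otu = 12, n_samples = 4, n_rep = 3,
                             n_blank = 3) {
  with_seed_helper(seed, {
    occ <- c(as.vector(outer(sprintf("S%d", 1:n_samples),
                             sprintf("_r%d", 1:n_rep), paste0)),
             sprintf("B%d_r1", seq_len(n_blank)))
    roles <- c(rep("sample", n_samples * n_rep),
               rep(c("extraction_blank", "pcr_negative"),
                   length.out = n_blank))
    sheet <- data.frame(
      occurrence_id = occ,
      sample_id = c(rep(sprintf("S%d", 1:n_samples), n_rep),
                    sprintf("B%d", seq_len(n_blank))),
      replicate = c(rep(1:n_rep, each = n_samples), rep(1L, n_blank)),
      role = roles, stringsAsFactors = FALSE)
    cnt <- matrix(rpois(n_otu * length(occ), 400), n_otu,
                  dimnames = list(sprintf("OTU%02d", seq_len(n_otu)), occ))
    blanks <- occ[roles != "sample"]
    cnt[, blanks] <- matrix(rbinom(n_otu * length(blanks), 6, 0.5),
                            n_otu)
    occurrence_table(cnt, sheet)
  })
}

# Brute-force leakage-threshold oracle: grid search over every observed
# blank ratio, picking the smallest that zeroes all blanks.
oracle_threshold <- function(tab) {
  bl <- tab$sheet$occurrence_id[tab$sheet$role %in%
                                  c("extraction_blank", "pcr_negative")]
  tot <- rowSums(tab$counts)
  ratios <- sort(unique(c(0, as.vector(tab$counts[, bl, drop = FALSE] /
                                         pmax(tot, 1)))))
  for (t in ratios) {
    cnt <- tab$counts
    cnt[cnt / pmax(tot, 1) <= t] <- 0 # rule applied in ratio form
    if (all(cnt[, bl] == 0)) return(t)
  }
  1
}

# Brute-force unoise oracle: re-derives beta(d) per pair and replays the
# greedy pass with a full precomputed distance matrix.
oracle_denoise <- function(uniques, alpha = 2, min_abundance = 10) {
  keep <- uniques$abundance >= min_abundance
  seqs <- uniques$sequence[keep]
  ab <- uniques$abundance[keep]
  n <- length(seqs)
  if (n == 0) return(list(centroids = character(0), assign = integer(0)))
  D <- as.matrix(utils::adist(seqs))
  cent <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    best <- NA_integer_
    best_d <- Inf
    for (c in cent) {
      d <- D[i, c]
      if (d >= 1 && ab[i] / ab[c] <= 1 / 2^(alpha * d + 1)) {
        if (d < best_d || (d == best_d && ab[c] > ab[best])) {
          best <- c; best_d <- d
        }
      }
    }
    if (is.na(best)) { cent <- c(cent, i); assign[i] <- i }
    else assign[i] <- best
  }
  list(centroids = seqs[cent], assign = assign)
}

# Brute-force assignment oracle: enumerate hits, filter, max, LCA, cap.
oracle_assign <- function(query, local_db, global_db, coverage_min) {
  score_all <- function(db) {
    do.call(rbind, lapply(seq_along(db$ids), function(j) {
      a <- align_identity(query, db$sequences[j])
      data.frame(j = j, identity = a$identity, coverage = a$coverage,
                 score = a$score)
    }))
  }
  tier <- function(idy) {
    if (idy >= 97) 4L else if (idy >= 90) 3L else if (idy >= 80) 2L else 0L
  }
  try_db <- function(db, scope) {
    h <- score_all(db)
    ok <- h$identity >= 80 &
      (if (coverage_min >= 100) h$coverage >= 100 else h$coverage >= coverage_min)
    h <- h[ok, , drop = FALSE]
    if (!nrow(h)) return(NULL)
    top <- h[h$score == max(h$score), , drop = FALSE]
    lin <- db$lineage[top$j, , drop = FALSE]
    anc <- lin[1, , drop = FALSE]
    for (r in c("clade", "family", "genus", "species")) {
      if (length(unique(lin[[r]])) > 1) {
        ri <- match(r, c("clade", "family", "genus", "species"))
        anc[, c("clade", "family", "genus", "species")[ri:4]] <- ""
        break
      }
    }
    depth <- sum(anc != "")
    depth <- min(depth, tier(max(top$identity)))
    ranks <- c("clade", "family", "genus", "species")
    if (depth < 4) anc[, ranks[(depth + 1):4]] <- ""
    rank <- if (depth == 0) "unassigned" else ranks[depth]
    list(lineage = anc, rank = rank, best_identity = max(top$identity),
         scope = scope)
  }
  r <- try_db(local_db, "local")
  if (is.null(r) && !is.null(global_db)) r <- try_db(global_db, "global")
  r %||% list(lineage = lineage(), rank = "unassigned",
              best_identity = NA_real_, scope = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hit-level assignment oracle: same decision logic as oracle_assign but
# taking precomputed hit tables, so large query batches stay affordable.
# Filtering, score ties, LCA and tier capping are re-derived from scratch.
oracle_assign_hits <- function(q, hits_local, hits_global, db_local,
                               db_global, coverage_min) {
  tier <- function(idy) {
    if (idy >= 97) 4L else if (idy >= 90) 3L else if (idy >= 80) 2L else 0L
  }
  ranks <- c("clade", "family", "genus", "species")
  try_hits <- function(h, db, scope) {
    h <- h[h$query == q, , drop = FALSE]
    ok <- h$identity >= 80 &
      (if (coverage_min >= 100) h$coverage >= 100 else h$coverage >= coverage_min)
    h <- h[ok, , drop = FALSE]
    if (!nrow(h)) return(NULL)
    top <- h[h$score == max(h$score), , drop = FALSE]
    lin <- db$lineage[match(top$subject, db$ids), , drop = FALSE]
    anc <- lin[1, , drop = FALSE]
    for (r in ranks) {
      if (length(unique(lin[[r]])) > 1) {
        ri <- match(r, ranks); anc[, ranks[ri:4]] <- ""; break
      }
    }
    depth <- min(sum(anc != ""), tier(max(top$identity)))
    if (depth < 4) anc[, ranks[(depth + 1):4]] <- ""
    list(lineage = anc,
         rank = if (depth == 0) "unassigned" else ranks[depth],
         scope = scope)
  }
  r <- try_hits(hits_local, db_local, "local")
  if (is.null(r) && !is.null(db_global)) {
    r <- try_hits(hits_global, db_global, "global")
  }
  r %||% list(lineage = lineage(), rank = "unassigned", scope = "")
}

# Direct, loop-based perMANOVA statistic (independent of the matrix
# formulation used by the package).
oracle_permanova_f <- function(d, groups) {
  n <- nrow(d)
  a <- length(unique(groups))
  ss_total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    if (length(idx) > 1) {
      for (ii in 1:(length(idx) - 1)) for (jj in (ii + 1):length(idx)) {
        s <- s + d[idx[ii], idx[jj]]^2
      }
    }
    ss_within <- ss_within + s / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# Small simulated dataset (counts only) shared by filtering/quantify tests.
quick_sim <- function(seed = 1, emit_reads = FALSE, ...) {
  args <- utils::modifyList(list(n_samples_per_cell = 2, n_pcr_negatives = 3,
                                 depth_mean = 4000, seed = seed),
                            list(...))
  design <- do.call(study_design, args)
  dbs <- list(
    trnL = generate_reference_sets(4, 4, 3, seq_length = 80,
                                   seed = seed + 1000),
    nrITS2 = generate_reference_sets(4, 4, 3, seq_length = 300,
                                     seed = seed + 2000))
  list(design = design, dbs = dbs,
       sim = simulate_dataset(design, dbs, emit_reads = emit_reads))
}

# occ_table from simulated species-level template counts of one marker.
sim_occ_table <- function(sim_obj, marker = "nrITS2") {
  occurrence_table(sim_obj$sim$template_counts[[marker]], sim_obj$sim$sheet)
}

# taxa descriptor for sim_occ_table rows (species-level rows).
sim_taxa <- function(sim_obj, marker = "nrITS2") {
  db <- sim_obj$dbs[[marker]]$global
  sp <- rownames(sim_obj$sim$template_counts[[marker]])
  lin <- db$lineage[match(sp, db$lineage$species), , drop = FALSE]
  data.frame(query = sp, lin, rank = "species", taxon = sp,
             key = sp, stringsAsFactors = FALSE)
}
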