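# Synthetic aerobiological dataset generator.
#
# Emulates a two-site, two-season airborne pollen metabarcoding study:
# per-sample true species proportions (Dirichlet around site/season-shifted
# community profiles), per-species log-normal amplification bias with
# marker-specific variance (larger for the plastid-like marker),
# Dirichlet-multinomial PCR-replicate overdispersion, per-base read errors,
# tag-jump-like leakage of reads into blank occurrences, sample-level food
# contaminants and non-target (fungal etc.) spikes, positive controls
# containing only a designated control taxon, and multinomial microscope
# counting at morphotype resolution.

#' Marker model parameters
#'
#' Defaults describe a short plastid trnL-P6-loop-like marker (tiny inserts,
#' strict 100% coverage gate, high amplification-bias variance) and a longer
#' nrITS2-like marker (>= 150 bp inserts, 90% coverage gate, low bias
#' variance).  Primer sequences are the published trnL g/h and ITS-p3/ITS4
#' primers.
#'
#' @param name marker label
#' @param fwd_primer,rev_primer primer sequences (IUPAC allowed)
#' @param min_insert minimum insert length after trimming (bp)
#' @param coverage_min minimum hit coverage accepted during assignment;
#'   100 means "exact full cover required"
#' @param bias_sd std. dev. of the per-species log amplification factor
#' @param seq_length reference sequence length for this marker (bp)
#' @return named list of marker parameters
#' @export
marker_params <- function(name, fwd_primer, rev_primer, min_insert,
                          coverage_min, bias_sd, seq_length) {
  stopifnot(min_insert >= 1, coverage_min > 0, coverage_min <= 100,
            bias_sd >= 0, seq_length >= 60)
  list(name = name, fwd_primer = fwd_primer, rev_primer = rev_primer,
       min_insert = min_insert, coverage_min = coverage_min,
       bias_sd = bias_sd, seq_length = seq_length)
}

#' @rdname marker_params
#' @export
default_markers <- function() {
  list(
    trnL = marker_params("trnL", "GGGCAATCCTGAGCCAA", "CCATTGAGTCTCTGCACCTATC",
                         min_insert = 8, coverage_min = 100, bias_sd = 0.8,
                         seq_length = 80),
    nrITS2 = marker_params("nrITS2", "YGACTCTCGGCAACGGATA", "TCCTCCGCTTATTGATATGC",
                           min_insert = 150, coverage_min = 90, bias_sd = 0.2,
                           seq_length = 300))
}

#' Study design for the synthetic dataset
#'
#' Defaults mirror the emulated study at desk scale: 2 sites x 2 seasons,
#' 24 samples with 3 PCR replicates each, ~5000 reads per replicate, a
#' 40-species pool, 2 extraction blanks, 7 PCR negatives and 2 positive
#' controls.
#'
#' @param sites,seasons factor labels
#' @param n_samples_per_cell samples per (site, season) cell
#' @param n_replicates PCR replicates per sample (>= 1)
#' @param n_extraction_blanks,n_pcr_negatives,n_positive_controls control
#'   occurrence counts
#' @param n_species_pool number of species in the airborne pool
#' @param base_log_sd std. dev. of the log community profile across species
#' @param site_effect_sd,season_effect_sd std. dev. of per-species log shifts
#'   distinguishing sites / seasons
#' @param theta_sample Dirichlet concentration of per-sample proportions
#'   around the cell profile (larger = less sample-to-sample variation)
#' @param rep_concentration Dirichlet-multinomial concentration of
#'   PCR-replicate overdispersion (paper-silent free parameter; see vignette)
#' @param depth_mean,depth_sdlog per-replicate read depth: log-normal with
#'   this mean and log-sd
#' @param error_rate per-base substitution probability of reads, in \[0, 0.05\]
#' @param leakage_rate fraction of each occurrence's reads redistributed into
#'   blank occurrences, in \[0, 1\]
#' @param n_contaminants number of food-contaminant species (drawn from the
#'   local database, outside the pool)
#' @param contam_prob,contam_mean probability a sample is contaminated and
#'   mean contaminant reads per replicate
#' @param nontarget_prob,nontarget_mean probability of a non-target (fungal)
#'   spike per sample and its mean reads per replicate
#' @param control_species species used for positive controls (default: first
#'   local species outside the pool); positive controls contain only it
#' @param grains_counted pollen grains counted per microscope sample
#' @param conc_meanlog,conc_sdlog total pollen concentration per sample
#'   (pollen/m3/24h): log-normal parameters
#' @param markers list of [marker_params()] models
#' @param seed root seed; all randomness derives from it
#' @return object of class `study_design`
#' @export
study_design <- function(sites = c("West", "SouthEast"),
                         seasons = c("spring", "fall"),
                         n_samples_per_cell = 6, n_replicates = 3,
                         n_extraction_blanks = 2, n_pcr_negatives = 7,
                         n_positive_controls = 2, n_species_pool = 40,
                         base_log_sd = 1.5, site_effect_sd = 0.5,
                         season_effect_sd = 1.5, theta_sample = 50,
                         rep_concentration = 200, depth_mean = 5000,
                         depth_sdlog = 0.2, error_rate = 0.001,
                         leakage_rate = 5e-4, n_contaminants = 2,
                         contam_prob = 0.25, contam_mean = 30,
                         nontarget_prob = 0.2, nontarget_mean = 40,
                         control_species = NULL, grains_counted = 500,
                         conc_meanlog = log(1000), conc_sdlog = 0.5,
                         markers = default_markers(), seed = 1) {
  stopifnot(n_replicates >= 1, n_samples_per_cell >= 1,
            error_rate >= 0, error_rate <= 0.05,
            leakage_rate >= 0, leakage_rate <= 1,
            contam_prob >= 0, contam_prob <= 1,
            nontarget_prob >= 0, nontarget_prob <= 1,
            theta_sample > 0, rep_concentration > 0, depth_mean > 0,
            grains_counted >= 1)
  d <- as.list(environment())
  class(d) <- "study_design"
  d
}

# Sample sheet for a design: one row per occurrence.
design_sheet <- function(design) {
  cells <- expand.grid(site = design$sites, season = design$seasons,
                       stringsAsFactors = FALSE)
  n_samples <- nrow(cells) * design$n_samples_per_cell
  samp <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    site = rep(cells$site, each = design$n_samples_per_cell),
    season = rep(cells$season, each = design$n_samples_per_cell),
    stringsAsFactors = FALSE)
  # synthetic collection dates: spring = Feb-May, fall = Jul-Sep, 2019/2020
  day_pool <- function(season, i) {
    months <- if (season == "spring") c("02", "03", "04", "05") else c("07", "08", "09")
    sprintf("%d-%s-%02d", 2019 + (i %% 2), months[1 + (i %% length(months))],
            1 + (i * 7) %% 28)
  }
  samp$date <- mapply(day_pool, samp$season, seq_len(nrow(samp)))
  rows <- list()
  for (i in seq_len(nrow(samp))) {
    for (r in seq_len(design$n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        occurrence_id = sprintf("%s_r%d", samp$sample_id[i], r),
        sample_id = samp$sample_id[i], replicate = r, role = "sample",
        site = samp$site[i], season = samp$season[i], date = samp$date[i],
        stringsAsFactors = FALSE)
    }
  }
  ctrl <- function(prefix, n, role) {
    if (n == 0) return(NULL)
    data.frame(occurrence_id = sprintf("%s%d_r1", prefix, seq_len(n)),
               sample_id = sprintf("%s%d", prefix, seq_len(n)),
               replicate = 1L, role = role, site = "", season = "", date = "",
               stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(
    ctrl("EB", design$n_extraction_blanks, "extraction_blank"),
    ctrl("NEG", design$n_pcr_negatives, "pcr_negative"),
    ctrl("POS", design$n_positive_controls, "positive_control"))))
}

#' Simulate a full synthetic dataset
#'
#' @param design a [study_design()]
#' @param ref_dbs named list, one entry per marker in `design$markers`, each
#'   a `list(local =, global =)` as returned by [generate_reference_sets()].
#'   A single db pair is recycled across markers.
#' @param emit_reads also generate read sequences (needed to run the
#'   amplicon-processing stage; set `FALSE` for fast count-level simulations)
#' @return a list of class `aeropollen_sim` with elements `sheet` (sample
#'   sheet), `template_counts` (per marker: species x occurrence matrix of
#'   true read counts, post leakage), `reads` (per marker: named list of
#'   character vectors per occurrence; `NULL` unless `emit_reads`),
#'   `microscope` (long data.frame: sample_id, morphotype, concentration),
#'   `morphotype_map` (taxon -> morphotype data.frame), `truth` (ground
#'   truth: true proportions, bias factors, leakage rate, contaminant and
#'   control ids) and `design`.
#' @export
simulate_dataset <- function(design, ref_dbs, emit_reads = TRUE) {
  stopifnot(inherits(design, "study_design"))
  if (!is.null(ref_dbs$local)) ref_dbs <- list(ref_dbs) # single pair given
  marker_names <- names(design$markers)
  if (is.null(names(ref_dbs)) || !all(marker_names %in% names(ref_dbs))) {
    ref_dbs <- setNames(rep(ref_dbs, length.out = length(marker_names)),
                        marker_names)
  }
  local0 <- ref_dbs[[1]]$local
  species_local <- local0$lineage$species
  if (length(species_local) < design$n_species_pool + 1 + design$n_contaminants) {
    stop("local database too small for pool + control + contaminants")
  }

  sheet <- design_sheet(design)
  sample_rows <- sheet[sheet$role == "sample", , drop = FALSE]
  samples <- unique(sample_rows[, c("sample_id", "site", "season")])

  with_seed(derive_seed(design$seed, "community"), {
    # the positive-control taxon mimics a non-native marker species (the
    # Citrus japonica analogue): its whole genus is reserved out of the
    # airborne pool so short markers cannot cross-assign pool reads to it
    control_sp <- design$control_species %||%
      sort(species_local)[length(species_local)]
    if (!control_sp %in% c(species_local, ref_dbs[[1]]$global$lineage$species)) {
      stop("control species not present in the reference databases")
    }
    ctrl_genus <- local0$lineage$genus[match(control_sp,
                                             local0$lineage$species)]
    candidates <- species_local[is.na(ctrl_genus) |
                                  local0$lineage$genus != ctrl_genus]
    if (length(candidates) < design$n_species_pool + design$n_contaminants) {
      stop("local database too small for pool + contaminants outside the ",
           "control genus")
    }
    pool <- sort(sample(candidates, design$n_species_pool))
    rest <- setdiff(candidates, pool)
    contaminants <- rest[seq_len(design$n_contaminants)]
    nontarget_sp <- ref_dbs[[1]]$global$lineage$species[
      ref_dbs[[1]]$global$lineage$clade != "seed_plants"]

    base_log <- rnorm(length(pool), 0, design$base_log_sd)
    cell_props <- list()
    for (st in design$sites) for (se in design$seasons) {
      shift <- rnorm(length(pool), 0, design$site_effect_sd) +
        rnorm(length(pool), 0, design$season_effect_sd)
      p <- exp(base_log + shift)
      cell_props[[paste(st, se, sep = "|")]] <- p / sum(p)
    }
    true_props <- matrix(0, nrow(samples), length(pool),
                         dimnames = list(samples$sample_id, pool))
    for (i in seq_len(nrow(samples))) {
      cp <- cell_props[[paste(samples$site[i], samples$season[i], sep = "|")]]
      g <- rgamma(length(pool), shape = design$theta_sample * cp)
      if (sum(g) == 0) g[which.max(cp)] <- 1
      true_props[i, ] <- g / sum(g)
    }
  })

  morphotype_map <- build_morphotype_map(ref_dbs)

  # ground-truth occurrence counts per marker (species x occurrence)
  all_species <- c(pool, contaminants, control_sp, nontarget_sp)
  template_counts <- list()
  bias <- list()
  for (m in marker_names) {
    mk <- design$markers[[m]]
    cnt <- with_seed(derive_seed(design$seed, paste0("counts_", m)), {
      b <- setNames(exp(rnorm(length(all_species), 0, mk$bias_sd)), all_species)
      bias[[m]] <- b
      simulate_marker_counts(design, sheet, samples, true_props, pool,
                             contaminants, control_sp, nontarget_sp, b)
    })
    template_counts[[m]] <- cnt
  }

  microscope <- with_seed(derive_seed(design$seed, "microscope"), {
    simulate_microscope(design, samples, true_props, morphotype_map)
  })

  reads <- NULL
  if (emit_reads) {
    reads <- list()
    for (m in marker_names) {
      mk <- design$markers[[m]]
      db_seqs <- c(setNames(ref_dbs[[m]]$local$sequences,
                            ref_dbs[[m]]$local$lineage$species),
                   setNames(ref_dbs[[m]]$global$sequences,
                            ref_dbs[[m]]$global$lineage$species))
      db_seqs <- db_seqs[!duplicated(names(db_seqs))]
      fwd <- iupac_realize(mk$fwd_primer)
      rev3 <- revcomp(iupac_realize(mk$rev_primer))
      templates <- paste0(fwd, db_seqs[rownames(template_counts[[m]])], rev3)
      names(templates) <- rownames(template_counts[[m]])
      reads[[m]] <- with_seed(derive_seed(design$seed, paste0("reads_", m)), {
        lapply(setNames(colnames(template_counts[[m]]),
                        colnames(template_counts[[m]])), function(occ) {
          cnt <- template_counts[[m]][, occ]
          mutate_reads(templates, cnt, design$error_rate,
                       seed = NULL) # already inside a seeded scope
        })
      })
    }
  }

  truth <- list(true_props = true_props, bias = bias,
                leakage_rate = design$leakage_rate,
                contaminants = contaminants, control_species = control_sp,
                nontarget_species = nontarget_sp, pool = pool)
  structure(list(sheet = sheet, template_counts = template_counts,
                 reads = reads, microscope = microscope,
                 morphotype_map = morphotype_map, truth = truth,
                 design = design),
            class = "aeropollen_sim")
}

# Species x occurrence ground-truth counts for one marker (runs inside a
# seeded scope).  Applies amplification bias, Dirichlet-multinomial replicate
# overdispersion, contaminant/non-target spikes, positive controls, and
# binomial leakage into blanks.
simulate_marker_counts <- function(design, sheet, samples, true_props, pool,
                                   contaminants, control_sp, nontarget_sp,
                                   bias) {
  all_species <- names(bias)
  counts <- matrix(0, length(all_species), nrow(sheet),
                   dimnames = list(all_species, sheet$occurrence_id))

  contam_hit <- setNames(runif(nrow(samples)) < design$contam_prob,
                         samples$sample_id)
  nontgt_hit <- setNames(runif(nrow(samples)) < design$nontarget_prob,
                         samples$sample_id)

  for (i in seq_len(nrow(sheet))) {
    occ <- sheet$occurrence_id[i]
    role <- sheet$role[i]
    if (role %in% c("extraction_blank", "pcr_negative")) next
    depth <- max(1L, round(rlnorm(1, log(design$depth_mean), design$depth_sdlog)))
    if (role == "positive_control") {
      counts[control_sp, occ] <- depth
      next
    }
    sid <- sheet$sample_id[i]
    p <- true_props[sid, ] * bias[pool]
    p <- p / sum(p)
    g <- rgamma(length(p), shape = design$rep_concentration * p)
    if (sum(g) == 0) g[which.max(p)] <- 1
    counts[pool, occ] <- rmultinom(1, depth, g / sum(g))[, 1]
    if (contam_hit[sid] && length(contaminants)) {
      counts[contaminants, occ] <- counts[contaminants, occ] +
        rpois(length(contaminants), design$contam_mean)
    }
    if (nontgt_hit[sid] && length(nontarget_sp)) {
      spike_sp <- nontarget_sp[1 + (match(sid, samples$sample_id) %% length(nontarget_sp))]
      counts[spike_sp, occ] <- counts[spike_sp, occ] +
        rpois(1, design$nontarget_mean)
    }
  }

  # tag-jump-like leakage: binomial thinning of every non-blank occurrence,
  # leaked reads land uniformly on blank occurrences
  blanks <- sheet$occurrence_id[sheet$role %in% c("extraction_blank", "pcr_negative")]
  if (design$leakage_rate > 0 && length(blanks)) {
    nonblank <- setdiff(sheet$occurrence_id, blanks)
    for (occ in nonblank) {
      c_occ <- counts[, occ]
      pos <- which(c_occ > 0)
      if (!length(pos)) next
      leak <- rbinom(length(pos), c_occ[pos], design$leakage_rate)
      take <- which(leak > 0)
      for (k in take) {
        sp <- pos[k]
        counts[sp, occ] <- counts[sp, occ] - leak[k]
        dest <- rmultinom(1, leak[k], rep(1 / length(blanks), length(blanks)))[, 1]
        counts[sp, blanks] <- counts[sp, blanks] + dest
      }
    }
  }
  counts
}

# Multinomial microscope counting at morphotype resolution.
simulate_microscope <- function(design, samples, true_props, morphotype_map) {
  map <- setNames(morphotype_map$morphotype, morphotype_map$taxon)
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    p <- true_props[i, ]
    mt <- map[colnames(true_props)]
    p_mt <- tapply(p, mt, sum)
    cnt <- rmultinom(1, design$grains_counted, p_mt)[, 1]
    total <- rlnorm(1, design$conc_meanlog, design$conc_sdlog)
    conc <- cnt / design$grains_counted * total
    rows[[i]] <- data.frame(sample_id = samples$sample_id[i],
                            morphotype = names(p_mt),
                            concentration = as.numeric(conc),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the taxon -> morphotype map implied by the reference databases
#'
#' The microscope resolves most pollen to genus, but the first family of the
#' local database is treated as stenopalynous: all its species collapse to a
#' single `"<family>-type"` morphotype (the Cupressaceae/Taxaceae analogue).
#' Family-level labels of other families, clade labels and anything
#' unresolved map to `"other"`.
#'
#' @param ref_dbs as in [simulate_dataset()]
#' @return data.frame with columns `taxon`, `morphotype`
#' @export
build_morphotype_map <- function(ref_dbs) {
  if (!is.null(ref_dbs$local)) ref_dbs <- list(ref_dbs)
  lin <- unique(do.call(rbind, lapply(ref_dbs, function(p) {
    rbind(p$local$lineage, p$global$lineage)
  })))
  steno_family <- sort(unique(lin$family[lin$clade == "seed_plants"]))[1]
  rows <- list()
  add <- function(taxon, morphotype) {
    rows[[length(rows) + 1L]] <<- data.frame(taxon = taxon,
                                             morphotype = morphotype,
                                             stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(lin))) {
    plant <- lin$clade[i] == "seed_plants"
    mt_gen <- if (!plant) "other"
      else if (lin$family[i] == steno_family) paste0(steno_family, "-type")
      else lin$genus[i]
    add(lin$species[i], mt_gen)
    add(lin$genus[i], mt_gen)
    add(lin$family[i],
        if (plant && lin$family[i] == steno_family) paste0(steno_family, "-type")
        else "other")
    add(lin$clade[i], "other")
  }
  out <- unique(do.call(rbind, rows))
  if (anyDuplicated(out$taxon)) {
    out <- out[!duplicated(out$taxon), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Expand templates into error-bearing reads
#'
#' Each template is replicated according to `counts` and every base is
#' substituted independently with probability `error_rate`.  Read names
#' record the template of origin.
#'
#' @param templates named character vector of template sequences
#' @param counts integer vector of copies per template (recycled to
#'   `length(templates)`); `NULL` means one read per template
#' @param error_rate per-base substitution probability in \[0, 0.05\]
#' @param seed integer seed, or `NULL` to use the current RNG state
#' @return character vector of reads, named `<template>_<k>`
#' @export
mutate_reads <- function(templates, counts = NULL, error_rate, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 0.05)
  run <- function() {
    counts <- counts %||% rep(1L, length(templates))
    counts <- rep(counts, length.out = length(templates))
    keep <- counts > 0
    reads <- rep(templates[keep], counts[keep])
    if (!length(reads)) return(character(0))
    nm <- rep(names(templates)[keep] %||%
                as.character(seq_along(templates))[keep], counts[keep])
    names(reads) <- paste0(nm, "_", sequence(counts[keep]))
    if (error_rate > 0) {
      L <- nchar(reads)
      n_err <- rbinom(length(reads), L, error_rate)
      idx <- which(n_err > 0)
      if (length(idx)) {
        bases <- c("A", "C", "G", "T")
        mut <- vapply(idx, function(i) {
          ch <- strsplit(reads[[i]], "", fixed = TRUE)[[1]]
          pos <- sample.int(length(ch), n_err[i])
          for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
          paste(ch, collapse = "")
        }, character(1))
        reads[idx] <- mut
      }
    }
    reads
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Write a simulated dataset to plain-text files
#'
#' Writes one FASTA of reads per occurrence per marker, the sample sheet,
#' the microscope table, the morphotype map and the ground truth (JSON).
#'
#' @param sim an `aeropollen_sim`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(sim$sheet, file.path(dir, "sample_sheet.tsv"))
  write_tsv(sim$microscope, file.path(dir, "microscope.tsv"))
  write_tsv(sim$morphotype_map, file.path(dir, "morphotype_map.tsv"))
  for (m in names(sim$template_counts)) {
    cdir <- file.path(dir, "reads", m)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(sim$reads)) {
      for (occ in names(sim$reads[[m]])) {
        rr <- sim$reads[[m]][[occ]]
        if (!length(rr)) rr <- setNames(character(0), character(0))
        write_fasta(rr, file.path(cdir, paste0(occ, ".fasta")))
      }
    }
    df <- data.frame(feature_id = rownames(sim$template_counts[[m]]),
                     sim$template_counts[[m]], check.names = FALSE)
    write_tsv(df, file.path(dir, paste0("template_counts_", m, ".tsv")))
  }
  truth <- sim$truth
  truth$true_props <- as.data.frame(truth$true_props)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}
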