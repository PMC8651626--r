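# End-to-end orchestration: simulate -> process -> assign -> filter ->
# quantify -> compare, driven by a single declarative config (R list or
# JSON file), with per-stage outputs, a reproducibility manifest and a
# non-destructive input validator.

#' Default pipeline configuration
#'
#' Every field can be overridden via a nested list or a JSON config file;
#' unknown keys are rejected.  All randomness derives from `seed`.
#'
#' @param out_dir output directory
#' @param seed root seed
#' @return nested named list of class `run_config`
#' @export
pipeline_config <- function(out_dir = tempfile("aeropollen_run_"), seed = 1) {
  cfg <- list(
    out_dir = out_dir,
    seed = seed,
    simulate = list(
      enabled = TRUE,
      write_files = FALSE,
      db = list(n_families = 5, n_genera_per_family = 4,
                n_species_per_genus = 3),
      design = list()), # overrides for study_design()
    input = list(                # used when simulate$enabled = FALSE
      reads_dir = NULL, sample_sheet = NULL, microscope = NULL,
      morphotype_map = NULL, references = NULL),
    denoise = list(alpha = 2, min_abundance = 10),
    filter = list(min_reads_per_repeat = 10, min_repeat_depth = 3000,
                  min_replicates_present = 2,
                  excluded_clades = c("fungi", "bryophytes", "green_algae"),
                  contaminants = character(0),
                  leakage_denominator = "otu_total"),
    quantify = list(combined_min_frac = 0.05),
    compare = list(n_perm = 999, nmds_starts = 20, factors = c("site", "season")))
  class(cfg) <- c("run_config", "list")
  cfg
}

# Merge user overrides into the default config, rejecting unknown keys.
merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    full <- if (nzchar(path)) paste0(path, "$", k) else k
    if (!k %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], override[[k]], full)
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a pipeline configuration
#'
#' @param config `NULL` (defaults), a nested list of overrides, a
#'   `run_config`, or the path to a JSON file of overrides
#' @param out_dir,seed defaults passed to [pipeline_config()]
#' @return a validated `run_config`
#' @export
load_config <- function(config = NULL, out_dir = tempfile("aeropollen_run_"),
                        seed = 1) {
  base <- pipeline_config(out_dir = out_dir, seed = seed)
  if (is.null(config)) return(base)
  if (inherits(config, "run_config")) return(config)
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- merge_config(unclass(base), config)
  class(cfg) <- c("run_config", "list")
  cfg
}

stage_log <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

#' Run the full pipeline
#'
#' Executes simulate (optional) -> process -> assign -> filter -> quantify
#' -> compare; every stage writes its outputs under `out_dir` and the
#' manifest records md5 checksums of all written files, so a rerun with an
#' identical config reproduces identical checksums.
#'
#' @param config see [load_config()]
#' @return the run manifest (list), invisibly; side effect: TSV/JSON
#'   outputs under `config$out_dir`
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    write_tsv(x, p)
    written <<- c(written, p)
    p
  }
  result <- list()

  # ---- simulate ----
  if (isTRUE(cfg$simulate$enabled)) {
    stage_log("stage simulate")
    design <- do.call(study_design,
                      c(cfg$simulate$design, list(seed = derive_seed(cfg$seed, "design"))))
    ref_dbs <- list()
    for (m in names(design$markers)) {
      ref_dbs[[m]] <- generate_reference_sets(
        cfg$simulate$db$n_families, cfg$simulate$db$n_genera_per_family,
        cfg$simulate$db$n_species_per_genus,
        seq_length = design$markers[[m]]$seq_length,
        seed = derive_seed(cfg$seed, paste0("refdb_", m)))
    }
    sim <- simulate_dataset(design, ref_dbs, emit_reads = TRUE)
    sheet <- sim$sheet
    microscope <- sim$microscope
    morphotype_map <- sim$morphotype_map
    reads <- sim$reads
    markers <- design$markers
    # the synthetic truth supplies the contaminant exclusion list and the
    # positive-control taxon, standing in for the analyst's curated lists
    if (!length(cfg$filter$contaminants)) {
      cfg$filter$contaminants <- sim$truth$contaminants
    }
    control_taxon <- sim$truth$control_species
    emit(sheet, "sample_sheet.tsv")
    emit(microscope, "microscope.tsv")
    emit(morphotype_map, "morphotype_map.tsv")
    if (isTRUE(cfg$simulate$write_files)) write_dataset(sim, file.path(cfg$out_dir, "sim"))
    result$truth <- sim$truth
  } else {
    stage_log("stage load inputs")
    inp <- cfg$input
    need <- c("reads_dir", "sample_sheet", "microscope", "morphotype_map",
              "references")
    if (any(vapply(inp[need], is.null, logical(1)))) {
      stop("simulate disabled: config$input needs ",
           paste(need, collapse = ", "))
    }
    sheet <- read_tsv(inp$sample_sheet)
    microscope <- read_tsv(inp$microscope)
    morphotype_map <- read_tsv(inp$morphotype_map)
    markers <- default_markers()
    ref_dbs <- list()
    for (m in names(inp$references)) {
      r <- inp$references[[m]]
      ref_dbs[[m]] <- list(
        local = read_ref_db(r$local_fasta, r$local_lineage, "local"),
        global = read_ref_db(r$global_fasta, r$global_lineage, "global"))
    }
    markers <- markers[names(ref_dbs)]
    reads <- list()
    for (m in names(ref_dbs)) {
      files <- list.files(file.path(inp$reads_dir, m), pattern = "\\.fa(sta)?$",
                          full.names = TRUE)
      reads[[m]] <- setNames(lapply(files, read_fasta),
                             sub("\\.fa(sta)?$", "", basename(files)))
    }
    control_taxon <- NULL
  }

  # ---- process + assign + filter + quantify, per marker ----
  rra_by_marker <- list()
  filtered <- list()
  for (m in names(reads)) {
    stage_log("stage process: ", m)
    proc <- process_occurrences(reads[[m]], markers[[m]],
                                alpha = cfg$denoise$alpha,
                                min_abundance = cfg$denoise$min_abundance)
    otus <- proc$otus
    emit(data.frame(otu_id = otus$otu$otu_id, abundance = otus$otu$abundance,
                    chimera = otus$otu$chimera, centroid = otus$otu$centroid),
         sprintf("otus_%s.tsv", m))

    stage_log("stage assign: ", m)
    asg <- assign_taxonomy(otus$otu$centroid, ref_dbs[[m]]$local,
                           ref_dbs[[m]]$global, markers[[m]],
                           query_ids = otus$otu$otu_id)
    emit(asg, sprintf("assignments_%s.tsv", m))
    agg <- aggregate_by_assignment(otus$counts, asg)

    stage_log("stage filter: ", m)
    # occurrences never observed for this marker get zero columns
    cnt <- matrix(0, nrow(agg$counts), nrow(sheet),
                  dimnames = list(rownames(agg$counts), sheet$occurrence_id))
    shared_cols <- intersect(colnames(agg$counts), sheet$occurrence_id)
    cnt[, shared_cols] <- agg$counts[, shared_cols]
    tab <- occurrence_table(cnt, sheet)
    fp <- do.call(filter_params, cfg$filter)
    fc <- run_filter_cascade(tab, agg$taxa, fp)
    filtered[[m]] <- fc
    emit(fc$report, sprintf("filter_report_%s.tsv", m))
    ft <- fc$table
    emit(data.frame(feature_id = rownames(ft$counts), ft$counts,
                    check.names = FALSE), sprintf("filtered_counts_%s.tsv", m))

    if (!is.null(control_taxon)) {
      # the control OTU may have been capped at genus rank; fall back to the
      # genus-level row when no species-level row matches
      key <- agg$taxa$key[match(control_taxon, agg$taxa$species)]
      if (is.na(key)) {
        ctrl_genus <- sub(" sp.*$", "", control_taxon)
        hit <- which(agg$taxa$genus == ctrl_genus & agg$taxa$species == "")
        key <- if (length(hit)) agg$taxa$key[hit[1]] else control_taxon
      }
      chk <- check_positive_controls(ft, key,
                                     leakage_threshold = fc$leakage_threshold)
      result$positive_controls[[m]] <- chk$pass
    }

    stage_log("stage quantify: ", m)
    rra <- to_rra(ft)
    colnames(rra) <- agg$taxa$taxon[match(colnames(rra), agg$taxa$key)]
    rra_by_marker[[m]] <- rra
  }

  quant <- quantification_report(rra_by_marker, microscope, morphotype_map,
                                 combined_min_frac = cfg$quantify$combined_min_frac)
  emit(quant, "quantification.tsv")
  result$quantification <- quant

  # ---- compare ----
  stage_log("stage compare")
  comp_rows <- list()
  for (m in names(rra_by_marker)) {
    rra_mt <- map_to_morphotypes(rra_by_marker[[m]], morphotype_map)
    d <- bray_curtis(rra_mt)
    emit(data.frame(sample_id = rownames(d), d, check.names = FALSE),
         sprintf("bray_curtis_%s.tsv", m))
    meta <- sheet[sheet$role == "sample", , drop = FALSE]
    meta <- unique(meta[, c("sample_id", intersect(cfg$compare$factors,
                                                   names(meta)))])
    meta <- meta[match(rownames(d), meta$sample_id), , drop = FALSE]
    for (f in intersect(cfg$compare$factors, names(meta))) {
      tabf <- table(meta[[f]])
      if (length(tabf) < 2 || any(tabf < 2)) {
        # filtering left a degenerate grouping; record, do not abort
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          marker = m, factor = f, f_stat = NA_real_, r_squared = NA_real_,
          p_value = NA_real_, n_perm = 0L, stringsAsFactors = FALSE)
        next
      }
      pm <- permanova(d, meta[[f]], n_perm = cfg$compare$n_perm,
                      seed = derive_seed(cfg$seed, paste0("perm_", m, "_", f)))
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        marker = m, factor = f, f_stat = pm$f, r_squared = pm$r_squared,
        p_value = pm$p_value, n_perm = pm$n_perm, stringsAsFactors = FALSE)
    }
    nm <- nmds(d, k = 2, n_starts = cfg$compare$nmds_starts,
               seed = derive_seed(cfg$seed, paste0("nmds_", m)))
    emit(data.frame(sample_id = rownames(nm$points), NMDS1 = nm$points[, 1],
                    NMDS2 = nm$points[, 2], stress = nm$stress),
         sprintf("nmds_%s.tsv", m))
  }
  comp <- do.call(rbind, comp_rows)
  emit(comp, "permanova.tsv")
  result$permanova <- comp

  # ---- manifest ----
  cfg_hashable <- unclass(cfg)
  cfg_hashable$out_dir <- NULL # hash covers analysis choices, not paths
  cfg_json <- jsonlite::toJSON(cfg_hashable, auto_unbox = TRUE, digits = NA,
                               null = "null")
  manifest <- list(
    package_version = as.character(utils::packageVersion("aeropollen")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(local({
      f <- file.path(cfg$out_dir, "config.json")
      writeLines(cfg_json, f); f
    }))),
    checksums = as.list(tools::md5sum(sort(written))))
  names(manifest$checksums) <- basename(sort(written))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  result$manifest <- manifest
  result$filtered <- filtered
  result$rra <- rra_by_marker
  invisible(result)
}

#' Validate pipeline input files (non-destructive)
#'
#' Checks FASTA well-formedness, sample-sheet role labels, morphotype-map
#' totality against a reference lineage table, and the microscope table
#' schema.  Problems are reported, not thrown.
#'
#' @param paths named list; any of `sample_sheet`, `reads_dir`,
#'   `microscope`, `morphotype_map`, `reference_fasta`, `reference_lineage`
#' @return data.frame with columns `input`, `problem` (zero rows when clean)
#' @export
validate_inputs <- function(paths) {
  problems <- list()
  add <- function(input, problem) {
    problems[[length(problems) + 1L]] <<- data.frame(
      input = input, problem = problem, stringsAsFactors = FALSE)
  }
  if (!is.null(paths$sample_sheet)) {
    if (!file.exists(paths$sample_sheet)) add("sample_sheet", "file not found")
    else {
      sh <- try(read_tsv(paths$sample_sheet), silent = TRUE)
      if (inherits(sh, "try-error")) add("sample_sheet", "unreadable TSV")
      else {
        need <- c("occurrence_id", "sample_id", "replicate", "role")
        miss <- setdiff(need, names(sh))
        if (length(miss)) add("sample_sheet",
                              paste("missing columns:", paste(miss, collapse = ", ")))
        else {
          bad <- setdiff(unique(sh$role), OCCURRENCE_ROLES)
          if (length(bad)) add("sample_sheet",
                               paste("unknown role(s):", paste(bad, collapse = ", ")))
          if (anyDuplicated(sh$occurrence_id))
            add("sample_sheet", "duplicate occurrence ids")
        }
      }
    }
  }
  if (!is.null(paths$reads_dir)) {
    if (!dir.exists(paths$reads_dir)) add("reads_dir", "directory not found")
    else {
      files <- list.files(paths$reads_dir, pattern = "\\.fa(sta)?$",
                          recursive = TRUE, full.names = TRUE)
      if (!length(files)) add("reads_dir", "no FASTA files found")
      for (f in head(files, 50)) {
        ok <- try(Biostrings::readDNAStringSet(f), silent = TRUE)
        if (inherits(ok, "try-error"))
          add("reads_dir", paste("malformed FASTA:", basename(f)))
      }
    }
  }
  if (!is.null(paths$microscope)) {
    ms <- try(read_tsv(paths$microscope), silent = TRUE)
    if (inherits(ms, "try-error")) add("microscope", "unreadable TSV")
    else {
      miss <- setdiff(c("sample_id", "morphotype", "concentration"), names(ms))
      if (length(miss)) add("microscope",
                            paste("missing columns:", paste(miss, collapse = ", ")))
      else if (any(ms$concentration < 0)) add("microscope", "negative concentrations")
    }
  }
  if (!is.null(paths$morphotype_map)) {
    mp <- try(read_tsv(paths$morphotype_map), silent = TRUE)
    if (inherits(mp, "try-error")) add("morphotype_map", "unreadable TSV")
    else {
      miss <- setdiff(c("taxon", "morphotype"), names(mp))
      if (length(miss)) add("morphotype_map",
                            paste("missing columns:", paste(miss, collapse = ", ")))
      else if (!is.null(paths$reference_lineage)) {
        lin <- try(read_tsv(paths$reference_lineage), silent = TRUE)
        if (!inherits(lin, "try-error")) {
          taxa <- unique(c(lin$species, lin$genus, lin$family))
          unmapped <- setdiff(taxa, mp$taxon)
          if (length(unmapped))
            add("morphotype_map",
                paste("unmapped taxa:", paste(head(unmapped, 5), collapse = ", "),
                      if (length(unmapped) > 5) "..." else ""))
        }
      }
    }
  }
  if (!is.null(paths$reference_fasta)) {
    ok <- try(Biostrings::readDNAStringSet(paths$reference_fasta), silent = TRUE)
    if (inherits(ok, "try-error")) add("reference_fasta", "malformed FASTA")
  }
  if (!length(problems)) {
    return(data.frame(input = character(0), problem = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, problems)
  rownames(out) <- NULL
  out
}
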