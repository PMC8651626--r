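make_tab <- function(cnt, roles = NULL) {
  occ <- colnames(cnt)
  if (is.null(roles)) {
    roles <- ifelse(startsWith(occ, "B"), "extraction_blank", "sample")
  }
  sheet <- data.frame(occurrence_id = occ,
                      sample_id = sub("_r[0-9]+$", "", occ),
                      replicate = as.integer(sub(".*_r", "", paste0(occ, "_r1"))),
                      role = roles, stringsAsFactors = FALSE)
  sheet$replicate[is.na(sheet$replicate)] <- 1L
  occurrence_table(cnt, sheet)
}

test_that("remove_blank_dominant applies the strict max-vs-max rule", {
  cnt <- rbind(OTU1 = c(S1_r1 = 40, S2_r1 = 10, B1 = 50),   # removed
               OTU2 = c(400, 10, 50),                       # kept
               OTU3 = c(50, 20, 50))                        # tie -> kept
  tab <- make_tab(cnt)
  out <- remove_blank_dominant(tab)
  expect_setequal(rownames(out$counts), c("OTU2", "OTU3"))

  nb <- make_tab(cnt, roles = rep("sample", 3))
  expect_warning(out2 <- remove_blank_dominant(nb), "no blank")
  expect_identical(out2$counts, nb$counts)
})

test_that("solve_leakage_threshold finds the minimal blank-zeroing ratio", {
  # OTU1: total 10000, blank 3 (3e-4); OTU2: total 2000, blank 4 (2e-3)
  cnt <- rbind(OTU1 = c(S1_r1 = 9000, S2_r1 = 997, B1 = 3),
               OTU2 = c(1500, 496, 4))
  tab <- make_tab(cnt)
  t_star <- solve_leakage_threshold(tab)
  expect_equal(as.numeric(t_star), 0.002)
  expect_equal(as.numeric(t_star), oracle_threshold(tab))

  # applying t* zeroes the blanks; re-solving then yields 0 (idempotence)
  cleaned <- apply_leakage_threshold(tab, as.numeric(t_star))
  expect_true(all(cleaned$counts[, "B1"] == 0))
  expect_equal(as.numeric(solve_leakage_threshold(cleaned)), 0)

  # empty blanks -> 0
  cnt0 <- cnt; cnt0[, "B1"] <- 0
  expect_equal(as.numeric(solve_leakage_threshold(make_tab(cnt0))), 0)

  # blank-only OTU is flagged
  cntb <- rbind(cnt, OTU3 = c(0, 0, 12))
  expect_warning(tb <- solve_leakage_threshold(make_tab(cntb)), "entirely in blanks")
  expect_equal(attr(tb, "flagged"), "OTU3")
})

test_that("t* matches the brute-force grid oracle on random tables", {
  for (seed in 1:25) {
    tab <- random_occ_table(seed)
    tab <- remove_blank_dominant(tab) # precondition of the solver
    t_star <- as.numeric(solve_leakage_threshold(tab))
    expect_equal(t_star, oracle_threshold(tab), tolerance = 1e-12)
    cleaned <- apply_leakage_threshold(tab, t_star)
    expect_true(all(cleaned$counts[, startsWith(colnames(cleaned$counts), "B")] == 0))
  }
})

test_that("the cascade is a fixed point on already-clean tables", {
  cnt <- rbind(OTU1 = c(S1_r1 = 4000, S1_r2 = 3500, S1_r3 = 3600, B1 = 0),
               OTU2 = c(3000, 3300, 3500, 0))
  tab <- make_tab(cnt)
  fc <- run_filter_cascade(tab)
  expect_identical(fc$table$counts, tab$counts)
  expect_true(all(fc$report$reads_removed == 0))
  expect_equal(fc$leakage_threshold, 0)
})

test_that("replicate-depth and replicate-consensus rules behave as stated", {
  # depths (5000, 2500, 2400): one replicate survives -> flagged single-rep
  cnt <- rbind(OTU1 = c(S1_r1 = 3000, S1_r2 = 1500, S1_r3 = 1200, B1 = 0),
               OTU2 = c(2000, 1000, 1200, 0))
  tab <- make_tab(cnt)
  fc <- run_filter_cascade(tab)
  expect_equal(fc$single_replicate_samples, "S1")
  expect_equal(sum(fc$table$sheet$role == "sample"), 1)
  # step f skipped for the single-replicate sample: counts kept
  expect_true(all(fc$table$counts[, "S1_r1"] == c(3000, 2000)))

  # OTU present in 1 of 3 replicates at count 500 -> zeroed in that sample
  cnt2 <- rbind(OTU1 = c(S1_r1 = 4000, S1_r2 = 3800, S1_r3 = 3900, B1 = 0),
                OTU2 = c(500, 0, 0, 0))
  fc2 <- run_filter_cascade(make_tab(cnt2))
  expect_false("OTU2" %in% rownames(fc2$table$counts))

  # present in 2 of 3 -> kept
  cnt3 <- rbind(OTU1 = c(S1_r1 = 4000, S1_r2 = 3800, S1_r3 = 3900, B1 = 0),
                OTU2 = c(500, 400, 0, 0))
  fc3 <- run_filter_cascade(make_tab(cnt3))
  expect_true("OTU2" %in% rownames(fc3$table$counts))
})

test_that("step (e) removes excluded clades and listed contaminants", {
  cnt <- rbind(t1 = c(S1_r1 = 4000, S1_r2 = 4000, B1 = 0),
               t2 = c(3000, 3100, 0),
               t3 = c(500, 600, 0))
  tab <- make_tab(cnt)
  taxa <- data.frame(
    query = c("t1", "t2", "t3"),
    rbind(lineage("seed_plants", "Urticaceae", "Urtica", "Urtica dioica"),
          lineage("fungi", "fungi_Fam01", "fungi_Genus01", "fungi sp01"),
          lineage("seed_plants", "Solanaceae", "Solanum",
                  "Solanum lycopersicum")),
    rank = "species", stringsAsFactors = FALSE)
  fc <- run_filter_cascade(tab, taxa,
                           filter_params(contaminants = "Solanum lycopersicum"))
  expect_equal(rownames(fc$table$counts), "t1")
})

test_that("raising min_reads_per_repeat never increases surviving reads", {
  tab <- random_occ_table(99)
  reads <- vapply(c(1, 10, 50, 200), function(m) {
    suppressWarnings(
      sum(run_filter_cascade(tab, params = filter_params(
        min_reads_per_repeat = m, min_repeat_depth = 0))$table$counts))
  }, numeric(1))
  expect_true(all(diff(reads) <= 0))
})

test_that("blank columns are exactly zero after the cascade on simulations", {
  qs <- quick_sim(seed = 8, leakage_rate = 2e-3)
  tab <- sim_occ_table(qs)
  fc <- run_filter_cascade(tab, sim_taxa(qs),
                           filter_params(contaminants = qs$sim$truth$contaminants))
  bl <- fc$table$sheet$occurrence_id[fc$table$sheet$role %in%
                                       c("extraction_blank", "pcr_negative")]
  expect_true(all(fc$table$counts[, bl] == 0))
  # deterministic: bit-identical on a rerun
  fc2 <- run_filter_cascade(tab, sim_taxa(qs),
                            filter_params(contaminants = qs$sim$truth$contaminants))
  expect_identical(fc$table$counts, fc2$table$counts)
  expect_identical(fc$report, fc2$report)
})

test_that("positive-control checks detect dominance and absence", {
  cnt <- rbind(ctrl = c(S1_r1 = 0, S1_r2 = 0, POS1 = 5000, B1 = 0),
               other = c(4000, 4100, 0, 0))
  roles <- c("sample", "sample", "positive_control", "extraction_blank")
  tab <- make_tab(cnt, roles)
  chk <- check_positive_controls(tab, "ctrl")
  expect_true(chk$pass)
  # control taxon absent from the control occurrence -> fail
  cnt2 <- cnt; cnt2["ctrl", "POS1"] <- 0; cnt2["other", "POS1"] <- 100
  expect_false(check_positive_controls(make_tab(cnt2, roles), "ctrl")$pass)
  # 40% share in a control -> fail
  cnt3 <- cnt; cnt3["ctrl", "POS1"] <- 400; cnt3["other", "POS1"] <- 600
  expect_false(check_positive_controls(make_tab(cnt3, roles), "ctrl")$pass)
  # absent role -> skipped with warning
  expect_warning(
    chk4 <- check_positive_controls(make_tab(cnt[, 1:2, drop = FALSE],
                                             c("sample", "sample")), "ctrl"),
    "skipped")
  expect_true(is.na(chk4$pass))
})
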