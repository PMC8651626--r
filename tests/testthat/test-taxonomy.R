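test_that("align_identity reproduces hand-computed alignments", {
  with_seed_helper(51, {
    s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  })
  perfect <- align_identity(s, s)
  expect_equal(perfect$identity, 100)
  expect_equal(perfect$coverage, 100)
  expect_equal(perfect$score, 200)

  one_sub <- mutate_n(s, 1)
  expect_equal(align_identity(one_sub, s)$identity, 99)

  # hand alignment: AAAA--TTTT vs AAAACCTTTT -> 8 matches over 10 columns
  h <- align_identity("AAAATTTT", "AAAACCTTTT")
  expect_equal(h$identity, 80)
  expect_equal(h$score, 8 * 2 - (5 + 2 * 2))

  expect_error(align_identity("", s), "empty")
})

test_that("assignment honours local priority, coverage gates and tiers", {
  db_l <- tiny_db("local")
  db_g <- tiny_db("global")
  # make the global version of record 1 a perfect match for the query while
  # the local best is 2 substitutions away: local must still win
  q <- db_l$sequences[2]                 # = Alnus incana local sequence
  db_g$sequences[1] <- q
  mk_its <- marker_params("nrITS2", "A", "T", 8, 90, 0.2, 100)
  asg <- assign_taxonomy(q, db_l, db_g, mk_its, query_ids = "q1")
  expect_equal(asg$db_scope, "local")
  expect_equal(asg$rank, "species")
  expect_equal(asg$species, "Alnus incana")

  # identity between tiers caps the rank: ~95% -> genus
  q95 <- mutate_n(db_l$sequences[1], 5)
  asg <- assign_taxonomy(q95, db_l, NULL, mk_its)
  expect_equal(asg$rank, "genus")
  expect_equal(asg$genus, "Alnus")
  expect_equal(asg$species, "")

  # ~85% -> family; ~70% -> unassigned
  q85 <- mutate_n(db_l$sequences[3], 15)
  asg <- assign_taxonomy(q85, db_l, NULL, mk_its)
  expect_true(asg$rank %in% c("family", "genus")) # 15 subs, alignment may rescue
  q70 <- mutate_n(db_l$sequences[3], 30)
  asg70 <- assign_taxonomy(q70, db_l, NULL, mk_its)
  expect_equal(asg70$rank, "unassigned")

  # trnL coverage gate: a sub-100 coverage hit is dropped even at 99% identity
  mk_trnl <- marker_params("trnL", "A", "T", 8, 100, 0.8, 100)
  hits <- data.frame(query = "q", subject = "ref1", identity = 99,
                     coverage = 99, score = 180)
  asg <- assign_from_hits("q", hits, NULL, db_l, NULL, mk_trnl)
  expect_equal(asg$rank, "unassigned")
  # the same hit passes the nrITS2 gate (>= 90)
  asg <- assign_from_hits("q", hits, NULL, db_l, NULL, mk_its)
  expect_equal(asg$rank, "species")
})

test_that("tied top scores trigger the LCA", {
  db <- tiny_db()
  mk <- marker_params("nrITS2", "A", "T", 8, 90, 0.2, 100)
  hits <- data.frame(query = "q",
                     subject = c("ref1", "ref2"),      # two Alnus species
                     identity = c(98, 98), coverage = 100,
                     score = c(150, 150))
  asg <- assign_from_hits("q", hits, NULL, db, NULL, mk)
  expect_equal(asg$rank, "genus")
  expect_equal(asg$genus, "Alnus")

  # Cupressus + Juniperus tie -> family Cupressaceae
  hits2 <- data.frame(query = "q", subject = c("ref3", "ref4"),
                      identity = c(98, 98), coverage = 100,
                      score = c(150, 150))
  asg2 <- assign_from_hits("q", hits2, NULL, db, NULL, mk)
  expect_equal(asg2$rank, "family")
  expect_equal(asg2$family, "Cupressaceae")

  # unequal scores: only the max-score hit defines the candidate set
  hits3 <- data.frame(query = "q", subject = c("ref1", "ref2"),
                      identity = c(98, 97), coverage = 100,
                      score = c(160, 150))
  asg3 <- assign_from_hits("q", hits3, NULL, db, NULL, mk)
  expect_equal(asg3$species, "Alnus glutinosa")
})

test_that("assign_taxonomy equals the brute-force oracle on random queries", {
  dbs <- generate_reference_sets(3, 2, 2, seq_length = 120, seed = 13)
  mk <- marker_params("nrITS2", "A", "T", 8, 90, 0.2, 120)
  with_seed_helper(77, {
    queries <- vapply(1:40, function(i) {
      base <- sample(dbs$global$sequences, 1)
      mutate_n(base, sample(0:20, 1))
    }, character(1))
  })
  asg <- assign_taxonomy(queries, dbs$local, dbs$global, mk)
  for (i in seq_along(queries)) {
    orc <- oracle_assign(queries[i], dbs$local, dbs$global, 90)
    expect_equal(asg$rank[i], orc$rank)
    expect_equal(asg$species[i], orc$lineage$species)
    expect_equal(asg$genus[i], orc$lineage$genus)
    expect_equal(asg$family[i], orc$lineage$family)
    if (orc$rank != "unassigned") expect_equal(asg$db_scope[i], orc$scope)
  }
})

test_that("adding mutations never deepens the assigned rank", {
  dbs <- generate_reference_sets(2, 2, 2, seq_length = 150, seed = 21)
  mk <- marker_params("nrITS2", "A", "T", 8, 90, 0.2, 150)
  depth_of <- c(unassigned = 0, family = 2, genus = 3, species = 4)
  with_seed_helper(31, {
    for (rep in 1:10) {
      base <- sample(dbs$local$sequences, 1)
      q1 <- mutate_n(base, sample(0:3, 1))
      q2 <- mutate_n(q1, sample(3:10, 1)) # strictly more mutations
      r1 <- assign_taxonomy(q1, dbs$local, dbs$global, mk)$rank
      r2 <- assign_taxonomy(q2, dbs$local, dbs$global, mk)$rank
      expect_lte(depth_of[[r2]], depth_of[[r1]])
    }
  })
})

test_that("aggregation sums shared assignments and conserves reads", {
  cnt <- matrix(c(100, 50, 7, 20,
                  40, 10, 3, 5), 4, 2,
                dimnames = list(c("OTU1", "OTU2", "OTU3", "OTU4"),
                                c("o1", "o2")))
  asg <- rbind(
    data.frame(query = "OTU1", lineage("seed_plants", "Urticaceae", "Urtica",
                                       "Urtica dioica"),
               rank = "species", best_identity = 99, db_scope = "local"),
    data.frame(query = "OTU2", lineage("seed_plants", "Urticaceae", "Urtica",
                                       "Urtica dioica"),
               rank = "species", best_identity = 98, db_scope = "local"),
    data.frame(query = "OTU3", lineage(), rank = "unassigned",
               best_identity = NA, db_scope = ""),
    data.frame(query = "OTU4", lineage("seed_plants", "Betulaceae", "Alnus"),
               rank = "genus", best_identity = 93, db_scope = "local"))
  agg <- aggregate_by_assignment(cnt, asg)
  expect_equal(nrow(agg$counts), 3)
  ud <- agg$taxa$key[agg$taxa$taxon == "Urtica dioica"]
  expect_equal(unname(agg$counts[ud, ]), c(150, 50))
  expect_equal(colSums(agg$counts), colSums(cnt)) # conservation
  expect_true(any(startsWith(rownames(agg$counts), "unassigned:")))
  # all-distinct assignments leave the table unchanged except row keys
  asg2 <- asg; asg2$species <- paste0(asg$species, "_", seq_len(4))
  asg2$rank <- "species"
  asg2[, c("clade", "family", "genus")] <-
    lapply(asg2[, c("clade", "family", "genus")], function(x)
      ifelse(nzchar(x), x, "z"))
  agg2 <- aggregate_by_assignment(cnt, asg2)
  expect_equal(nrow(agg2$counts), 4)
  expect_equal(sum(agg2$counts), sum(cnt))
})

test_that("hit tables round-trip and are validated", {
  h <- data.frame(query = "q1", subject = "s1", identity = 98.5,
                  coverage = 100, score = 180)
  f <- tempfile(fileext = ".tsv")
  data.table::fwrite(h, f, sep = "\t")
  expect_equal(read_hit_table(f)$identity, 98.5)
  h2 <- h; h2$identity <- 120
  data.table::fwrite(h2, f, sep = "\t")
  expect_error(read_hit_table(f), "0, 100")
})
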