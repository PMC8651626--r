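test_that("merge_pairs joins exact overlaps and applies both gates", {
  with_seed_helper(21, {
    core <- paste(sample(c("A", "C", "G", "T"), 160, TRUE), collapse = "")
  })
  fwd <- substr(core, 1, 100)
  rev <- revcomp(substr(core, 61, 160))
  expect_equal(merge_pairs(fwd, rev), core)            # 40 bp exact overlap

  # exact overlap of only 5 bp -> below the 10 bp minimum
  expect_null(merge_pairs(substr(core, 1, 20), revcomp(substr(core, 16, 35))))

  # 10 bp overlap with 3 mismatches: ratio 0.3 > 0.25 -> reject
  with_seed_helper(23, {
    a <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  })
  ov <- substr(a, 11, 20)
  flip <- function(s, pos) { # guaranteed substitution at each position
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- chartr("ACGT", "CGTA", ch[pos])
    paste(ch, collapse = "")
  }
  ov_mm <- flip(ov, c(1, 5, 9))
  b_seq <- paste0(ov_mm, "AAAACCCCGG")
  expect_null(merge_pairs(a, revcomp(b_seq), min_overlap = 10))

  # 2 mismatches in 10 (ratio 0.2 <= 0.25) merges; consensus prefers the
  # higher-quality base, ties -> forward
  ov_mm2 <- flip(ov, c(1, 5))
  b2 <- paste0(ov_mm2, "AAAACCCCGG")
  m <- merge_pairs(a, revcomp(b2))
  expect_equal(substr(m, 11, 11), substr(ov, 1, 1)) # tie -> forward base
  m2 <- merge_pairs(a, revcomp(b2), fwd_qual = rep(10, 20),
                    rev_qual = rep(30, 20))
  expect_equal(substr(m2, 11, 11), substr(ov_mm2, 1, 1)) # rev wins on quality
})

test_that("trim_primers requires both primers and the length floor", {
  fwd_p <- "GGGCAATCCTGAGCCAA"
  rev_p <- "CCATTGAGTCTCTGCACCTATC"
  with_seed_helper(22, {
    ins20 <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    ins7 <- paste(sample(c("A", "C", "G", "T"), 7, TRUE), collapse = "")
  })
  read <- paste0(fwd_p, ins20, revcomp(rev_p))
  tr <- trim_primers(read, fwd_p, rev_p, min_len = 8)
  expect_equal(tr$insert, ins20)

  no_rev <- paste0(fwd_p, ins20)
  tr <- trim_primers(no_rev, fwd_p, rev_p, min_len = 8)
  expect_false(tr$kept)
  expect_equal(tr$reject_reason, "no_rev_primer")

  short <- paste0(fwd_p, ins7, revcomp(rev_p))
  tr <- trim_primers(short, fwd_p, rev_p, min_len = 8)
  expect_equal(tr$reject_reason, "too_short")

  # mismatch budget: floor(0.2 * 17) = 3 substitutions in the fwd primer ok
  fwd_mut <- fwd_p
  substr(fwd_mut, 2, 2) <- "T"; substr(fwd_mut, 8, 8) <- "A"
  substr(fwd_mut, 15, 15) <- "T"
  tr <- trim_primers(paste0(fwd_mut, ins20, revcomp(rev_p)), fwd_p, rev_p,
                     min_len = 8)
  expect_equal(tr$insert, ins20)

  # IUPAC degeneracy: Y matches C and T
  tr_c <- trim_primers(paste0("C", substr(fwd_p, 2, 17), ins20, revcomp(rev_p)),
                       paste0("Y", substr(fwd_p, 2, 17)), rev_p, min_len = 8)
  expect_true(tr_c$kept)
})

test_that("dereplicate groups exactly and keeps per-occurrence counts", {
  uq <- dereplicate(list(A = c("AAA", "AAA", "AAT"), B = character(0)))
  expect_equal(uq$sequence, c("AAA", "AAT"))
  expect_equal(uq$abundance, c(2L, 1L))
  expect_equal(unname(uq$counts[1, ]), c(2L, 0L))

  empty <- dereplicate(list(A = character(0)))
  expect_length(empty$sequence, 0)

  # abundance ties break lexicographically
  uq2 <- dereplicate(list(X = c("TTT", "AAA", "CCC")))
  expect_equal(uq2$sequence, c("AAA", "CCC", "TTT"))
})

test_that("denoise_unoise applies the beta(d) skew rule and the floor", {
  with_seed_helper(31, {
    c1 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  })
  v1 <- mutate_n(c1, 1)  # edit distance 1

  mk <- function(seqs, ab) {
    structure(list(sequence = seqs, abundance = ab,
                   counts = matrix(as.integer(ab), length(ab), 1,
                                   dimnames = list(NULL, "occ1"))),
              class = "unique_seqs")
  }
  # 100/1000 = 0.1 <= beta(1) = 1/8 -> merged
  ot <- denoise_unoise(mk(c(c1, v1), c(1000L, 100L)), min_abundance = 1)
  expect_equal(nrow(ot$otu), 1)
  expect_equal(ot$otu$abundance, 1100)
  # 200/1000 = 0.2 > 0.125 -> separate centroid
  ot <- denoise_unoise(mk(c(c1, v1), c(1000L, 200L)), min_abundance = 1)
  expect_equal(nrow(ot$otu), 2)
  # abundance 9 is discarded before clustering
  ot <- denoise_unoise(mk(c(c1, v1), c(1000L, 9L)), min_abundance = 10)
  expect_equal(nrow(ot$otu), 1)
  expect_equal(ot$otu$abundance, 1000)
  # unsorted input rejected
  expect_error(denoise_unoise(mk(c(c1, v1), c(10L, 1000L)), min_abundance = 1),
               "sorted")
})

test_that("clustering conserves reads and matches the brute-force oracle", {
  for (seed in c(101, 202, 303)) {
    with_seed_helper(seed, {
      temps <- vapply(1:6, function(i) {
        paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
      }, character(1))
      occs <- list()
      for (o in c("o1", "o2", "o3")) {
        reads <- character(0)
        for (t in temps) {
          n <- rpois(1, 300)
          reads <- c(reads, rep(t, n))
          # error variants at distance 1-2
          for (k in 1:3) {
            v <- mutate_n(t, sample(1:2, 1))
            reads <- c(reads, rep(v, rpois(1, 8)))
          }
        }
        occs[[o]] <- sample(reads)
      }
    })
    uq <- dereplicate(occs)
    ot <- denoise_unoise(uq, min_abundance = 5)
    # read conservation: OTU totals equal retained unique totals
    expect_equal(sum(ot$counts), sum(uq$abundance[uq$abundance >= 5]))
    expect_equal(unname(colSums(ot$counts)),
                 unname(colSums(uq$counts[uq$abundance >= 5, , drop = FALSE])))
    # oracle equivalence
    orc <- oracle_denoise(uq, alpha = 2, min_abundance = 5)
    expect_identical(ot$otu$centroid, orc$centroids)
  }
})

test_that("exact two-parent concatenations are flagged as chimeras", {
  with_seed_helper(41, {
    p1 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    p2 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  })
  chi <- paste0(substr(p1, 1, 30), substr(p2, 31, 60))
  mk <- function(seqs, ab) {
    structure(list(sequence = seqs, abundance = ab,
                   counts = matrix(as.integer(ab), length(ab), 1,
                                   dimnames = list(NULL, "occ1"))),
              class = "unique_seqs")
  }
  ot <- denoise_unoise(mk(c(p1, p2, chi), c(1000L, 900L, 50L)),
                       min_abundance = 1, detect_chimeras = TRUE)
  expect_equal(ot$otu$chimera, c(FALSE, FALSE, TRUE))
  ot2 <- denoise_unoise(mk(c(p1, p2, chi), c(1000L, 900L, 50L)),
                        min_abundance = 1)
  expect_false(any(ot2$otu$chimera))
})
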