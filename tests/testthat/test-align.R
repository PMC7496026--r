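test_that("global alignment reproduces hand-derived optima", {
  id <- global_align("ACGT", "ACGT")
  expect_equal(id$row_a, "ACGT")
  expect_equal(id$score, 100)
  expect_equal(glance(id)$matches, 4)

  gap <- global_align("ACGT", "AGT")
  expect_equal(gap$score_raw, 3 - (10 + 0.2), tolerance = 1e-5)
  expect_equal(sum(tidy(gap)$class == "gap_b"), 1)

  mm <- global_align("AAAA", "TTTT")
  expect_equal(mm$score_raw, -4)  # gaps dearer than mismatches
  expect_equal(unique(tidy(mm)$class), "mismatch")
})

test_that("aligner matches the exhaustive brute-force oracle on short pairs", {
  set.seed(21)
  for (k in 1:60) {
    a <- random_dna(sample(1:7, 1))
    b <- random_dna(sample(1:7, 1))
    al <- global_align(a, b)
    expect_equal(al$score_raw, brute_force_align_score(a, b),
                 tolerance = 1e-5, label = paste(a, b))
  }
})

test_that("alignment rows ungap back to their inputs", {
  set.seed(22)
  for (k in 1:10) {
    a <- random_dna(30); b <- random_dna(sample(25:35, 1))
    al <- global_align(a, b)
    expect_equal(gsub("-", "", al$row_a), a)
    expect_equal(gsub("-", "", al$row_b), b)
    expect_false(any(tidy(al)$a == "-" & tidy(al)$b == "-"))
  }
})

test_that("percent-identity score uses the shorter ungapped length", {
  expect_equal(alignment_score("ACGT", "ACGT"), 100)
  expect_equal(alignment_score("ACGT", "TGCA"), 0)
  # 570 matches over 601/601
  row <- paste0(strrep("A", 570), strrep("C", 31))
  row_b <- paste0(strrep("A", 570), strrep("G", 31))
  expect_equal(round(alignment_score(row, row_b), 1), 94.8)
  # N never matches, even against N
  expect_equal(alignment_score("NN", "NN"), 0)
})

test_that("alignment score is symmetric in its arguments", {
  set.seed(23)
  for (k in 1:15) {
    a <- random_dna(40); b <- random_dna(sample(30:50, 1))
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
  }
})

test_that("candidate selection takes the longest hit passing both filters", {
  hits <- tibble::tibble(identity = c(0.95, 0.99, 0.92),
                         span = c(250L, 150L, 400L))
  expect_equal(select_candidate(hits)$span, 400L)
  none <- tibble::tibble(identity = c(0.8, 0.85), span = c(300L, 400L))
  expect_equal(nrow(select_candidate(none)), 0)
  one <- tibble::tibble(identity = 0.95, span = 300L)
  expect_equal(nrow(select_candidate(one)), 1)
})

test_that("pair filtering enforces the score cutoff and YR agreement", {
  mk <- function(seq_a, seq_b, tss = 3L) {
    align_pairs(tibble::tibble(seq_a = seq_a, seq_b = seq_b,
                               tss_a = tss, tss_b = tss))
  }
  # identical pairs pass
  al <- mk("TTTCATTT", "TTTCATTT")
  expect_equal(nrow(filter_pairs(al, min_score = 90)), 1)
  # Y mismatch at the anchor: dropped even at score >= cutoff
  al2 <- mk("TTTCATTT", "TTTTATTT")
  kept <- filter_pairs(al2, min_score = 50)
  expect_equal(nrow(kept), 0)
  expect_equal(unname(attr(kept, "attrition")["yr_mismatch"]), 1)
  # score below cutoff: dropped
  al3 <- mk("TTTCATTT", "AATCAAAA")
  expect_equal(nrow(filter_pairs(al3, min_score = 90)), 0)
})

test_that("anchoring a hit maps the TSS, checks YR and extends", {
  set.seed(31)
  # target genome contains the query promoter verbatim at offset 1000
  core <- paste0(random_dna(299), "CA", random_dna(300))  # Y/R at 299/300
  target <- paste0(random_dna(1000), core, random_dna(1000))
  g <- genome_source(c(t1 = target))
  hit <- tibble::tibble(
    matches = 601L, strand = "+", q_name = "q", q_size = 601L,
    t_name = "t1", t_start = 1000L, t_end = 1601L,
    block_sizes = list(601L), q_starts = list(0L), t_starts = list(1000L),
    span = 601L, identity = 1
  )
  res <- anchor_and_extend(hit, g, query_tss_offset = 300L)
  expect_equal(res$status, "ok")
  expect_equal(res$window$pos, 1300L)
  expect_equal(res$window$seq, substr(target, 1001, 1601))
  expect_equal(substr(res$window$seq, 300, 301), "CA")

  # minus-strand hit: same query found on the reverse strand
  target2 <- paste0(random_dna(500), revcomp(core), random_dna(500))
  g2 <- genome_source(c(t2 = target2))
  hit2 <- tibble::tibble(
    matches = 601L, strand = "-", q_name = "q", q_size = 601L,
    t_name = "t2", t_start = 500L, t_end = 1101L,
    block_sizes = list(601L), q_starts = list(0L), t_starts = list(500L),
    span = 601L, identity = 1
  )
  res2 <- anchor_and_extend(hit2, g2, query_tss_offset = 300L)
  expect_equal(res2$status, "ok")
  expect_equal(res2$window$seq, core)

  # TSS outside the aligned block -> unmapped
  hit3 <- dplyr::mutate(hit, block_sizes = list(100L))
  expect_equal(anchor_and_extend(hit3, g)$status, "unmapped")

  # purine at the mapped Y position -> no-YR
  target4 <- target
  substr(target4, 1300, 1300) <- "G"
  expect_equal(anchor_and_extend(hit, genome_source(c(t1 = target4)))$status,
               "no-YR")

  # mapped centre too close to the contig end -> gap
  g5 <- genome_source(c(t1 = substr(target, 1, 1500)))
  expect_equal(anchor_and_extend(hit, g5)$status, "gap")

  # N inside the extended window -> gap
  target6 <- target
  substr(target6, 1100, 1100) <- "N"
  expect_equal(anchor_and_extend(hit, genome_source(c(t1 = target6)))$status,
               "gap")
})

test_that("anchoring an unmutated duplicate genome recovers the window
          exactly", {
  set.seed(32)
  core <- paste0(random_dna(299), "CA", random_dna(300))
  g <- genome_source(c(t = paste0(random_dna(400), core, random_dna(400))))
  hit <- tibble::tibble(
    matches = 601L, strand = "+", q_name = "q", q_size = 601L,
    t_name = "t", t_start = 400L, t_end = 1001L,
    block_sizes = list(601L), q_starts = list(0L), t_starts = list(400L),
    span = 601L, identity = 1
  )
  res <- anchor_and_extend(hit, g)
  expect_equal(res$status, "ok")
  al <- align_pairs(tibble::tibble(seq_a = core, seq_b = res$window$seq,
                                   tss_a = 300L, tss_b = 300L))
  expect_equal(al$score, 100)
})
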