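test_that("gap runs become indel sites with carrier, sequence and flanks", {
  # 2-bp insertion in A relative to B, interior placement with long flanks
  row_a <- paste0(strrep("A", 12), "TC", strrep("G", 12))
  row_b <- paste0(strrep("A", 12), "--", strrep("G", 12))
  s <- detect_indels(row_a, row_b)
  expect_equal(nrow(s), 1)
  expect_equal(s$carrier, "a")
  expect_equal(s$seq, "TC")
  expect_equal(s$length, 2L)
  expect_equal(s$col_start, 12L)
  expect_equal(s$col_end, 14L)
  expect_equal(s$pos_carrier, 12L)
  expect_equal(s$pos_other, 12L)
  expect_equal(s$flank_left, 10L)
  expect_equal(s$flank_right, 10L)
  expect_false(s$truncated)

  expect_equal(nrow(detect_indels("ACGT", "ACGT")), 0)
})

test_that("flank mismatches, gaps in flanks, and edges are handled", {
  # mismatch in the left flank window
  row_a <- paste0(strrep("A", 11), "TC", strrep("G", 12))
  row_b <- paste0(strrep("A", 11), "A-", strrep("G", 12))
  s <- detect_indels(row_a, row_b)
  expect_equal(s$flank_left, 9L)
  # edge-touching run is truncated
  s2 <- detect_indels("TTAAAAAAAAAAAA", "--AAAAAAAAAAAA")
  expect_true(s2$truncated)
  expect_equal(s2$flank_left, 0L)
  # a neighbouring gap column counts as a flank mismatch
  row_a3 <- paste0(strrep("A", 12), "C", "-", strrep("G", 12))
  row_b3 <- paste0(strrep("A", 12), "-", "T", strrep("G", 12))
  s3 <- detect_indels(row_a3, row_b3)
  expect_equal(nrow(s3), 2)  # two distinct adjacent runs, not merged
  expect_equal(s3$flank_right[s3$carrier == "a"], 9L)
})

test_that("the flank filter keeps >= 8/10 on both sides, untruncated", {
  sites <- tibble::tibble(flank_left = c(10L, 8L, 8L, 10L),
                          flank_right = c(9L, 8L, 7L, 10L),
                          truncated = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(flank_filter(sites)$keep, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("CpG delta counts junction-spanning CpGs in both rows", {
  # "CGCG" inserted between A and T: +2
  row_a <- paste0(strrep("T", 10), "ACGCGT", strrep("A", 10))
  row_b <- paste0(strrep("T", 10), "A----T", strrep("A", 10))
  s <- detect_indels(row_a, row_b)
  expect_equal(s$cpg_delta, 2L)
  # "AT" inserted between T and A: 0
  row_a2 <- paste0(strrep("C", 10), "TATA", strrep("T", 10))
  row_b2 <- paste0(strrep("C", 10), "T--A", strrep("T", 10))
  expect_equal(detect_indels(row_a2, row_b2)$cpg_delta, 0L)
  # deletion where the junction forms a new CpG in the shorter row:
  # carrier CATG over the extended region vs other row's junction CG
  row_a3 <- paste0(strrep("T", 10), "CATG", strrep("T", 10))
  row_b3 <- paste0(strrep("T", 10), "C--G", strrep("T", 10))
  expect_equal(detect_indels(row_a3, row_b3)$cpg_delta, -1L)
  # indel and junctions free of C/G: delta 0
  row_a4 <- paste0(strrep("C", 10), "ATTTA", strrep("C", 10))
  row_b4 <- paste0(strrep("C", 10), "A---A", strrep("C", 10))
  expect_equal(detect_indels(row_a4, row_b4)$cpg_delta, 0L)
})

test_that("length histogram bins into the five classes", {
  sites <- tibble::tibble(length = c(1L, 1L, 3L, 12L))
  h <- indel_length_histogram(sites)
  expect_equal(h$count[h$class == "1"], 2L)
  expect_equal(h$count[h$class == "2-4"], 1L)
  expect_equal(h$count[h$class == "10-19"], 1L)
  expect_equal(sum(h$count), 4L)
  expect_equal(sum(indel_length_histogram(sites[0, ])$count), 0L)
})

test_that("single-nucleotide base bias is tallied per pair group", {
  sites <- tibble::tibble(
    length = c(1L, 1L, 1L, 1L, 2L),
    seq = c("C", "G", "G", "A", "AT"),
    group = c("hCmC", "hCmC", "hCmC", "hCmC", "hCmC")
  )
  b <- single_nt_bias(sites)
  cg <- sum(b$fraction[b$base %in% c("C", "G")])
  expect_equal(cg, 0.75)
  expect_equal(sum(b$count), 4L)
  expect_equal(nrow(single_nt_bias(sites[sites$length > 1, ])), 0)
})

test_that("left normalisation shifts repeat-ambiguous indels to a canonical
          placement", {
  # inserting A anywhere in an A-run normalises to the run start
  ctx <- "TTAAAAG"  # fragment "A" at 0-based 4
  expect_equal(left_normalize_indel(ctx, 4L, "A")$pos, 2L)
  # rotating a 2-mer inside a GA-repeat
  n <- left_normalize_indel("TGAGAGAC", 3L, "GA")
  expect_equal(n$pos, 1L)
  expect_equal(n$seq, "GA")
  # non-repetitive context does not move
  expect_equal(left_normalize_indel("TTTCGTT", 3L, "CG")$pos, 3L)
})

test_that("indel polarity follows single-event parsimony on the primate
          tree", {
  sp <- c("human", "chimpanzee", "gorilla", "macaque", "baboon", "marmoset")
  pres <- function(absent) setNames(!(sp %in% absent), sp)
  # deletion on the great-ape stem
  d <- polarize_indel(pres(c("human", "chimpanzee", "gorilla")))
  expect_equal(d$event, "deletion")
  expect_setequal(strsplit(d$branch, ",")[[1]],
                  c("human", "chimpanzee", "gorilla"))
  # insertion on the macaque branch
  i <- polarize_indel(setNames(sp == "macaque", sp))
  expect_equal(i$event, "insertion")
  expect_equal(i$branch, "macaque")
  # two events required -> ambiguous
  a <- polarize_indel(pres(c("human", "marmoset")))
  expect_equal(a$event, "ambiguous")
  # uniform -> no event
  expect_equal(polarize_indel(pres(character(0)))$event, "none")
  expect_error(polarize_indel(setNames(c(TRUE, NA, NA, NA, NA, NA), sp)),
               "3 species")
})

test_that("polarity calls agree with Fitch parsimony scores", {
  skip_if_not_installed("phangorn")
  sp <- c("human", "chimpanzee", "gorilla", "macaque", "baboon", "marmoset")
  tree <- primate_tree()
  set.seed(51)
  for (k in 1:40) {
    pres <- setNames(sample(c(TRUE, FALSE), 6, replace = TRUE), sp)
    res <- polarize_indel(pres, tree)
    states <- matrix(ifelse(pres[tree$tip.label], "p", "a"), ncol = 1,
                     dimnames = list(tree$tip.label, NULL))
    pd <- phangorn::phyDat(states, type = "USER", levels = c("p", "a"))
    score <- phangorn::fitch(tree, pd)
    if (res$event %in% c("insertion", "deletion")) {
      expect_equal(score, 1)
    } else if (res$event == "none") {
      expect_equal(score, 0)
    } else {
      # ambiguous: either >= 2 events, or a tie between single-event placements
      expect_gte(score, 1)
    }
  }
})
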