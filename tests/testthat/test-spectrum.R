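test_that("dinucleotide alteration rates match hand enumeration", {
  al <- tibble::tibble(row_a = "CGAT", row_b = "TGAT")
  sp <- dinuc_alteration_rates(al)
  get <- function(d, col) sp[[col]][sp$dinuc == d]
  expect_equal(get("CG", "rate"), 1)    # C->T altered the CpG
  expect_equal(get("GA", "rate"), 0)
  expect_equal(get("AT", "rate"), 0)
  expect_equal(sum(sp$total), 3)
})

test_that("identical rows give all-zero rates; gaps and N count as altered", {
  id <- dinuc_alteration_rates(tibble::tibble(row_a = "ACGTACGT",
                                              row_b = "ACGTACGT"))
  expect_true(all(id$altered == 0))
  # gap inside the CpG
  g <- dinuc_alteration_rates(tibble::tibble(row_a = "ACGT", row_b = "AC-T"))
  expect_equal(g$rate[g$dinuc == "CG"], 1)
  # N in the counterpart
  n <- dinuc_alteration_rates(tibble::tibble(row_a = "ACGT", row_b = "ACNT"))
  expect_equal(n$rate[n$dinuc == "CG"], 1)
  expect_equal(n$rate[n$dinuc == "GT"], 1)
  # insertion in the counterpart between the two source bases
  ins <- dinuc_alteration_rates(tibble::tibble(row_a = "AC-GT",
                                               row_b = "ACTGT"))
  expect_equal(ins$rate[ins$dinuc == "CG"], 1)
})

test_that("source totals equal ungapped dinucleotide counts and rates lie
          in [0,1]", {
  set.seed(41)
  co <- generate_cohort(8, seed = 41)
  al <- align_pairs(co)
  sp <- dinuc_alteration_rates(al)
  src <- cpg_stats(co$seq_a)
  expect_equal(sp$total[sp$dinuc == "CG"], sum(src$n_cpg))
  expect_equal(sum(sp$total), sum(nchar(co$seq_a) - 1L))
  expect_true(all(sp$rate >= 0 & sp$rate <= 1, na.rm = TRUE))
})

test_that("direction symmetry holds on identical rows", {
  al <- tibble::tibble(row_a = c("ACGGT", "TTCGA"), row_b = c("ACGGT", "TTCGA"))
  ab <- dinuc_alteration_rates(al, "a_to_b")
  ba <- dinuc_alteration_rates(al, "b_to_a")
  expect_equal(ab$total, ba$total)
  expect_equal(ab$altered, ba$altered)
})

test_that("CpG fates are classified by the counterpart dinucleotide", {
  al <- tibble::tibble(
    row_a = c("ACGT", "ACGT", "ACGT", "ACGT", "AC-GT"),
    row_b = c("ACGT", "ATGT", "ACAT", "AGTT", "ACTGT")
  )
  f <- cpg_fate_spectrum(al)
  expect_equal(f$count[f$fate == "CpG"], 1L)
  expect_equal(f$count[f$fate == "TpG"], 1L)
  expect_equal(f$count[f$fate == "CpA"], 1L)
  expect_equal(f$count[f$fate == "other"], 1L)
  expect_equal(f$count[f$fate == "gap"], 1L)
  expect_equal(sum(f$fraction), 1)
})

test_that("fate fractions sum to one per group across a simulated cohort", {
  co <- generate_cohort(6, seed = 43)
  al <- align_pairs(co)
  al$grp <- rep(c("x", "y"), 3)
  f <- cpg_fate_spectrum(al, group = "grp")
  sums <- tapply(f$fraction, f$group, sum)
  expect_equal(as.numeric(sums), c(1, 1))
})

test_that("island pairs at low divergence keep most CpGs intact", {
  co <- generate_cohort(
    60, sim_config(island_fraction = 1, sub_rate = 0.01, cpg_multiplier = 1),
    seed = 44
  )
  f <- cpg_fate_spectrum(align_pairs(co))
  expect_gt(f$fraction[f$fate == "CpG"], 0.8)
})

test_that("deamination enrichment is 1 for identical groups and flags a
          zero-deamination denominator", {
  co <- generate_cohort(5, seed = 45)
  al <- align_pairs(co)
  en <- deamination_enrichment(al, al)
  expect_equal(en$ratio, c(1, 1))
  clean <- tibble::tibble(row_a = "ACGT", row_b = "ACGT",
                          tss_a = 1L, tss_b = 1L)
  en2 <- deamination_enrichment(al, clean)
  expect_true(all(en2$infinite))
})

test_that("planted deamination excess is recovered as an enrichment ratio", {
  base <- sim_config(island_fraction = 1, sub_rate = 0.008,
                     cpg_multiplier = 1, slippage_rate = 0,
                     tandem_dup_rate = 0, tandem_del_rate = 0)
  hot <- sim_config(island_fraction = 1, sub_rate = 0.008,
                    cpg_multiplier = 3, slippage_rate = 0,
                    tandem_dup_rate = 0, tandem_del_rate = 0)
  co_base <- generate_cohort(250, base, seed = 46)
  co_hot <- generate_cohort(250, hot, seed = 47)
  en <- deamination_enrichment(align_pairs(co_hot), align_pairs(co_base))
  expect_true(all(abs(en$ratio - 3) < 0.75))  # 25% sampling tolerance
})
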