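#' Pipeline configuration
#'
#' Houses the fixed analysis parameters: promoter window half-width (300,
#' giving the 601-nt window), logo flanks (34 upstream / 5 downstream), TATA
#' scan width (40), island thresholds (G+C 0.5, CpG score 0.6), candidate
#' hit filters (identity 0.90 over > 200 bp), alignment score cutoffs (90
#' for refinement, 80 for the indel stage), indel flank rule (>= 8 matches
#' of 10 columns), dot-plot window/stride (5/1) and minimum TSS clone
#' support (3).
#'
#' @param window_halfwidth,logo_upstream,logo_downstream,tata_scan_width
#'   Window geometry (bp).
#' @param gc_threshold,score_threshold Island classification thresholds.
#' @param min_identity,min_span Candidate hit filters.
#' @param min_align_score,indel_align_score Percent-identity cutoffs.
#' @param flank_width,min_flank_match Indel flank-conservation rule.
#' @param dotplot_window,dotplot_stride,dotplot_neighborhood Harr-plot
#'   parameters.
#' @param min_clones Minimum TSS clone support.
#' @param align An [align_params()] object.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_halfwidth = 300L, logo_upstream = 34L,
                            logo_downstream = 5L, tata_scan_width = 40L,
                            gc_threshold = 0.5, score_threshold = 0.6,
                            min_identity = 0.90, min_span = 200L,
                            min_align_score = 90, indel_align_score = 80,
                            flank_width = 10L, min_flank_match = 8L,
                            dotplot_window = 5L, dotplot_stride = 1L,
                            dotplot_neighborhood = 25L,
                            min_clones = 3L, align = align_params()) {
  stopifnot(window_halfwidth > 0, logo_upstream > 0, logo_downstream >= 0,
            tata_scan_width > 0, gc_threshold >= 0, gc_threshold <= 1,
            score_threshold >= 0, score_threshold <= 1,
            min_identity >= 0, min_identity <= 1, flank_width > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the comparative promoter pipeline on a cohort of pairs
#'
#' End-to-end orchestration over a table of orthologous promoter pairs
#' (e.g. from [generate_cohort()], or assembled from extracted and
#' anchor-extended windows): classification of both species' windows,
#' global alignment, score + YR filtering, quadrant-transition counting,
#' dinucleotide alteration and CpG-fate spectra (grouped by source species x
#' counterpart island status), deamination enrichment (type-change pairs vs
#' island-conserved pairs), indel detection at the relaxed score cutoff with
#' flank filtering, repeat association of indels, logo matrix and TATAAA
#' scan. Per-stage input/surviving counts are collected, and eight TSV
#' reports plus a JSON summary are written when `out_dir` is given. The run
#' is deterministic: identical inputs yield byte-identical reports.
#'
#' @param pairs Tibble with `seq_a`, `seq_b`, `tss_a`, `tss_b` (0-based +1
#'   base indices) and optionally `pair`, `gene`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for reports (created if needed), or NULL
#'   to skip writing.
#' @param refseq,tss_table Optional inputs for the RefSeq-offset stage (see
#'   [refseq_dbtss_offsets()]); when absent the offsets report is empty.
#' @return A `promdiv_report` list: `classification`, `type_changes`,
#'   `spectrum`, `fate`, `enrichment`, `indels`, `single_nt_bias`,
#'   `length_histogram`, `tata`, `logo`, `offsets`, `counts`.
#' @export
run_pipeline <- function(pairs, config = pipeline_config(), out_dir = NULL,
                         refseq = NULL, tss_table = NULL) {
  stopifnot(all(c("seq_a", "seq_b", "tss_a", "tss_b") %in% names(pairs)))
  if (!("pair" %in% names(pairs))) pairs$pair <- seq_len(nrow(pairs))
  counts <- list(pairs_in = nrow(pairs))

  ## classification of both windows
  stats_a <- cpg_stats(pairs$seq_a)
  stats_b <- cpg_stats(pairs$seq_b)
  cls_a <- classify_promoters(stats_a, gc_threshold = config$gc_threshold,
                              score_threshold = config$score_threshold)
  cls_b <- classify_promoters(stats_b, gc_threshold = config$gc_threshold,
                              score_threshold = config$score_threshold)
  classification <- tibble(
    pair = pairs$pair,
    gene = pairs[["gene"]] %||% as.character(pairs$pair),
    gc_a = stats_a$gc, score_a = stats_a$score,
    quadrant_a = cls_a$quadrant, island_a = cls_a$island,
    gc_b = stats_b$gc, score_b = stats_b$score,
    quadrant_b = cls_b$quadrant, island_b = cls_b$island,
    group = pair_group(cls_a$island, cls_b$island)
  )

  ## alignment + refinement filter
  aligned <- align_pairs(pairs, config$align)
  aligned <- dplyr::left_join(
    aligned,
    dplyr::select(classification, "pair", "quadrant_a", "quadrant_b",
                  "island_a", "island_b", "group"),
    by = "pair"
  )
  refined <- filter_pairs(aligned, min_score = config$min_align_score,
                          require_yr_match = TRUE)
  counts$refined <- nrow(refined)
  counts$refined_attrition <- as.list(attr(refined, "attrition"))

  type_changes <- count_type_changes(refined$quadrant_a, refined$quadrant_b)

  ## divergence spectra, grouped by counterpart island status
  spectrum <- fate <- NULL
  if (nrow(refined) > 0) {
    refined$counter_island_b <- ifelse(refined$island_b, "counterpart-island",
                                       "counterpart-non-island")
    refined$counter_island_a <- ifelse(refined$island_a, "counterpart-island",
                                       "counterpart-non-island")
    sp_ab <- dinuc_alteration_rates(refined, "a_to_b", group = "counter_island_b")
    sp_ba <- dinuc_alteration_rates(refined, "b_to_a", group = "counter_island_a")
    spectrum <- dplyr::bind_rows(
      dplyr::mutate(as_tibble(sp_ab), direction = "a_to_b", .before = 1),
      dplyr::mutate(as_tibble(sp_ba), direction = "b_to_a", .before = 1)
    )
    fate <- dplyr::bind_rows(
      dplyr::mutate(as_tibble(cpg_fate_spectrum(refined, "a_to_b", group = "group")),
                    direction = "a_to_b", .before = 1),
      dplyr::mutate(as_tibble(cpg_fate_spectrum(refined, "b_to_a", group = "group")),
                    direction = "b_to_a", .before = 1)
    )
  } else {
    spectrum <- tibble(direction = character(0), group = character(0),
                       dinuc = character(0), total = integer(0),
                       altered = integer(0), rate = numeric(0))
    fate <- tibble(direction = character(0), group = character(0),
                   fate = character(0), count = integer(0),
                   fraction = numeric(0))
  }

  ## deamination enrichment: type-change pairs vs island-conserved pairs
  changed <- dplyr::filter(refined, .data$group %in% c("hCmN", "hNmC"))
  conserved <- dplyr::filter(refined, .data$group == "hCmC")
  enrichment <- if (nrow(changed) > 0 && nrow(conserved) > 0) {
    deamination_enrichment(changed, conserved)
  } else {
    tibble(direction = character(0), freq_changed = numeric(0),
           freq_conserved = numeric(0), ratio = numeric(0),
           infinite = logical(0))
  }

  ## indel stage at the relaxed cutoff
  indel_pairs <- filter_pairs(aligned, min_score = config$indel_align_score,
                              require_yr_match = TRUE)
  counts$indel_stage_pairs <- nrow(indel_pairs)
  sites <- detect_indels_cohort(indel_pairs, flank_width = config$flank_width)
  sites <- flank_filter(sites, min_match = config$min_flank_match)
  if (nrow(sites) > 0) {
    sites <- dplyr::left_join(
      sites, dplyr::select(classification, "pair", "group"), by = "pair"
    )
  } else {
    sites$group <- factor(character(0), levels = levels(pair_group(TRUE, TRUE)))
  }
  counts$indel_sites <- nrow(sites)
  counts$indel_sites_kept <- sum(sites$keep)
  kept <- dplyr::filter(sites, .data$keep)

  assoc <- repeat_association_cohort(kept, indel_pairs,
                                     neighborhood = config$dotplot_neighborhood,
                                     window = config$dotplot_window)
  if (nrow(assoc) > 0) {
    sites <- dplyr::left_join(
      sites,
      dplyr::select(assoc, "pair", "col_start", "carrier", "tandem", "inverted"),
      by = c("pair", "col_start", "carrier")
    )
  } else {
    sites$tandem <- NA
    sites$inverted <- NA
  }
  bias <- single_nt_bias(kept)
  lengths_hist <- indel_length_histogram(kept)

  ## motif stage (windows of species A)
  logo_windows <- tibble(
    seq = substr(pairs$seq_a,
                 pairs$tss_a - config$logo_upstream + 1L,
                 pairs$tss_a + config$logo_downstream + 1L),
    upstream = config$logo_upstream, downstream = config$logo_downstream
  )
  logo <- position_frequency_matrix(logo_windows)
  tata <- tataaa_scan(pairs$seq_a, upstream = pairs$tss_a,
                      scan_width = config$tata_scan_width)

  ## optional RefSeq-offset stage
  offsets <- if (!is.null(refseq) && !is.null(tss_table)) {
    refseq_dbtss_offsets(refseq, tss_table)
  } else {
    tibble(gene = character(0), strand = character(0), offset = integer(0))
  }

  report <- structure(
    list(classification = classification, type_changes = type_changes,
         spectrum = spectrum, fate = fate, enrichment = enrichment,
         indels = sites, single_nt_bias = bias,
         length_histogram = lengths_hist, tata = tata, logo = logo,
         offsets = offsets, counts = counts, config = config),
    class = "promdiv_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.promdiv_report <- function(x, ...) {
  cat("<promdiv_report>\n")
  cat("  pairs in:            ", x$counts$pairs_in, "\n")
  cat("  refined alignments:  ", x$counts$refined, "\n")
  cat("  indel-stage pairs:   ", x$counts$indel_stage_pairs, "\n")
  cat("  indel sites (kept):  ", x$counts$indel_sites,
      sprintf("(%d)", x$counts$indel_sites_kept), "\n")
  invisible(x)
}

matrix_to_tibble <- function(m, rowname) {
  df <- as_tibble(as.data.frame.matrix(m), rownames = rowname)
  df
}

#' Write the eight TSV reports and JSON summary of a pipeline run
#'
#' Files: `classification.tsv`, `type_changes.tsv`, `dinuc_rates.tsv`,
#' `cpg_fate.tsv`, `indels.tsv`, `single_nt_bias.tsv`, `tata_histogram.tsv`,
#' `refseq_offsets.tsv`, plus `summary.json` (stage counts, enrichment,
#' length histogram, parameters).
#'
#' @param report A `promdiv_report`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_tsv(df, file.path(out_dir, name), progress = FALSE)
  }
  w(report$classification, "classification.tsv")
  w(matrix_to_tibble(report$type_changes$quadrant, "quadrant_a"),
    "type_changes.tsv")
  w(report$spectrum, "dinuc_rates.tsv")
  w(report$fate, "cpg_fate.tsv")
  w(dplyr::select(report$indels, -dplyr::any_of("group")) |>
      dplyr::mutate(group = as.character(report$indels$group)),
    "indels.tsv")
  w(report$single_nt_bias, "single_nt_bias.tsv")
  w(report$tata, "tata_histogram.tsv")
  w(report$offsets, "refseq_offsets.tsv")
  summary <- list(
    counts = report$counts,
    island_table = report$type_changes$island,
    enrichment = report$enrichment,
    length_histogram = report$length_histogram,
    parameters = report$config[setdiff(names(report$config), "align")]
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
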