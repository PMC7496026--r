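#' Dinucleotide alteration rates between aligned promoters
#'
#' Walks every overlapping dinucleotide of the ungapped source row (positions
#' i, i+1) of each alignment and asks whether its aligned counterpart is
#' intact. A source dinucleotide is *altered* if either counterpart base
#' differs, is a gap or is `N`, or if an insertion in the counterpart
#' intervenes between the two columns. Source dinucleotides containing `N`
#' are not counted. Occurrences are pooled over all alignments (optionally
#' within groups).
#'
#' @param aligned Tibble with gapped rows `row_a`, `row_b`; any further
#'   columns are preserved for grouping.
#' @param direction `"a_to_b"` (row A supplies source dinucleotides) or
#'   `"b_to_a"`.
#' @param group Optional name of a column of `aligned` to aggregate within.
#' @return A `dinuc_spectrum` tibble: `group` (if requested), `dinuc` (16
#'   levels), `total`, `altered`, `rate`.
#' @export
dinuc_alteration_rates <- function(aligned, direction = c("a_to_b", "b_to_a"),
                                   group = NULL) {
  direction <- match.arg(direction)
  counts <- purrr::map(seq_len(nrow(aligned)), function(i) {
    pair_dinuc_counts(aligned$row_a[i], aligned$row_b[i], direction)
  })
  key <- if (is.null(group)) rep("all", nrow(aligned)) else
    as.character(aligned[[group]])
  out <- tibble(
    group = rep(key, each = 16L),
    dinuc = rep(DINUCLEOTIDES, length(counts)),
    total = unlist(purrr::map(counts, "total")),
    altered = unlist(purrr::map(counts, "altered"))
  ) |>
    dplyr::group_by(.data$group, .data$dinuc) |>
    dplyr::summarise(total = sum(.data$total), altered = sum(.data$altered),
                     .groups = "drop") |>
    dplyr::mutate(rate = ifelse(.data$total > 0, .data$altered / .data$total,
                                NA_real_),
                  dinuc = factor(.data$dinuc, levels = DINUCLEOTIDES)) |>
    dplyr::arrange(.data$group, .data$dinuc)
  if (is.null(group)) out$group <- NULL
  class(out) <- c("dinuc_spectrum", class(out))
  out
}

# Source-dinucleotide totals/altered counts for one alignment.
pair_dinuc_counts <- function(row_a, row_b, direction) {
  if (direction == "b_to_a") { tmp <- row_a; row_a <- row_b; row_b <- tmp }
  s <- seq_chars(row_a)[[1]]
  t <- seq_chars(row_b)[[1]]
  idx <- which(s != "-")
  total <- setNames(integer(16L), DINUCLEOTIDES)
  altered <- setNames(integer(16L), DINUCLEOTIDES)
  if (length(idx) < 2L) return(list(total = total, altered = altered))
  i1 <- idx[-length(idx)]
  i2 <- idx[-1]
  b1 <- s[i1]; b2 <- s[i2]
  valid <- b1 %in% DNA_BASES4 & b2 %in% DNA_BASES4
  dinuc <- paste0(b1, b2)[valid]
  t1 <- t[i1][valid]; t2 <- t[i2][valid]
  alt <- t1 != b1[valid] | t2 != b2[valid] |
    t1 %in% c("-", "N") | t2 %in% c("-", "N") |
    (i2 - i1)[valid] != 1L
  tt <- table(factor(dinuc, levels = DINUCLEOTIDES))
  ta <- table(factor(dinuc[alt], levels = DINUCLEOTIDES))
  total[] <- as.integer(tt)
  altered[] <- as.integer(ta)
  list(total = total, altered = altered)
}

CPG_FATES <- c("CpG", "TpG", "CpA", "other", "gap")

#' Fate spectrum of source CpG sites
#'
#' Classifies every CpG dinucleotide of the ungapped source row by the
#' counterpart dinucleotide it aligns to: conserved `CpG`, the deamination
#' products `TpG` and `CpA`, any `other` dinucleotide, or `gap` (a gap or `N`
#' in the counterpart, or an intervening insertion).
#'
#' @inheritParams dinuc_alteration_rates
#' @return A `cpg_fate` tibble: `group` (if requested), `fate` (5 levels),
#'   `count`, `fraction` (fractions sum to 1 within each group with >= 1
#'   source CpG).
#' @export
cpg_fate_spectrum <- function(aligned, direction = c("a_to_b", "b_to_a"),
                              group = NULL) {
  direction <- match.arg(direction)
  fates <- purrr::map(seq_len(nrow(aligned)), function(i) {
    pair_cpg_fates(aligned$row_a[i], aligned$row_b[i], direction)
  })
  key <- if (is.null(group)) rep("all", nrow(aligned)) else
    as.character(aligned[[group]])
  out <- tibble(
    group = rep(key, vapply(fates, length, integer(1))),
    fate = unlist(fates, use.names = FALSE)
  ) |>
    dplyr::count(.data$group, fate = factor(.data$fate, levels = CPG_FATES),
                 .drop = FALSE, name = "count") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(fraction = if (sum(.data$count) > 0)
      .data$count / sum(.data$count) else NA_real_) |>
    dplyr::ungroup()
  if (is.null(group)) out$group <- NULL
  class(out) <- c("cpg_fate", class(out))
  out
}

# Character vector of fates, one per source CpG, for one alignment.
pair_cpg_fates <- function(row_a, row_b, direction) {
  if (direction == "b_to_a") { tmp <- row_a; row_a <- row_b; row_b <- tmp }
  s <- seq_chars(row_a)[[1]]
  t <- seq_chars(row_b)[[1]]
  idx <- which(s != "-")
  if (length(idx) < 2L) return(character(0))
  i1 <- idx[-length(idx)]
  i2 <- idx[-1]
  at_cpg <- s[i1] == "C" & s[i2] == "G"
  i1 <- i1[at_cpg]; i2 <- i2[at_cpg]
  if (length(i1) == 0) return(character(0))
  t1 <- t[i1]; t2 <- t[i2]
  gap <- t1 %in% c("-", "N") | t2 %in% c("-", "N") | (i2 - i1) != 1L
  counter <- paste0(t1, t2)
  dplyr::case_when(
    gap ~ "gap",
    counter == "CG" ~ "CpG",
    counter == "TG" ~ "TpG",
    counter == "CA" ~ "CpA",
    TRUE ~ "other"
  )
}

#' Deamination enrichment between promoter groups
#'
#' Ratio of per-CpG deamination frequencies (fraction of source CpGs whose
#' fate is TpG or CpA) in a "changed" group of alignments relative to a
#' "conserved" group, per direction. A conserved group with zero deamination
#' events yields an infinite ratio, flagged in the output.
#'
#' @param changed,conserved Aligned-pair tibbles (`row_a`, `row_b`), e.g. the
#'   promoter-type-change pairs and the island-conserved pairs.
#' @return Tibble with one row per direction: `direction`, `freq_changed`,
#'   `freq_conserved`, `ratio`, `infinite` (logical flag).
#' @export
deamination_enrichment <- function(changed, conserved) {
  stopifnot(nrow(changed) > 0, nrow(conserved) > 0)
  one <- function(direction) {
    fc <- deamination_freq(changed, direction)
    fv <- deamination_freq(conserved, direction)
    if (is.na(fc) || is.na(fv)) {
      abort("deamination_enrichment() requires >= 1 source CpG in each group")
    }
    ratio <- if (fv == 0) Inf else fc / fv
    tibble(direction = direction, freq_changed = fc, freq_conserved = fv,
           ratio = ratio, infinite = is.infinite(ratio))
  }
  dplyr::bind_rows(one("a_to_b"), one("b_to_a"))
}

deamination_freq <- function(aligned, direction) {
  f <- cpg_fate_spectrum(aligned, direction)
  n <- sum(f$count)
  if (n == 0) return(NA_real_)
  sum(f$count[f$fate %in% c("TpG", "CpA")]) / n
}

#' Estimate the CpG deamination multiplier from aligned pairs
#'
#' Recovers the factor by which CpG-context transitions outpace the baseline
#' substitution rate from a cohort of pairwise alignments of a two-branch
#' orthologous design. Both ingredients are per-branch, per-base hazards:
#'
#' * the deamination hazard `h` comes from the CpG fate channel: among
#'   source CpGs aligned without a gap, the deamination fates satisfy
#'   `f(TpG) + f(CpA) = 2 h (1 - h)` (a source CpG is conditioned on having
#'   survived its own branch, so only the counterpart branch contributes),
#'   giving `h = (1 - sqrt(1 - 2 s)) / 2`;
#' * the baseline hazard `b` is the mismatch rate at *A/T-embedded* sites —
#'   source positions carrying A or T whose immediate neighbours are A/T in
#'   both species and identical across them — converted to a one-branch
#'   hazard via `b = 1 - sqrt(1 - rate)`. This neighbourhood condition is
#'   what makes the background clean: deamination products are T (from CpG
#'   C) and A (from CpG G), but they sit next to a G, a C, or a fellow
#'   product that the counterpart species still carries as C/G, so such
#'   sites cannot enter the background set.
#'
#' Two refinements keep the moments clean at high multipliers, where
#' deamination products (T from CpG cytosines, A from CpG guanines) pervade
#' the sequence:
#'
#' * the baseline uses only the *A-versus-T* mismatches at those sites —
#'   deamination mismatches are always T:C or A:G, so the A:T channel is
#'   deamination-free; with per-branch hazard `b` its rate is
#'   `q (1 - q)` for `q = 2b/3`;
#' * source CpGs that are not ancestral (created by a baseline substitution
#'   on the source branch) leak into the fate channel; their expected
#'   contributions to the TpG, CpA and other fates are estimated from the
#'   counterpart species' dinucleotide composition (`C_xG * b/3` CpGs arise
#'   from each `xG`, etc.) and subtracted before inverting `s = 2 h (1 - h)`.
#'
#' The estimate is `h / b`, averaged over both directions.
#'
#' @param aligned Tibble with gapped rows `row_a`, `row_b`
#'   (e.g. from [align_pairs()]).
#' @return The estimated multiplier (a single number).
#' @export
estimate_cpg_multiplier <- function(aligned) {
  one <- function(direction) {
    rev_direction <- if (direction == "a_to_b") "b_to_a" else "a_to_b"
    ## baseline hazard from the deamination-free A:T channel
    bg <- at_background_rate(aligned, direction)
    if (bg$n == 0) abort("no clean A/T-embedded background sites")
    p <- bg$at_mismatches / bg$n
    if (p >= 0.25) abort("A:T mismatch rate too high; hazard not identifiable")
    b <- 3 * (1 - sqrt(1 - 4 * p)) / 4
    if (b == 0) return(Inf)
    ## deamination hazard from the CpG fate channel, influx-corrected
    f <- cpg_fate_spectrum(aligned, direction)
    counts <- setNames(f$count, as.character(f$fate))
    nongap <- sum(counts[c("CpG", "TpG", "CpA", "other")])
    if (nongap == 0) abort("no gap-free source CpG sites")
    cnt <- dinuc_alteration_rates(aligned, rev_direction)  # counterpart totals
    dn <- setNames(cnt$total, as.character(cnt$dinuc))
    influx_tpg <- dn[["TG"]] * b / 3
    influx_cpa <- dn[["CA"]] * b / 3
    influx_other <- (dn[["AG"]] + dn[["GG"]] + dn[["CC"]] + dn[["CT"]]) * b / 3
    ancestral <- nongap - influx_tpg - influx_cpa - influx_other
    s <- (counts[["TpG"]] + counts[["CpA"]] - influx_tpg - influx_cpa) /
      ancestral
    if (is.na(s) || s <= 0 || s >= 0.5 || ancestral <= 0) {
      abort("deamination fate fraction not identifiable")
    }
    h <- (1 - sqrt(1 - 2 * s)) / 2
    h / b
  }
  mean(c(one("a_to_b"), one("b_to_a")))
}

# A/T-embedded background sites: source positions carrying A or T whose
# immediate neighbours are A/T in both species and identical across them.
# Returns the site count and the number of A-versus-T mismatches among them.
at_background_rate <- function(aligned, direction) {
  at <- c("A", "T")
  tot <- 0L; at_mis <- 0L
  for (i in seq_len(nrow(aligned))) {
    s <- seq_chars(aligned$row_a[i])[[1]]
    t <- seq_chars(aligned$row_b[i])[[1]]
    if (direction == "b_to_a") { tmp <- s; s <- t; t <- tmp }
    n <- length(s)
    if (n < 3) next
    mid <- 2:(n - 1)
    ok <- s[mid] %in% at & t[mid] %in% DNA_BASES4 &
      s[mid - 1] %in% at & s[mid + 1] %in% at &
      t[mid - 1] == s[mid - 1] & t[mid + 1] == s[mid + 1]
    tot <- tot + sum(ok)
    at_mis <- at_mis + sum(ok & t[mid] %in% at & s[mid] != t[mid])
  }
  list(n = tot, at_mismatches = at_mis)
}

#' Heat-map of a dinucleotide alteration spectrum
#'
#' @param object A `dinuc_spectrum`.
#' @param ... Unused.
#' @return A ggplot object (tile heat map, dinucleotides on the x axis).
#' @method autoplot dinuc_spectrum
#' @export
autoplot.dinuc_spectrum <- function(object, ...) {
  df <- as_tibble(object)
  if (is.null(df[["group"]])) df$group <- "all"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dinuc, y = .data$group,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = "dinucleotide", y = NULL, fill = "alteration rate") +
    ggplot2::theme_minimal()
}

#' Band graph of CpG fates
#'
#' @param object A `cpg_fate`.
#' @param ... Unused.
#' @return A ggplot object (stacked horizontal bands per group).
#' @method autoplot cpg_fate
#' @export
autoplot.cpg_fate <- function(object, ...) {
  df <- as_tibble(object)
  if (is.null(df[["group"]])) df$group <- "all"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$group,
                                   fill = .data$fate)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "fraction of source CpG sites", y = NULL, fill = "fate") +
    ggplot2::theme_minimal()
}
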