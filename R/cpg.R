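#' G+C content and CpG observed/expected score
#'
#' Computes, per sequence: length `n`, base counts `n_c`/`n_g`, overlapping
#' `CG` dinucleotide count `n_cpg`, G+C content `gc = (n_c + n_g) / n`, and
#' the Gardiner-Garden & Frommer obs/exp CpG score
#' `score = n_cpg * n / (n_c * n_g)` (defined as 0 when `n_c * n_g = 0`).
#' `N` bases are excluded from the base and dinucleotide counts but still
#' count toward the length `n`, matching the fixed-length window convention.
#'
#' @param seq Character vector of uppercase A/C/G/T/N sequences.
#' @return Tibble with columns `n`, `n_cpg`, `n_c`, `n_g`, `gc`, `score`
#'   (one row per input sequence).
#' @export
#' @examples
#' cpg_stats(c("CGCG", "CCGG", "ATAT"))
cpg_stats <- function(seq) {
  stopifnot(is.character(seq))
  if (length(seq) == 0) {
    return(tibble(n = integer(0), n_cpg = integer(0), n_c = integer(0),
                  n_g = integer(0), gc = numeric(0), score = numeric(0)))
  }
  if (any(is.na(seq)) || any(nchar(seq) == 0)) {
    abort("cpg_stats() is undefined for empty or missing sequences")
  }
  n <- nchar(seq)
  n_c <- stringr::str_count(seq, stringr::fixed("C"))
  n_g <- stringr::str_count(seq, stringr::fixed("G"))
  n_cpg <- stringr::str_count(seq, stringr::fixed("CG"))
  denom <- as.numeric(n_c) * as.numeric(n_g)
  score <- ifelse(denom == 0, 0, as.numeric(n_cpg) * n / denom)
  tibble(n = n, n_cpg = n_cpg, n_c = n_c, n_g = n_g,
         gc = (n_c + n_g) / n, score = score)
}

PROMOTER_QUADRANTS <- c("low-GC/high-CpG", "high-GC/high-CpG",
                        "low-GC/low-CpG", "high-GC/low-CpG")

#' Classify promoters by G+C content and CpG score
#'
#' A promoter is a CpG-island promoter iff `gc >= gc_threshold` and
#' `score >= score_threshold` (thresholds inclusive; defaults 0.5 and 0.6).
#' The two comparisons also assign one of four quadrants:
#' low-GC/high-CpG, high-GC/high-CpG (the island quadrant), low-GC/low-CpG,
#' high-GC/low-CpG.
#'
#' @param gc Tibble with `gc` and `score` columns (e.g. from [cpg_stats()]),
#'   or a numeric vector of G+C contents.
#' @param score Numeric vector of CpG scores (only when `gc` is numeric).
#' @param gc_threshold,score_threshold Inclusive thresholds.
#' @return Tibble with columns `quadrant` (factor with the four levels) and
#'   `island` (logical).
#' @export
classify_promoters <- function(gc, score = NULL, gc_threshold = 0.5,
                               score_threshold = 0.6) {
  if (is.data.frame(gc)) {
    score <- gc$score
    gc <- gc$gc
  }
  stopifnot(gc_threshold >= 0, gc_threshold <= 1,
            score_threshold >= 0, score_threshold <= 1)
  high_gc <- gc >= gc_threshold
  high_cpg <- score >= score_threshold
  quadrant <- dplyr::case_when(
    !high_gc & high_cpg ~ PROMOTER_QUADRANTS[1],
    high_gc & high_cpg ~ PROMOTER_QUADRANTS[2],
    !high_gc & !high_cpg ~ PROMOTER_QUADRANTS[3],
    TRUE ~ PROMOTER_QUADRANTS[4]
  )
  tibble(quadrant = factor(quadrant, levels = PROMOTER_QUADRANTS),
         island = high_gc & high_cpg)
}

#' Pair-group labels from two island flags
#'
#' Groups orthologous promoter pairs by island status in each species:
#' `hCmC` (island in both), `hCmN`, `hNmC`, `hNmN`. "h" refers to the first
#' (query) species of each pair and "m" to the second.
#'
#' @param island_a,island_b Logical vectors of island flags.
#' @return Factor with levels `hCmC`, `hCmN`, `hNmC`, `hNmN`.
#' @export
pair_group <- function(island_a, island_b) {
  lab <- paste0("h", ifelse(island_a, "C", "N"), "m", ifelse(island_b, "C", "N"))
  factor(lab, levels = c("hCmC", "hCmN", "hNmC", "hNmN"))
}

#' Count promoter-type changes between species
#'
#' Tallies the 4x4 quadrant transition matrix between the two species of each
#' pair, plus the 2x2 island/non-island table obtained by collapsing
#' quadrants on the island flag.
#'
#' @param class_a,class_b Quadrant factors (from [classify_promoters()]) for
#'   species A and B of each pair.
#' @return List with `quadrant` (4x4 integer matrix, species A in rows) and
#'   `island` (2x2 matrix with rows/cols `island`, `non_island`).
#' @export
count_type_changes <- function(class_a, class_b) {
  class_a <- factor(class_a, levels = PROMOTER_QUADRANTS)
  class_b <- factor(class_b, levels = PROMOTER_QUADRANTS)
  quad <- table(a = class_a, b = class_b)
  island_of <- function(f) factor(
    ifelse(f == "high-GC/high-CpG", "island", "non_island"),
    levels = c("island", "non_island")
  )
  isl <- table(a = island_of(class_a), b = island_of(class_b))
  list(quadrant = unclass(as.matrix(quad)), island = unclass(as.matrix(isl)))
}

#' CpG-island gain trajectory under successive motif insertions
#'
#' Inserts successive tandem copies of a CpG-containing motif (default
#' `TCGGC`) into a sequence and re-scores it after every copy, recording when
#' the classification flips to CpG-island. This reproduces, in a controlled
#' setting, island gain through expansion of CpG-containing repeat units.
#'
#' @param seq A single sequence (e.g. a non-island 601-nt promoter).
#' @param motif Repeat unit to insert.
#' @param at 0-based position at which the tandem array grows; defaults to
#'   the sequence midpoint.
#' @param max_copies Maximum number of copies to insert.
#' @param gc_threshold,score_threshold Classification thresholds.
#' @return Tibble with one row per copy number (0 .. `max_copies`): `copies`,
#'   `n`, `gc`, `score`, `island`. Attribute `flip_at` gives the first copy
#'   number classified as island (NA if never).
#' @export
island_gain_trajectory <- function(seq, motif = "TCGGC", at = NULL,
                                   max_copies = 60L, gc_threshold = 0.5,
                                   score_threshold = 0.6) {
  assert_seq(seq)
  at <- at %||% (nchar(seq) %/% 2L)
  rows <- vector("list", max_copies + 1L)
  cur <- seq
  insert_point <- at
  for (k in 0:max_copies) {
    st <- cpg_stats(cur)
    cl <- classify_promoters(st, gc_threshold = gc_threshold,
                             score_threshold = score_threshold)
    rows[[k + 1L]] <- tibble(copies = k, n = st$n, gc = st$gc,
                             score = st$score, island = cl$island)
    cur <- paste0(substr0(cur, 0L, insert_point), motif,
                  substr0(cur, insert_point, nchar(cur)))
    insert_point <- insert_point + nchar(motif)
  }
  out <- dplyr::bind_rows(rows)
  flips <- which(out$island)
  attr(out, "flip_at") <- if (length(flips)) out$copies[flips[1]] else NA_integer_
  out
}
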