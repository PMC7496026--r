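#' Alignment parameters
#'
#' Scoring scheme for the affine-gap global aligner. A gap of length L is
#' penalised `gap_open + gap_extension * L`. The defaults (match +1,
#' mismatch -1, open 10, extension 0.2 per gapped base) keep gaps rare but
#' cheap to extend, as is usual for diverged non-coding DNA; they are pinned
#' by the test suite and fully configurable. `N` scores as a mismatch
#' against every letter, including `N`.
#'
#' @param match,mismatch Per-column substitution scores.
#' @param gap_open,gap_extension Affine gap penalties (both >= 0).
#' @return An `align_params` list.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = 10,
                         gap_extension = 0.2) {
  stopifnot(gap_open >= 0, gap_extension >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extension = gap_extension), class = "align_params")
}

substitution_matrix <- function(params) {
  letters5 <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(m)[1:4] <- params$match
  m["N", "N"] <- params$mismatch
  m
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under affine-gap scoring (via
#' Biostrings' dynamic-programming engine). Output is deterministic.
#'
#' @param a,b Sequences to align (uppercase A/C/G/T/N).
#' @param params An [align_params()] object.
#' @return A `pairwise_alignment`: list with gapped rows `row_a`, `row_b`,
#'   the raw DP `score_raw`, the percent-identity `score` (see
#'   [alignment_score()]) and `params`.
#' @export
#' @examples
#' global_align("ACGT", "AGT")
global_align <- function(a, b, params = align_params()) {
  assert_seq(a); assert_seq(b)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = substitution_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extension
  )
  row_a <- as.character(Biostrings::alignedPattern(al))
  row_b <- as.character(Biostrings::alignedSubject(al))
  new_pairwise_alignment(unname(row_a), unname(row_b),
                         score_raw = Biostrings::score(al), params = params)
}

new_pairwise_alignment <- function(row_a, row_b, score_raw = NA_real_,
                                   params = NULL) {
  stopifnot(nchar(row_a) == nchar(row_b))
  structure(
    list(row_a = row_a, row_b = row_b, score_raw = score_raw,
         score = alignment_score(row_a, row_b), params = params),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment>", nchar(x$row_a), "columns, score",
      round(x$score, 1), "\n")
  cat(" A:", x$row_a, "\n B:", x$row_b, "\n")
  invisible(x)
}

#' Per-column tidy view of a pairwise alignment
#'
#' @param x A `pairwise_alignment`.
#' @param ... Unused.
#' @return Tibble with 0-based `col`, characters `a` and `b`, and `class`
#'   (`match`, `mismatch`, `gap_a`, `gap_b`).
#' @method tidy pairwise_alignment
#' @export
tidy.pairwise_alignment <- function(x, ...) {
  a <- seq_chars(x$row_a)[[1]]
  b <- seq_chars(x$row_b)[[1]]
  cls <- dplyr::case_when(
    a == "-" ~ "gap_a",
    b == "-" ~ "gap_b",
    a == b & a %in% DNA_BASES4 ~ "match",
    TRUE ~ "mismatch"
  )
  tibble(col = seq_along(a) - 1L, a = a, b = b, class = cls)
}

#' One-row summary of a pairwise alignment
#'
#' @param x A `pairwise_alignment`.
#' @param ... Unused.
#' @return Tibble with columns `columns`, `matches`, `mismatches`, `gaps_a`,
#'   `gaps_b`, `score_raw`, `score`.
#' @method glance pairwise_alignment
#' @export
glance.pairwise_alignment <- function(x, ...) {
  cols <- tidy(x)
  tibble(
    columns = nrow(cols),
    matches = sum(cols$class == "match"),
    mismatches = sum(cols$class == "mismatch"),
    gaps_a = sum(cols$class == "gap_a"),
    gaps_b = sum(cols$class == "gap_b"),
    score_raw = x$score_raw,
    score = x$score
  )
}

#' Percent-identity alignment score
#'
#' `100 * (match columns) / min(ungapped length A, ungapped length B)`, the
#' pairwise-score convention used for the 90 (refinement) and 80 (indel
#' stage) cutoffs. Columns where either letter is `N` do not count as
#' matches.
#'
#' @param row_a,row_b Gapped alignment rows (equal length), or a
#'   `pairwise_alignment` as `row_a`.
#' @return Numeric score in `[0, 100]` (vectorised over rows).
#' @export
alignment_score <- function(row_a, row_b = NULL) {
  if (inherits(row_a, "pairwise_alignment")) {
    row_b <- row_a$row_b
    row_a <- row_a$row_a
  }
  stopifnot(nchar(row_a) == nchar(row_b))
  a <- seq_chars(row_a)
  b <- seq_chars(row_b)
  matches <- mapply(function(x, y) sum(x == y & x %in% DNA_BASES4), a, b)
  len_a <- nchar(gsub("-", "", row_a, fixed = TRUE))
  len_b <- nchar(gsub("-", "", row_b, fixed = TRUE))
  unname(100 * matches / pmin(len_a, len_b))
}

#' Align a cohort of promoter pairs
#'
#' Vectorised global alignment over a pairs table; the anchored TSS index of
#' each row is carried through so downstream filters can locate the YR
#' dinucleotide columns.
#'
#' @param pairs Tibble with sequence columns `seq_a`, `seq_b` and (optionally)
#'   0-based TSS indices `tss_a`, `tss_b`.
#' @param params An [align_params()] object.
#' @return The input tibble with `row_a`, `row_b` (gapped rows) and `score`
#'   columns added.
#' @export
align_pairs <- function(pairs, params = align_params()) {
  stopifnot(all(c("seq_a", "seq_b") %in% names(pairs)))
  if (nrow(pairs) == 0) {
    return(dplyr::mutate(pairs, row_a = character(0), row_b = character(0),
                         score = numeric(0)))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(pairs$seq_a), Biostrings::DNAStringSet(pairs$seq_b),
    type = "global", substitutionMatrix = substitution_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extension
  )
  pairs$row_a <- unname(as.character(Biostrings::alignedPattern(al)))
  pairs$row_b <- unname(as.character(Biostrings::alignedSubject(al)))
  pairs$score <- alignment_score(pairs$row_a, pairs$row_b)
  pairs
}

# Map 0-based ungapped positions of a gapped row to 0-based column indices.
ungapped_to_columns <- function(row) {
  chars <- seq_chars(row)[[1]]
  which(chars != "-") - 1L
}

#' Filter aligned pairs on score and YR-consensus agreement
#'
#' Keeps pairs whose percent-identity score reaches `min_score` and (by
#' default) whose YR initiator dinucleotide is identical in the two species
#' at the anchored TSS columns.
#'
#' @param aligned Tibble from [align_pairs()]; YR matching needs `tss_a`
#'   (0-based TSS index in `seq_a`) and `tss_b`.
#' @param min_score Minimum percent-identity score (default 90).
#' @param require_yr_match Also require identical Y and R bases across
#'   species at the anchor.
#' @return The surviving rows, with a logical `yr_match` column added when
#'   checked. Attribute `attrition` is a named count of drops per reason.
#' @export
filter_pairs <- function(aligned, min_score = 90, require_yr_match = TRUE) {
  score_ok <- aligned$score >= min_score
  if (require_yr_match) {
    stopifnot(all(c("tss_a", "tss_b") %in% names(aligned)))
    yr_ok <- vapply(seq_len(nrow(aligned)), function(i) {
      yr_columns_match(aligned$row_a[i], aligned$row_b[i],
                       aligned$tss_a[i], aligned$tss_b[i])
    }, logical(1))
    aligned$yr_match <- yr_ok
  } else {
    yr_ok <- rep(TRUE, nrow(aligned))
  }
  out <- aligned[score_ok & yr_ok, ]
  attr(out, "attrition") <- c(low_score = sum(!score_ok),
                              yr_mismatch = sum(score_ok & !yr_ok))
  out
}

# TRUE iff the Y (TSS-1) and R (TSS) bases of row A's source sequence align to
# identical bases in row B, and those columns carry row B's own Y/R positions.
yr_columns_match <- function(row_a, row_b, tss_a, tss_b) {
  cols_a <- ungapped_to_columns(row_a)
  cols_b <- ungapped_to_columns(row_b)
  ca <- cols_a[c(tss_a, tss_a + 1L)]  # Y, R columns (tss_a is 0-based; +1 index)
  cb <- cols_b[c(tss_b, tss_b + 1L)]
  if (any(is.na(ca)) || any(is.na(cb)) || !identical(ca, cb)) return(FALSE)
  a <- seq_chars(row_a)[[1]][ca + 1L]
  b <- seq_chars(row_b)[[1]][ca + 1L]
  all(a == b) && all(a %in% DNA_BASES4)
}

#' Select the best ortholog candidate among BLAT hits
#'
#' Hits must reach `min_identity` (matches over target span) and `min_span`
#' (target span in bp); among passing hits the one with the largest target
#' span wins.
#'
#' @param hits PSL hit tibble ([read_psl()]) for one query promoter.
#' @param min_identity Minimum identity (default 0.90).
#' @param min_span Minimum target span in bp (default 200).
#' @return One-row tibble (the selected hit) or a zero-row tibble if no hit
#'   passes.
#' @export
select_candidate <- function(hits, min_identity = 0.90, min_span = 200L) {
  passing <- dplyr::filter(hits, .data$identity >= min_identity,
                           .data$span > min_span)
  if (nrow(passing) == 0) return(passing)
  dplyr::slice_max(passing, .data$span, n = 1, with_ties = FALSE)
}

#' Anchor a candidate hit at the mapped TSS and extend to the full window
#'
#' Maps the query TSS through the hit's block structure to a target
#' coordinate, verifies the YR initiator consensus at the mapped dinucleotide
#' and extends to the fixed-length window (601 nt by default, TSS centred),
#' slicing the unmasked layer. Failures are returned as values, not errors:
#' `"unmapped"` (TSS falls in an unaligned block), `"no-YR"` (mapped
#' dinucleotide fails the consensus), `"gap"` (window overruns the contig or
#' contains `N`).
#'
#' @param hit One-row PSL hit tibble (with list-columns `block_sizes`,
#'   `q_starts`, `t_starts`).
#' @param genome Target `genome_source`.
#' @param query_tss_offset 0-based index of the TSS base within the query
#'   promoter window (default 300).
#' @param upstream,downstream Flanks of the extended window.
#' @param species Species tag for the returned window.
#' @return List with `status` (`"ok"`, `"unmapped"`, `"no-YR"`, `"gap"`) and,
#'   when ok, `window` (one-row promoter-window tibble).
#' @export
anchor_and_extend <- function(hit, genome, query_tss_offset = 300L,
                              upstream = 300L, downstream = 300L,
                              species = "macaque") {
  stopifnot(nrow(hit) == 1)
  sizes <- hit$block_sizes[[1]]
  q_starts <- hit$q_starts[[1]]
  t_starts <- hit$t_starts[[1]]
  q <- query_tss_offset
  if (hit$strand == "-") q <- hit$q_size - 1L - q
  k <- which(q >= q_starts & q < q_starts + sizes)
  if (length(k) == 0) return(list(status = "unmapped", window = NULL))
  t_pos <- t_starts[k[1]] + (q - q_starts[k[1]])
  tssr <- tibble(chrom = hit$t_name, pos = t_pos, strand = hit$strand,
                 gene = hit$q_name)
  dinuc <- tryCatch(
    extract_window(genome, tssr$chrom, tssr$pos, tssr$strand,
                   upstream = 1L, downstream = 0L, layer = "unmasked"),
    error = function(e) NULL
  )
  if (is.null(dinuc)) return(list(status = "gap", window = NULL))
  if (!check_yr(dinuc, 1L)) return(list(status = "no-YR", window = NULL))
  win <- tryCatch(
    extract_window(genome, tssr$chrom, tssr$pos, tssr$strand,
                   upstream = upstream, downstream = downstream,
                   layer = "unmasked"),
    error = function(e) NULL
  )
  if (is.null(win) || grepl("N", win, fixed = TRUE)) {
    return(list(status = "gap", window = NULL))
  }
  list(status = "ok", window = tibble(
    species = species, gene = tssr$gene, chrom = tssr$chrom, pos = tssr$pos,
    strand = tssr$strand, upstream = as.integer(upstream),
    downstream = as.integer(downstream), seq = win
  ))
}
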