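#' Extract TSS-anchored promoter windows
#'
#' For each TSS, excises a window of `upstream` bases before and `downstream`
#' bases after the +1 base, in transcript orientation: index `upstream`
#' (0-based) of the returned sequence is the TSS base, and smaller indices are
#' biologically upstream. On the minus strand this is the reverse complement
#' of the plus-strand genomic slice. Windows that would run off a chromosome
#' end are dropped (and counted in the `dropped` attribute) rather than
#' padded.
#'
#' @param tss Tibble of TSS records (`chrom`, `pos`, `strand`, `gene`, and
#'   optionally `clones`), as returned by [read_tss_table()].
#' @param genome A `genome_source`.
#' @param upstream,downstream Flank lengths; the default 300/300 yields the
#'   601-nt promoter window with the TSS at the centre.
#' @param layer Genome layer to slice (`"unmasked"` or `"masked"`).
#' @param species Species tag recorded with each window.
#' @return Tibble of promoter windows: `species`, `gene`, `chrom`, `pos`,
#'   `strand`, `upstream`, `downstream`, `seq`. Attribute `dropped` holds the
#'   number of out-of-bounds TSSs.
#' @export
extract_windows <- function(tss, genome, upstream = 300L, downstream = 300L,
                            layer = c("unmasked", "masked"), species = "human") {
  layer <- match.arg(layer)
  stopifnot(upstream >= 0, downstream >= 0)
  n <- nrow(tss)
  seqs <- character(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    w <- tryCatch(
      extract_window(genome, tss$chrom[i], tss$pos[i], tss$strand[i],
                     upstream, downstream, layer),
      error = function(e) NULL
    )
    if (!is.null(w)) { seqs[i] <- w; ok[i] <- TRUE }
  }
  out <- tibble(
    species = species, gene = tss$gene, chrom = tss$chrom, pos = tss$pos,
    strand = tss$strand, upstream = as.integer(upstream),
    downstream = as.integer(downstream), seq = seqs
  )[ok, ]
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Extract a single promoter window
#'
#' Low-level single-TSS form of [extract_windows()]; errors if the window
#' exceeds the chromosome bounds.
#'
#' @inheritParams extract_windows
#' @param chrom,pos,strand TSS coordinates (0-based position of the +1 base).
#' @return Sequence string of length `upstream + 1 + downstream`, transcript
#'   oriented.
#' @export
extract_window <- function(genome, chrom, pos, strand, upstream = 300L,
                           downstream = 300L, layer = "unmasked") {
  if (strand == "+") {
    genome_slice(genome, chrom, pos - upstream, pos + downstream + 1L,
                 strand = "+", layer = layer)
  } else {
    genome_slice(genome, chrom, pos - downstream, pos + upstream + 1L,
                 strand = "-", layer = layer)
  }
}

#' Check the YR initiator consensus at the TSS
#'
#' The minimal initiator signature is a pyrimidine (C or T) at position -1 and
#' a purine (A or G) at position 0 (the TSS base). `N` at either position
#' fails the check.
#'
#' @param seq Character vector of transcript-oriented window sequences.
#' @param tss_index 0-based index of the TSS base within each sequence
#'   (equal to the window's upstream length). Recycled as needed.
#' @return Logical vector.
#' @export
#' @examples
#' check_yr("TTCATT", 3)  # C at -1, A at 0 -> TRUE
check_yr <- function(seq, tss_index) {
  stopifnot(all(tss_index >= 1))
  y <- substr0(seq, tss_index - 1L, tss_index)
  r <- substr0(seq, tss_index, tss_index + 1L)
  y %in% c("C", "T") & r %in% c("A", "G")
}

#' Transcript-oriented offsets between RefSeq 5' ends and database TSSs
#'
#' For each gene, the RefSeq variant whose 5' end is nearest the database TSS
#' is selected, and the offset `refseq_pos - tss_pos` is reported with the
#' sign flipped on the minus strand, so that negative always means the RefSeq
#' 5' end lies upstream of the TSS in transcript orientation.
#'
#' @param refseq Tibble of RefSeq 5' ends: `gene`, `pos` (0-based genomic),
#'   one row per transcript variant.
#' @param tss Tibble of TSS records: `gene`, `pos`, `strand` (one row per
#'   gene).
#' @return Tibble `gene`, `strand`, `offset`, one row per gene present in
#'   both inputs. Attribute `skipped` counts genes present in only one input.
#' @export
refseq_dbtss_offsets <- function(refseq, tss) {
  stopifnot(all(c("gene", "pos") %in% names(refseq)),
            all(c("gene", "pos", "strand") %in% names(tss)))
  shared <- intersect(unique(refseq$gene), unique(tss$gene))
  skipped <- length(setdiff(unique(refseq$gene), shared)) +
    length(setdiff(unique(tss$gene), shared))
  joined <- dplyr::inner_join(
    dplyr::select(refseq, "gene", refseq_pos = "pos"),
    dplyr::select(tss, "gene", tss_pos = "pos", "strand"),
    by = "gene", relationship = "many-to-many"
  )
  out <- joined |>
    dplyr::mutate(raw = .data$refseq_pos - .data$tss_pos) |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_min(abs(.data$raw), n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(offset = ifelse(.data$strand == "-", -.data$raw, .data$raw)) |>
    dplyr::select("gene", "strand", "offset")
  attr(out, "skipped") <- skipped
  out
}

#' Slice a logo window out of wider promoter windows
#'
#' Re-anchors windows to a shorter flank, e.g. the 40-nt logo window
#' (34 upstream, 5 downstream) from the 601-nt promoter window.
#'
#' @param windows Promoter-window tibble from [extract_windows()] (or any
#'   tibble with `seq` and `upstream` columns).
#' @param upstream,downstream New flank lengths (must not exceed the old).
#' @return The tibble with `seq`, `upstream`, `downstream` replaced.
#' @export
slice_windows <- function(windows, upstream = 34L, downstream = 5L) {
  old_up <- windows$upstream
  stopifnot(all(old_up >= upstream))
  start <- old_up - upstream
  end <- old_up + downstream + 1L
  if (any(end > nchar(windows$seq))) abort("downstream flank exceeds window")
  windows$seq <- substr(windows$seq, start + 1L, end)
  windows$upstream <- as.integer(upstream)
  windows$downstream <- as.integer(downstream)
  windows
}
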