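#' Harr plot (dot plot) of two sequences
#'
#' Slides a window of `window` bp with a stride of `stride` bp along both
#' sequences and records a dot at (i, j) — 0-based window start coordinates —
#' wherever the two windows match exactly. In `reverse` orientation the
#' window of `a` is compared against the reverse complement of the window of
#' `b` (j remains the forward-strand start in `b`). Windows containing `N`
#' never match.
#'
#' @param a,b Sequences (uppercase); both at least `window` long.
#' @param window Window size in bp (default 5; one dot = one perfect
#'   `window`-bp match).
#' @param stride Step between window starts (default 1).
#' @param orientation `"direct"` or `"reverse"` (reverse complement).
#' @return A `harr_plot`: tibble of dots `i`, `j` with attributes `window`,
#'   `stride`, `orientation`, `len_a`, `len_b`.
#' @export
#' @examples
#' harr_plot("ACGTACGTAC", "ACGTACGTAC")
harr_plot <- function(a, b, window = 5L, stride = 1L,
                      orientation = c("direct", "reverse")) {
  orientation <- match.arg(orientation)
  assert_seq(a); assert_seq(b)
  if (nchar(a) < window || nchar(b) < window) {
    abort("sequences must be at least `window` long")
  }
  starts_a <- seq.int(1L, nchar(a) - window + 1L, by = stride)
  starts_b <- seq.int(1L, nchar(b) - window + 1L, by = stride)
  wa <- substring(a, starts_a, starts_a + window - 1L)
  wb <- substring(b, starts_b, starts_b + window - 1L)
  if (orientation == "reverse") wb <- revcomp(wb)
  ok_a <- !grepl("N", wa, fixed = TRUE)
  ok_b <- !grepl("N", wb, fixed = TRUE)
  hits <- outer(wa, wb, "==") & outer(ok_a, ok_b, "&")
  idx <- which(hits, arr.ind = TRUE)
  out <- tibble(i = starts_a[idx[, 1]] - 1L, j = starts_b[idx[, 2]] - 1L) |>
    dplyr::arrange(.data$i, .data$j)
  structure(out, window = as.integer(window), stride = as.integer(stride),
            orientation = orientation, len_a = nchar(a), len_b = nchar(b),
            class = c("harr_plot", class(out)))
}

#' @method tidy harr_plot
#' @export
tidy.harr_plot <- function(x, ...) {
  tibble(i = x$i, j = x$j, orientation = attr(x, "orientation"))
}

#' Dot-plot rendering of a Harr plot
#'
#' @param object A `harr_plot`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot harr_plot
#' @export
autoplot.harr_plot <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_fixed(
      xlim = c(0, attr(object, "len_a")), ylim = c(0, attr(object, "len_b"))
    ) +
    ggplot2::labs(
      x = "sequence A (window start)", y = "sequence B (window start)",
      title = sprintf("%d-bp windows, %s orientation",
                      attr(object, "window"), attr(object, "orientation"))
    ) +
    ggplot2::theme_minimal()
}

#' Tandem / inverted repeat association of an indel site
#'
#' Operationalises visual Harr-plot inspection: the carrier-row sequence
#' spanning the indel plus `neighborhood` bp on each side is self-compared;
#' the site is *tandem-repeat associated* if the direct self-plot contains an
#' off-diagonal dot whose window (on either axis) overlaps the indel
#' interval, and *inverted-repeat associated* if the reverse-complement
#' self-plot does (self-hits at i = j are ignored in both orientations).
#'
#' @param site One row of a [detect_indels()] tibble.
#' @param row_a,row_b The gapped alignment rows the site was detected in.
#' @param neighborhood Flank, in bp of the carrier sequence, around the indel
#'   (default 25).
#' @param window Dot-plot window size (default 5). Sites shorter than
#'   `window` are not assessable.
#' @return Tibble with logical columns `tandem` and `inverted`.
#' @export
repeat_association <- function(site, row_a, row_b, neighborhood = 25L,
                               window = 5L) {
  stopifnot(site$length >= window)
  carrier_row <- if (site$carrier == "a") row_a else row_b
  carrier_seq <- gsub("-", "", carrier_row, fixed = TRUE)
  pos <- site$pos_carrier
  len <- site$length
  region_start <- max(0L, pos - neighborhood)
  region_end <- min(nchar(carrier_seq), pos + len + neighborhood)
  region <- substr0(carrier_seq, region_start, region_end)
  indel_lo <- pos - region_start          # 0-based, within region
  indel_hi <- indel_lo + len              # half-open
  assoc <- function(orientation) {
    dots <- harr_plot(region, region, window = window,
                      orientation = orientation)
    if (nrow(dots) == 0) return(FALSE)
    off <- dots$i != dots$j
    overlaps <- function(start) start < indel_hi & start + window > indel_lo
    any(off & (overlaps(dots$i) | overlaps(dots$j)))
  }
  tibble(tandem = assoc("direct"), inverted = assoc("reverse"))
}

#' Repeat association across a cohort of indel sites
#'
#' @param sites Indel-site tibble with a `pair` column
#'   ([detect_indels_cohort()]).
#' @param aligned The aligned-pairs tibble the sites came from.
#' @param neighborhood,window See [repeat_association()].
#' @return `sites` restricted to assessable rows (`length >= window`), with
#'   `tandem` and `inverted` columns added.
#' @export
repeat_association_cohort <- function(sites, aligned, neighborhood = 25L,
                                      window = 5L) {
  sites <- dplyr::filter(sites, .data$length >= window)
  if (nrow(sites) == 0) {
    return(dplyr::mutate(sites, tandem = logical(0), inverted = logical(0)))
  }
  ids <- aligned[["pair"]] %||% seq_len(nrow(aligned))
  purrr::map_dfr(seq_len(nrow(sites)), function(k) {
    i <- match(sites$pair[k], ids)
    dplyr::bind_cols(
      sites[k, ],
      repeat_association(sites[k, ], aligned$row_a[i], aligned$row_b[i],
                         neighborhood = neighborhood, window = window)
    )
  })
}
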