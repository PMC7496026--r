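#' Position frequency and information matrix for logo windows
#'
#' Per-position A/C/G/T frequencies over a set of equal-length,
#' equally-anchored windows, with per-position information content
#' `2 - H` bits (Shannon entropy, log base 2), computed from raw frequencies
#' without small-sample correction. `N` observations are excluded per
#' position; positions with zero non-N observations get NA frequencies and
#' are flagged.
#'
#' @param windows Promoter-window tibble (columns `seq`, `upstream`,
#'   `downstream`) or a character vector of equal-length sequences.
#' @param upstream TSS offset when `windows` is a character vector.
#' @return A `logo_matrix`: list with `freq` (4 x L matrix), `info` (length-L
#'   numeric, bits), `positions` (TSS-relative labels, -upstream .. +down),
#'   `n_obs` (non-N observations per position).
#' @export
position_frequency_matrix <- function(windows, upstream = NULL) {
  if (is.data.frame(windows)) {
    seqs <- windows$seq
    upstream <- unique(windows$upstream)
    if (length(upstream) != 1) abort("windows have mixed TSS offsets")
  } else {
    seqs <- windows
    if (is.null(upstream)) abort("`upstream` required for a character vector")
  }
  if (length(seqs) == 0) abort("no windows supplied")
  L <- unique(nchar(seqs))
  if (length(L) != 1) abort("windows have mixed lengths")
  mat <- do.call(rbind, seq_chars(seqs))
  freq <- matrix(NA_real_, 4, L, dimnames = list(DNA_BASES4, NULL))
  n_obs <- integer(L)
  for (p in seq_len(L)) {
    col <- mat[, p]
    col <- col[col %in% DNA_BASES4]
    n_obs[p] <- length(col)
    if (n_obs[p] > 0) {
      freq[, p] <- as.integer(table(factor(col, levels = DNA_BASES4))) / n_obs[p]
    }
  }
  info <- apply(freq, 2, function(f) {
    if (anyNA(f)) return(NA_real_)
    nz <- f[f > 0]
    2 + sum(nz * log2(nz))
  })
  structure(
    list(freq = freq, info = info,
         positions = seq_len(L) - 1L - upstream, n_obs = n_obs),
    class = "logo_matrix"
  )
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("<logo_matrix>", ncol(x$freq), "positions,",
      sprintf("%.2f", max(x$info, na.rm = TRUE)), "bits max information\n")
  invisible(x)
}

#' Long tidy view of a logo matrix
#'
#' @param x A `logo_matrix`.
#' @param ... Unused.
#' @return Tibble `position`, `base`, `freq`, `info`, `n_obs`.
#' @method tidy logo_matrix
#' @export
tidy.logo_matrix <- function(x, ...) {
  L <- ncol(x$freq)
  tibble(
    position = rep(x$positions, each = 4L),
    base = rep(DNA_BASES4, L),
    freq = as.vector(x$freq),
    info = rep(x$info, each = 4L),
    n_obs = rep(x$n_obs, each = 4L)
  )
}

#' Information-scaled logo bar plot
#'
#' Stacked bars per position: total bar height is the information content in
#' bits; segments are the base frequencies scaled by it (a text-free sequence
#' logo).
#'
#' @param object A `logo_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot logo_matrix
#' @export
autoplot.logo_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$freq * .data$info,
                                   fill = .data$base)) +
    ggplot2::geom_col(position = "stack", width = 0.8) +
    ggplot2::labs(x = "position relative to TSS", y = "information (bits)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Positional scan for the TATA-box consensus TATAAA
#'
#' Counts 5'-end positions of every exact `TATAAA` occurrence lying wholly
#' within the `scan_width` bases upstream of the TSS (positions
#' `-scan_width` .. `-1`; the last admissible 5' end is `-6`). Overlapping
#' occurrences are all counted.
#'
#' @param windows Promoter-window tibble (columns `seq`, `upstream`) or a
#'   character vector with `upstream` given.
#' @param upstream TSS offset when `windows` is a character vector.
#' @param scan_width Upstream scan width in bp (default 40).
#' @return Tibble `position` (TSS-relative 5' end), `count`, sorted by
#'   position; positions with zero hits are absent.
#' @export
tataaa_scan <- function(windows, upstream = NULL, scan_width = 40L) {
  if (is.data.frame(windows)) {
    seqs <- windows$seq
    up <- windows$upstream
  } else {
    if (is.null(upstream)) abort("`upstream` required for a character vector")
    seqs <- windows
    up <- rep_len(upstream, length(seqs))
  }
  if (any(up < scan_width)) abort("windows have fewer upstream bases than `scan_width`")
  region <- substr(seqs, up - scan_width + 1L, up)
  hits <- gregexpr("(?=TATAAA)", region, perl = TRUE)
  pos <- unlist(purrr::map(hits, function(h) {
    h <- as.integer(h)
    h <- h[h > 0]
    h[h <= scan_width - 5L]
  }))
  pos <- pos - 1L - scan_width  # 1-based region index -> TSS-relative 5' end
  if (length(pos) == 0) {
    return(tibble(position = integer(0), count = integer(0)))
  }
  tb <- table(pos)
  tibble(position = as.integer(names(tb)), count = as.integer(tb)) |>
    dplyr::arrange(.data$position)
}
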