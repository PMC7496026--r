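# Independent oracles and small fixture builders used across the suite.

# Exhaustive optimal global alignment score under affine gaps: enumerates
# every gapped alignment recursively (no dynamic programming), scoring a gap
# of length L as open + ext * L. Only feasible for short sequences.
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    open = 10, ext = 0.2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  pair_score <- function(x, y) {
    if (x == y && x %in% c("A", "C", "G", "T")) match else mismatch
  }
  rec <- function(i, j, state) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, pair_score(ca[i], cb[j]) + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(ca)) {  # gap in b (consume a)
      cost <- ext + if (state == "gb") 0 else open
      best <- max(best, -cost + rec(i + 1, j, "gb"))
    }
    if (j <= length(cb)) {  # gap in a (consume b)
      cost <- ext + if (state == "ga") 0 else open
      best <- max(best, -cost + rec(i, j + 1, "ga"))
    }
    best
  }
  rec(1, 1, "start")
}

# All-pairs exact window comparison; returns a sorted data.frame of 0-based
# dots, mirroring harr_plot()'s contract but computed by direct loops.
brute_force_harr <- function(a, b, window = 5, stride = 1,
                             orientation = "direct") {
  rc <- function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  ii <- c(); jj <- c()
  for (i in seq(1, nchar(a) - window + 1, by = stride)) {
    wa <- substr(a, i, i + window - 1)
    if (grepl("N", wa, fixed = TRUE)) next
    for (j in seq(1, nchar(b) - window + 1, by = stride)) {
      wb <- substr(b, j, j + window - 1)
      if (grepl("N", wb, fixed = TRUE)) next
      if (orientation == "reverse") wb <- rc(wb)
      if (wa == wb) { ii <- c(ii, i - 1); jj <- c(jj, j - 1) }
    }
  }
  df <- data.frame(i = as.integer(ii %||% integer(0)),
                   j = as.integer(jj %||% integer(0)))
  df[order(df$i, df$j), , drop = FALSE]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

random_dna <- function(n, prob = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Build a gapped alignment object directly from rows (bypasses the aligner).
make_alignment <- function(row_a, row_b) {
  promdiverge:::new_pairwise_alignment(row_a, row_b)
}
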