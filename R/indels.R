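#' Detect indel sites in a pairwise alignment
#'
#' One site per maximal gap run. The *carrier* is the row holding bases over
#' the run (`"a"` or `"b"`); the other species lacks the fragment. Flank
#' conservation is counted over the `flank_width` alignment columns on each
#' side of the run: a flank column counts as a match only if both rows carry
#' the same A/C/G/T base (gaps and `N` count as mismatches). Runs touching an
#' alignment edge have their flank counted over the available columns only
#' and are flagged `truncated`.
#'
#' @param row_a,row_b Gapped alignment rows, or a `pairwise_alignment` as
#'   `row_a`.
#' @param flank_width Flank width in alignment columns (default 10).
#' @return Tibble with one row per gap run: `col_start`, `col_end` (0-based,
#'   half-open column interval), `carrier`, `seq`, `length`, `pos_carrier`
#'   (0-based position of the fragment in the carrier's ungapped sequence),
#'   `pos_other` (0-based position of the gap in the other species' ungapped
#'   sequence), `flank_left`, `flank_right`, `truncated`, `cpg_delta` (see
#'   [cpg_delta()]).
#' @export
detect_indels <- function(row_a, row_b = NULL, flank_width = 10L) {
  if (inherits(row_a, "pairwise_alignment")) {
    row_b <- row_a$row_b
    row_a <- row_a$row_a
  }
  stopifnot(nchar(row_a) == nchar(row_b))
  a <- seq_chars(row_a)[[1]]
  b <- seq_chars(row_b)[[1]]
  if (any(a == "-" & b == "-")) abort("alignment has a column gapped in both rows")
  runs_for <- function(gapped, carrier_chars, carrier_label) {
    r <- rle(gapped == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    purrr::map(keep, function(k) {
      s <- starts[k]; e <- ends[k]
      list(start = s, end = e, carrier = carrier_label)
    })
  }
  sites <- c(runs_for(a, b, "b"), runs_for(b, a, "a"))
  if (length(sites) == 0) {
    return(tibble(col_start = integer(0), col_end = integer(0),
                  carrier = character(0), seq = character(0),
                  length = integer(0), pos_carrier = integer(0),
                  pos_other = integer(0), flank_left = integer(0),
                  flank_right = integer(0), truncated = logical(0),
                  cpg_delta = integer(0)))
  }
  sites <- sites[order(vapply(sites, `[[`, integer(1), "start"))]
  L <- length(a)
  flank_matches <- function(cols) {
    sum(a[cols] == b[cols] & a[cols] %in% DNA_BASES4)
  }
  rows <- purrr::map(sites, function(st) {
    s <- st$start; e <- st$end
    carrier_chars <- if (st$carrier == "a") a else b
    other_chars <- if (st$carrier == "a") b else a
    left_cols <- seq.int(max(1L, s - flank_width), s - 1L)
    if (s == 1L) left_cols <- integer(0)
    right_cols <- if (e == L) integer(0) else seq.int(e + 1L, min(L, e + flank_width))
    tibble(
      col_start = s - 1L,
      col_end = e,
      carrier = st$carrier,
      seq = paste(carrier_chars[s:e], collapse = ""),
      length = e - s + 1L,
      pos_carrier = sum(carrier_chars[seq_len(s - 1L)] != "-"),
      pos_other = sum(other_chars[seq_len(s - 1L)] != "-"),
      flank_left = flank_matches(left_cols),
      flank_right = flank_matches(right_cols),
      truncated = length(left_cols) < flank_width ||
        length(right_cols) < flank_width,
      cpg_delta = cpg_delta_cols(a, b, s, e, st$carrier)
    )
  })
  dplyr::bind_rows(rows)
}

#' Detect indels across a cohort of aligned pairs
#'
#' @param aligned Tibble from [align_pairs()] with `row_a`, `row_b`; a `pair`
#'   id column is carried through if present.
#' @param flank_width Flank width in alignment columns.
#' @return Tibble of indel sites ([detect_indels()] columns) with a `pair`
#'   column.
#' @export
detect_indels_cohort <- function(aligned, flank_width = 10L) {
  ids <- aligned[["pair"]] %||% seq_len(nrow(aligned))
  out <- purrr::map(seq_len(nrow(aligned)), function(i) {
    s <- detect_indels(aligned$row_a[i], aligned$row_b[i], flank_width)
    dplyr::mutate(s, pair = rep(ids[i], nrow(s)), .before = 1)
  })
  empty <- dplyr::mutate(detect_indels("A", "A"), pair = integer(0),
                         .before = 1)
  dplyr::bind_rows(c(list(empty), out))
}

#' Flank-conservation filter for indel sites
#'
#' Keeps sites whose two flanks both show at least `min_match` matching
#' columns (default 8 of 10) and are not edge-truncated.
#'
#' @param sites Indel-site tibble from [detect_indels()].
#' @param min_match Minimum matches per flank.
#' @return The sites tibble with a logical `keep` column added.
#' @export
flank_filter <- function(sites, min_match = 8L) {
  dplyr::mutate(sites, keep = .data$flank_left >= min_match &
                  .data$flank_right >= min_match & !.data$truncated)
}

#' CpG-count change attributable to an indel
#'
#' Counts CpG dinucleotides over the gap-run columns extended by one flanking
#' column on each side — so junction-spanning CpGs are included — in the
#' carrier row and in the other row (both ungapped over that region), and
#' returns carrier minus other.
#'
#' @param site One row of a [detect_indels()] tibble.
#' @param row_a,row_b The gapped alignment rows the site was detected in.
#' @return Signed integer.
#' @export
cpg_delta <- function(site, row_a, row_b) {
  a <- seq_chars(row_a)[[1]]
  b <- seq_chars(row_b)[[1]]
  cpg_delta_cols(a, b, site$col_start + 1L, site$col_end, site$carrier)
}

cpg_delta_cols <- function(a, b, s, e, carrier) {
  cols <- seq.int(max(1L, s - 1L), min(length(a), e + 1L))
  count_cpg <- function(chars) {
    x <- chars[chars != "-"]
    if (length(x) < 2L) return(0L)
    sum(x[-length(x)] == "C" & x[-1] == "G")
  }
  carrier_chars <- if (carrier == "a") a else b
  other_chars <- if (carrier == "a") b else a
  count_cpg(carrier_chars[cols]) - count_cpg(other_chars[cols])
}

#' Indel length histogram
#'
#' Bins indel lengths into the classes 1, 2-4, 5-9, 10-19 and 20+ (by
#' default).
#'
#' @param sites Indel-site tibble (rows already filtered as desired).
#' @param breaks Left edges of the length classes.
#' @return Tibble `class`, `count`; counts sum to `nrow(sites)`.
#' @export
indel_length_histogram <- function(sites, breaks = c(1, 2, 5, 10, 20)) {
  labels <- paste0(breaks, c(ifelse(diff(breaks) > 1,
                                    paste0("-", breaks[-1] - 1), ""), "+"))
  labels[diff(c(breaks, Inf)) == 1] <- as.character(breaks[diff(c(breaks, Inf)) == 1])
  cls <- cut(sites$length, breaks = c(breaks, Inf), labels = labels,
             right = FALSE)
  out <- as_tibble(table(class = cls))
  names(out) <- c("class", "count")
  out$count <- as.integer(out$count)
  out
}

#' Single-nucleotide indel base bias per pair group
#'
#' For length-1 indel sites, tabulates the inserted/deleted base by pair
#' group; fractions sum to 1 within every group that has sites.
#'
#' @param sites Indel-site tibble with a `group` column (e.g. the pair group
#'   `hCmC` ... `hNmN`).
#' @return Tibble `group`, `base`, `count`, `fraction`. Groups with no
#'   single-nucleotide sites are absent.
#' @export
single_nt_bias <- function(sites) {
  stopifnot("group" %in% names(sites))
  single <- dplyr::filter(sites, .data$length == 1L,
                          .data$seq %in% DNA_BASES4)
  if (nrow(single) == 0) {
    return(tibble(group = character(0), base = character(0),
                  count = integer(0), fraction = numeric(0)))
  }
  single |>
    dplyr::count(group = as.character(.data$group),
                 base = factor(.data$seq, levels = DNA_BASES4),
                 .drop = FALSE, name = "count") |>
    dplyr::group_by(.data$group) |>
    dplyr::filter(sum(.data$count) > 0) |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}

#' Left-normalise an indel placement
#'
#' Gap placement inside a repeat is alignment-degenerate: inserting (or
#' deleting) `seq` at position `pos` of `context` can be equivalent to doing
#' so further left. This shifts the event to its leftmost equivalent
#' placement (VCF-style), rotating the indel sequence as it moves, so that
#' equivalent events compare equal.
#'
#' @param context The sequence the position refers to: the carrier sequence
#'   *with* the fragment for both insertions and deletions (i.e. the
#'   fragment occupies `[pos, pos + nchar(seq))` of `context`).
#' @param pos 0-based fragment position.
#' @param seq Fragment sequence.
#' @return List with normalised `pos` and `seq`.
#' @export
left_normalize_indel <- function(context, pos, seq) {
  L <- nchar(seq)
  while (pos > 0) {
    prev <- substr0(context, pos - 1L, pos)
    last <- substr0(seq, L - 1L, L)
    if (prev != last) break
    seq <- paste0(prev, substr0(seq, 0L, L - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, seq = seq)
}

#' The fixed primate species tree
#'
#' Rooted topology over human, chimpanzee, gorilla, macaque, baboon and
#' marmoset used to polarise indel events.
#'
#' @return An `ape::phylo` object.
#' @export
primate_tree <- function() {
  ape::read.tree(
    text = "((((human,chimpanzee),gorilla),(macaque,baboon)),marmoset);"
  )
}

#' Polarise an indel from per-species fragment presence
#'
#' Single-event parsimony on a fixed rooted species tree: the event is
#' assignable iff exactly one branch exists whose descendant clade carries
#' the minority state — an *insertion* on that branch if the clade has the
#' fragment and all other species lack it, a *deletion* if the clade lacks
#' it. Patterns requiring two or more events, or fitting more than one
#' single-event placement, are `ambiguous`; a uniform pattern is `none`.
#' Species with `NA` presence are unconstrained.
#'
#' @param presence Named logical vector: fragment presence per species
#'   (names must be tree tip labels; at least 3 non-NA).
#' @param tree Rooted `phylo` tree (default [primate_tree()]).
#' @return Tibble with `event` (`insertion`, `deletion`, `none`,
#'   `ambiguous`) and `branch` (comma-joined clade tips, NA unless
#'   assignable).
#' @export
polarize_indel <- function(presence, tree = primate_tree()) {
  stopifnot(is.logical(presence), !is.null(names(presence)))
  stopifnot(all(names(presence) %in% tree$tip.label))
  if (sum(!is.na(presence)) < 3) abort("presence known for < 3 species")
  known <- presence[!is.na(presence)]
  tips <- tree$tip.label
  # clades = descendant tip sets of every branch (excluding the root set)
  n_tip <- length(tips)
  clades <- purrr::map(seq_len(n_tip + tree$Nnode), function(node) {
    if (node == n_tip + 1L) return(NULL)  # root
    tips[phangorn_free_descendants(tree, node)]
  })
  clades <- purrr::compact(clades)
  fits <- purrr::map_dfr(clades, function(cl) {
    inside <- names(known) %in% cl
    dplyr::bind_rows(
      tibble(event = "insertion", ok = all(known[inside]) && !any(known[!inside]),
             branch = paste(cl, collapse = ",")),
      tibble(event = "deletion", ok = !any(known[inside]) && all(known[!inside]),
             branch = paste(cl, collapse = ","))
    )
  })
  fits <- dplyr::filter(fits, .data$ok,
                        vapply(strsplit(.data$branch, ","), function(cl)
                          any(names(known) %in% cl), logical(1)),
                        TRUE)
  if (all(known) || !any(known)) {
    return(tibble(event = "none", branch = NA_character_))
  }
  if (nrow(fits) == 1) {
    return(tibble(event = fits$event, branch = fits$branch))
  }
  tibble(event = "ambiguous", branch = NA_character_)
}

# Descendant tips of a node in an ape phylo tree, without loading phangorn.
phangorn_free_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, phangorn_free_descendants, tree = tree))
}
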