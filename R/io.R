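#' Read a (soft-masked) FASTA file into a two-layer genome source
#'
#' Lowercase letters are treated as soft-masked repeat bases. Two layers are
#' kept: `unmasked` (everything uppercased) and `masked` (soft-masked bases
#' hardened to `N`). Letters outside A/C/G/T/N are preserved as `N` in both
#' layers.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_source` object: list with character vectors `unmasked`
#'   and `masked`, named by chromosome id (first whitespace-delimited token of
#'   each header).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (!is.na(first) && !startsWith(lines[first], ">")) {
    abort(sprintf("malformed FASTA: line %d does not start a record", first))
  }
  seqs <- Biostrings::readBStringSet(path)
  raw <- as.character(seqs)
  names(raw) <- sub("\\s.*$", "", names(seqs))
  masked <- toupper(gsub("[a-z]", "N", raw))
  masked <- gsub("[^ACGTN]", "N", masked)
  unmasked <- gsub("[^ACGTN]", "N", toupper(raw))
  structure(list(unmasked = unmasked, masked = masked), class = "genome_source")
}

#' @export
print.genome_source <- function(x, ...) {
  cat("<genome_source>", length(x$unmasked), "chromosome(s):\n")
  for (nm in names(x$unmasked)) {
    cat(sprintf("  %s  %d bp\n", nm, nchar(x$unmasked[[nm]])))
  }
  invisible(x)
}

#' Build a genome source from in-memory sequences
#'
#' Convenience constructor used by the simulator and tests. Lowercase letters
#' are treated as soft-masked, as in [read_fasta()].
#'
#' @param seqs Named character vector of chromosome sequences.
#' @return A `genome_source` object.
#' @export
genome_source <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  masked <- toupper(gsub("[a-z]", "N", seqs))
  masked <- gsub("[^ACGTN]", "N", masked)
  unmasked <- gsub("[^ACGTN]", "N", toupper(seqs))
  structure(list(unmasked = unmasked, masked = masked), class = "genome_source")
}

#' Slice a genome source
#'
#' Coordinates are 0-based, half-open. Minus-strand requests return the
#' reverse complement of the plus-strand slice.
#'
#' @param genome A `genome_source`.
#' @param chrom Chromosome id.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @param layer `"unmasked"` (default) or `"masked"`.
#' @return A single sequence string of length `end - start`.
#' @export
genome_slice <- function(genome, chrom, start, end, strand = "+",
                         layer = c("unmasked", "masked")) {
  layer <- match.arg(layer)
  stopifnot(inherits(genome, "genome_source"), strand %in% c("+", "-"))
  seq <- unname(genome[[layer]][chrom])
  if (is.na(seq)) abort(sprintf("chromosome '%s' not in genome", chrom))
  if (start < 0 || end > nchar(seq) || end < start) {
    abort(sprintf("slice [%d,%d) out of bounds for %s (%d bp)",
                  start, end, chrom, nchar(seq)))
  }
  out <- substr0(seq, start, end)
  if (strand == "-") out <- revcomp(out)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    if (nchar(s) == 0L) next
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a TSS table
#'
#' Tab-separated columns: chromosome, position (0-based index of the +1
#' base), strand, gene id, clone count. Sites supported by fewer than
#' `min_clones` clones are removed (row order otherwise preserved).
#'
#' @param path Path to the TSV file (no header).
#' @param min_clones Minimum clone support; default 3.
#' @return Tibble with columns `chrom`, `pos`, `strand`, `gene`, `clones`.
#' @export
read_tss_table <- function(path, min_clones = 3L) {
  tb <- suppressWarnings(readr::read_tsv(
    path,
    col_names = c("chrom", "pos", "strand", "gene", "clones"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      strand = readr::col_character(),
      gene = readr::col_character(),
      clones = readr::col_integer()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(tb)
  if (nrow(probs) > 0) {
    abort(sprintf("TSS table parse error at line %d: expected %s",
                  probs$row[1], probs$expected[1]))
  }
  if (nrow(tb) > 0 && !all(tb$strand %in% c("+", "-"))) {
    abort("TSS table strand column must be '+' or '-'")
  }
  dplyr::filter(tb, .data$clones >= min_clones)
}

PSL_COLS <- c("matches", "mismatches", "rep_matches", "n_count",
              "q_num_insert", "q_base_insert", "t_num_insert", "t_base_insert",
              "strand", "q_name", "q_size", "q_start", "q_end",
              "t_name", "t_size", "t_start", "t_end",
              "block_count", "block_sizes", "q_starts", "t_starts")

#' Read BLAT hits in PSL format
#'
#' Accepts PSL with or without the 5-line `psLayout` header. Percent identity
#' is computed as `matches / (t_end - t_start)` (matches over target span).
#'
#' @param path Path to a PSL file.
#' @return Tibble with one row per hit; comma lists (`block_sizes`,
#'   `q_starts`, `t_starts`) are parsed into integer list-columns, and
#'   `span`/`identity` are added.
#' @export
read_psl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) > 0 && startsWith(lines[1], "psLayout")) {
    lines <- lines[-seq_len(5L)]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(!!!setNames(rep(list(integer(0)), length(PSL_COLS)), PSL_COLS),
                  span = integer(0), identity = numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21L)) {
    abort(sprintf("PSL parse error: line %d has %d columns (expected 21)",
                  which(nf != 21L)[1], nf[nf != 21L][1]))
  }
  m <- do.call(rbind, fields)
  colnames(m) <- PSL_COLS
  int_cols <- setdiff(PSL_COLS, c("strand", "q_name", "t_name",
                                  "block_sizes", "q_starts", "t_starts"))
  tb <- as_tibble(m)
  tb <- dplyr::mutate(tb, dplyr::across(dplyr::all_of(int_cols), as.integer))
  parse_list <- function(x) lapply(strsplit(x, ",", fixed = TRUE), as.integer)
  tb$block_sizes <- parse_list(tb$block_sizes)
  tb$q_starts <- parse_list(tb$q_starts)
  tb$t_starts <- parse_list(tb$t_starts)
  tb$span <- tb$t_end - tb$t_start
  if (any(tb$span <= 0)) abort("PSL hit with non-positive target span")
  tb$identity <- tb$matches / tb$span
  tb
}

#' Read pairwise alignments in axt format
#'
#' Each axt block is a summary line followed by two gapped sequence rows and a
#' blank line. Rows are uppercased; lines starting with `#` are skipped.
#'
#' @param path Path to an axt file.
#' @return Tibble with columns `block`, `row_a`, `row_b`.
#' @export
read_axt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  keep <- nzchar(trimws(lines))
  # group contiguous non-blank runs into blocks
  runs <- rle(keep)
  idx <- split(seq_along(lines)[keep], rep(cumsum(runs$values), runs$lengths)[keep])
  rows_a <- character(0); rows_b <- character(0)
  for (blk in idx) {
    if (length(blk) != 3L) {
      abort(sprintf("axt parse error: block near line %d has %d lines (expected 3)",
                    blk[1], length(blk)))
    }
    a <- toupper(lines[blk[2]]); b <- toupper(lines[blk[3]])
    if (nchar(a) != nchar(b)) {
      abort(sprintf("axt parse error: row-length mismatch in block near line %d", blk[1]))
    }
    rows_a <- c(rows_a, a); rows_b <- c(rows_b, b)
  }
  tibble(block = seq_along(rows_a), row_a = rows_a, row_b = rows_b)
}
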