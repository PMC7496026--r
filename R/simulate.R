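#' Simulation configuration for synthetic promoter-pair cohorts
#'
#' Defaults describe the emulated comparative design: two primate-like
#' lineages diverging from a common ancestral promoter, with CpG-island
#' ancestors (G+C 0.60, CpG obs/exp 0.8) and non-island ancestors (G+C 0.42,
#' obs/exp 0.25) mixed 67:33, a per-branch substitution rate of 0.025
#' (roughly the substitution component of ~7% human-macaque divergence), a
#' 10-fold CpG-context transition multiplier (deamination of methylated
#' CpG), and indels from homopolymer slippage (mean 0.3 events/branch) and
#' tandem duplication/deletion of 5-10 nt units including CpG-containing
#' motifs such as `TCGGC` (mean 0.05 + 0.05 events/branch). Indel events keep
#' `indel_spacing` bp clear of each other, of the central YR dinucleotide and
#' of the sequence ends, so every planted event retains intact flanks and
#' stays individually identifiable.
#'
#' @param length Ancestor length (odd, so a central TSS exists; default 601).
#' @param island_fraction Fraction of pairs with an island-class ancestor.
#' @param island_gc,island_score Composition targets for island ancestors.
#' @param nonisland_gc,nonisland_score Targets for non-island ancestors.
#' @param composition_tol Accepted deviation from the targets (rejection
#'   sampling window).
#' @param sub_rate Per-site, per-branch substitution probability.
#' @param cpg_multiplier Rate factor for C->T at CpG (and G->A on the
#'   complementary-strand context).
#' @param slippage_rate,tandem_dup_rate,tandem_del_rate Mean indel events per
#'   branch by mechanism (Poisson).
#' @param unit_len Length range of tandem units.
#' @param unit_motifs Motif pool for tandem duplications.
#' @param motif_prob Probability that a tandem duplication copies a pool
#'   motif occurrence instead of a random unit.
#' @param indel_spacing Minimum distance (bp) between indel events, and from
#'   the central YR and the sequence ends.
#' @param yr_protect Exempt the central YR dinucleotide from mutation (lift
#'   to test YR-filter attrition itself).
#' @return A `sim_config` list.
#' @export
sim_config <- function(length = 601L, island_fraction = 0.67,
                       island_gc = 0.60, island_score = 0.8,
                       nonisland_gc = 0.42, nonisland_score = 0.25,
                       composition_tol = 0.05,
                       sub_rate = 0.025, cpg_multiplier = 10,
                       slippage_rate = 0.3, tandem_dup_rate = 0.05,
                       tandem_del_rate = 0.05, unit_len = c(5L, 10L),
                       unit_motifs = "TCGGC", motif_prob = 0.25,
                       indel_spacing = 12L, yr_protect = TRUE) {
  stopifnot(length %% 2L == 1L, length >= 41L,
            island_fraction >= 0, island_fraction <= 1,
            sub_rate >= 0, sub_rate <= 1, cpg_multiplier >= 1,
            slippage_rate >= 0, tandem_dup_rate >= 0, tandem_del_rate >= 0)
  structure(
    list(length = as.integer(length), island_fraction = island_fraction,
         island_gc = island_gc, island_score = island_score,
         nonisland_gc = nonisland_gc, nonisland_score = nonisland_score,
         composition_tol = composition_tol, sub_rate = sub_rate,
         cpg_multiplier = cpg_multiplier, slippage_rate = slippage_rate,
         tandem_dup_rate = tandem_dup_rate, tandem_del_rate = tandem_del_rate,
         unit_len = as.integer(unit_len), unit_motifs = unit_motifs,
         motif_prob = motif_prob, indel_spacing = as.integer(indel_spacing),
         yr_protect = yr_protect),
    class = "sim_config"
  )
}

empty_mutation_log <- function() {
  tibble(event = integer(0), type = character(0), pos = integer(0),
         ref = character(0), alt = character(0), mechanism = character(0),
         cpg_context = logical(0))
}

#' Simulate an ancestral promoter sequence
#'
#' Draws a first-order Markov sequence whose stationary composition and
#' CpG-transition weighting target the class composition (rejection-sampled
#' until G+C content and CpG score fall within `composition_tol` of the
#' targets), then plants a YR dinucleotide (C/T then A/G) at the centre so
#' the +1 base is index `(length - 1) / 2`.
#'
#' @param class `"island"` or `"non_island"`.
#' @param config A [sim_config()].
#' @param max_tries Rejection-sampling budget.
#' @return A sequence string of length `config$length`.
#' @export
simulate_ancestor <- function(class = c("island", "non_island"),
                              config = sim_config(), max_tries = 200L) {
  class <- match.arg(class)
  L <- config$length
  if (class == "island") {
    gc_t <- config$island_gc; sc_t <- config$island_score
  } else {
    gc_t <- config$nonisland_gc; sc_t <- config$nonisland_score
  }
  p <- c(A = (1 - gc_t) / 2, C = gc_t / 2, G = gc_t / 2, T = (1 - gc_t) / 2)
  # CpG weighting: P(G | C) = f * p_G / z targets obs/exp = sc_t after
  # renormalisation, hence f = sc_t * (1 - p_G) / (1 - sc_t * p_G).
  f <- sc_t * (1 - p[["G"]]) / (1 - sc_t * p[["G"]])
  p_after_c <- p
  p_after_c[["G"]] <- f * p[["G"]]
  p_after_c <- p_after_c / sum(p_after_c)
  tol <- config$composition_tol
  center <- (L - 1L) %/% 2L  # 0-based index of the +1 base
  for (try in seq_len(max_tries)) {
    chars <- character(L)
    chars[1] <- sample(DNA_BASES4, 1, prob = p)
    for (i in 2:L) {
      probs <- if (chars[i - 1L] == "C") p_after_c else p
      chars[i] <- sample(DNA_BASES4, 1, prob = probs)
    }
    chars[center] <- sample(c("C", "T"), 1)       # Y at -1 (0-based center-1)
    chars[center + 1L] <- sample(c("A", "G"), 1)  # R at 0
    seq <- paste(chars, collapse = "")
    st <- cpg_stats(seq)
    if (abs(st$gc - gc_t) <= tol && abs(st$score - sc_t) <= tol) return(seq)
  }
  abort(sprintf("could not reach composition targets for class '%s' in %d tries",
                class, max_tries))
}

#' Evolve a promoter sequence along one branch
#'
#' Applies (1) per-site substitutions — CpG-context cytosines mutate C->T
#' (and guanines G->A on the complementary-strand context) with probability
#' `cpg_multiplier * sub_rate`, all other A/C/G/T sites mutate to a uniform
#' different base with probability `sub_rate`; contexts are read off the
#' input sequence — and (2) indels: homopolymer slippage (a run of >= 2
#' gains or loses one base) and tandem duplication/deletion of a short unit
#' adjacent to an existing copy. The central YR dinucleotide is exempt when
#' `yr_protect` is set. Every event is recorded in a mutation log whose
#' replay ([replay_log()]) reproduces the derived sequence exactly.
#'
#' @param seq Ancestral sequence (uppercase A/C/G/T).
#' @param config A [sim_config()]; the rate fields drive this branch.
#' @param tss 0-based index of the +1 base (default: centre of `seq`).
#' @return List: `seq` (derived), `log` (mutation-log tibble; substitution
#'   positions refer to the ancestor, indel positions to the sequence state
#'   at event time), `tss` (0-based index of the +1 base in the derived
#'   sequence).
#' @export
evolve_sequence <- function(seq, config = sim_config(), tss = NULL) {
  assert_seq(seq)
  L <- nchar(seq)
  tss <- tss %||% ((L - 1L) %/% 2L)
  chars <- seq_chars(seq)[[1]]
  protected <- if (config$yr_protect) c(tss - 1L, tss) else integer(0)  # Y, R (0-based)
  log <- list()
  ev <- 0L

  ## substitutions (contexts from the input sequence)
  r <- config$sub_rate
  mr <- min(1, config$cpg_multiplier * r)
  is_c <- chars == "C"; is_g <- chars == "G"
  cpg_c <- which(is_c & c(is_g[-1], FALSE))      # C of a CpG (1-based)
  cpg_g <- which(is_g & c(FALSE, is_c[-L]))      # G of a CpG
  ctx <- rep("none", L)
  ctx[cpg_c] <- "cpg_c"; ctx[cpg_g] <- "cpg_g"
  eligible <- which(chars %in% DNA_BASES4 & !((seq_len(L) - 1L) %in% protected))
  u <- runif(L)
  for (i in eligible) {
    if (ctx[i] == "cpg_c") {
      if (u[i] < mr) {
        ev <- ev + 1L
        log[[ev]] <- tibble(event = ev, type = "sub", pos = i - 1L,
                            ref = "C", alt = "T", mechanism = "deamination",
                            cpg_context = TRUE)
      }
    } else if (ctx[i] == "cpg_g") {
      if (u[i] < mr) {
        ev <- ev + 1L
        log[[ev]] <- tibble(event = ev, type = "sub", pos = i - 1L,
                            ref = "G", alt = "A", mechanism = "deamination",
                            cpg_context = TRUE)
      }
    } else if (u[i] < r) {
      alt <- sample(setdiff(DNA_BASES4, chars[i]), 1)
      ev <- ev + 1L
      log[[ev]] <- tibble(event = ev, type = "sub", pos = i - 1L,
                          ref = chars[i], alt = alt, mechanism = "substitution",
                          cpg_context = FALSE)
    }
  }
  for (e in log) chars[e$pos + 1L] <- e$alt
  cur <- paste(chars, collapse = "")

  ## indels
  spacing <- config$indel_spacing
  occupied <- list()  # 0-based half-open intervals in *current* coordinates
  if (config$yr_protect) occupied <- list(c(tss - 1L, tss + 1L))
  cur_tss <- tss
  blocked <- function(lo, hi) {
    if (lo < spacing || hi > nchar(cur) - spacing) return(TRUE)
    any(vapply(occupied, function(iv)
      lo < iv[2] + spacing && hi > iv[1] - spacing, logical(1)))
  }
  apply_indel <- function(pos, piece, insert, mechanism) {
    w <- nchar(piece)
    if (insert) {
      cur <<- paste0(substr0(cur, 0L, pos), piece, substr0(cur, pos, nchar(cur)))
      shift <- w
      occupied <<- lapply(occupied, function(iv)
        if (iv[1] >= pos) iv + shift else iv)
      if (cur_tss >= pos) cur_tss <<- cur_tss + shift
      occupied[[length(occupied) + 1L]] <<- c(pos, pos + w)
    } else {
      cur <<- paste0(substr0(cur, 0L, pos), substr0(cur, pos + w, nchar(cur)))
      occupied <<- lapply(occupied, function(iv)
        if (iv[1] >= pos + w) iv - w else iv)
      if (cur_tss >= pos + w) cur_tss <<- cur_tss - w
      occupied[[length(occupied) + 1L]] <<- c(pos, pos)
    }
    ev <<- ev + 1L
    log[[ev]] <<- tibble(event = ev, type = if (insert) "ins" else "del",
                         pos = pos, ref = if (insert) "" else piece,
                         alt = if (insert) piece else "",
                         mechanism = mechanism, cpg_context = FALSE)
  }

  n_slip <- rpois(1, config$slippage_rate)
  n_dup <- rpois(1, config$tandem_dup_rate)
  n_del <- rpois(1, config$tandem_del_rate)

  for (k in seq_len(n_slip)) {
    runs <- homopolymer_runs(cur, min_len = 2L)
    if (nrow(runs) == 0) next
    runs <- runs[!vapply(seq_len(nrow(runs)), function(j)
      blocked(runs$start[j], runs$end[j]), logical(1)), , drop = FALSE]
    if (nrow(runs) == 0) next
    j <- sample(nrow(runs), 1)
    base <- runs$base[j]
    if (runif(1) < 0.5) {
      apply_indel(runs$start[j], base, insert = TRUE, mechanism = "slippage")
    } else {
      apply_indel(runs$start[j], base, insert = FALSE, mechanism = "slippage")
    }
  }

  # Tandem arrays built this branch: index into `occupied` plus the unit, so
  # successive duplications can keep expanding one array (repeat expansion),
  # the one sanctioned exception to the event-spacing rule.
  arrays <- list()
  for (k in seq_len(n_dup)) {
    unit <- NULL; s <- NA_integer_
    use_motif <- runif(1) < config$motif_prob && length(config$unit_motifs) > 0
    if (use_motif) {
      motif <- sample(config$unit_motifs, 1)
      grow <- which(vapply(arrays, function(ar) ar$unit == motif, logical(1)))
      if (length(grow) > 0) {
        j <- grow[sample(length(grow), 1)]
        iv <- occupied[[arrays[[j]]$slot]]
        apply_indel(iv[2], motif, insert = TRUE, mechanism = "tandem_dup")
        # extend the array's occupied interval over the new copy
        occupied[[arrays[[j]]$slot]] <- c(iv[1], iv[2] + nchar(motif))
        occupied[[length(occupied)]] <- NULL
        next
      }
      occ <- motif_occurrences(cur, motif)
      occ <- occ[!vapply(occ, function(o)
        blocked(o, o + nchar(motif)), logical(1))]
      if (length(occ) > 0) {
        s <- occ[[sample(length(occ), 1)]]
        unit <- motif
      }
    }
    if (is.null(unit)) {
      if (length(arrays) > 0) {  # no fresh template: keep expanding an array
        j <- sample(length(arrays), 1)
        iv <- occupied[[arrays[[j]]$slot]]
        apply_indel(iv[2], arrays[[j]]$unit, insert = TRUE,
                    mechanism = "tandem_dup")
        occupied[[arrays[[j]]$slot]] <- c(iv[1], iv[2] + nchar(arrays[[j]]$unit))
        occupied[[length(occupied)]] <- NULL
        next
      }
      w <- sample(seq(config$unit_len[1], config$unit_len[2]), 1)
      cands <- which(!vapply(seq_len(max(0L, nchar(cur) - w + 1L)) - 1L,
                             function(o) blocked(o, o + w), logical(1))) - 1L
      if (length(cands) == 0) next
      s <- cands[sample(length(cands), 1)]
      unit <- substr0(cur, s, s + w)
    }
    apply_indel(s + nchar(unit), unit, insert = TRUE, mechanism = "tandem_dup")
    # record the template + inserted copy as one growable array
    occupied[[length(occupied)]] <- c(s, s + 2L * nchar(unit))
    arrays[[length(arrays) + 1L]] <- list(slot = length(occupied), unit = unit)
  }

  for (k in seq_len(n_del)) {
    cands <- adjacent_duplications(cur, config$unit_len[1], config$unit_len[2])
    if (nrow(cands) == 0) next
    cands <- cands[!vapply(seq_len(nrow(cands)), function(j)
      blocked(cands$start[j], cands$start[j] + 2L * cands$len[j]),
      logical(1)), , drop = FALSE]
    if (nrow(cands) == 0) next
    j <- sample(nrow(cands), 1)
    piece <- substr0(cur, cands$start[j] + cands$len[j],
                     cands$start[j] + 2L * cands$len[j])
    apply_indel(cands$start[j] + cands$len[j], piece, insert = FALSE,
                mechanism = "tandem_del")
  }

  list(seq = cur,
       log = if (ev > 0) dplyr::bind_rows(log) else empty_mutation_log(),
       tss = cur_tss)
}

# Homopolymer runs of length >= min_len: tibble start (0-based), end
# (half-open), base.
homopolymer_runs <- function(seq, min_len = 2L) {
  chars <- seq_chars(seq)[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_len & r$values %in% DNA_BASES4
  tibble(start = starts[keep], end = ends[keep], base = r$values[keep])
}

# 0-based start positions of exact motif occurrences.
motif_occurrences <- function(seq, motif) {
  h <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1]]
  h <- as.integer(h)
  as.list(h[h > 0] - 1L)
}

# Positions where seq[start, start+len) == seq[start+len, start+2len):
# existing adjacent duplications, over the unit-length range.
adjacent_duplications <- function(seq, min_len, max_len) {
  out <- list()
  for (w in seq.int(min_len, max_len)) {
    n <- nchar(seq) - 2L * w + 1L
    if (n < 1) next
    starts <- seq_len(n) - 1L
    first <- substring(seq, starts + 1L, starts + w)
    second <- substring(seq, starts + w + 1L, starts + 2L * w)
    hit <- which(first == second & !grepl("N", first, fixed = TRUE))
    if (length(hit)) out[[length(out) + 1L]] <-
        tibble(start = starts[hit], len = w)
  }
  if (length(out) == 0) return(tibble(start = integer(0), len = integer(0)))
  dplyr::bind_rows(out)
}

#' Replay a mutation log
#'
#' Applies the events of a mutation log, in order, to an ancestral sequence.
#' Reproduces [evolve_sequence()]'s derived sequence exactly.
#'
#' @param seq Ancestral sequence.
#' @param log Mutation-log tibble.
#' @return The derived sequence string.
#' @export
replay_log <- function(seq, log) {
  cur <- seq
  for (i in seq_len(nrow(log))) {
    pos <- log$pos[i]
    if (log$type[i] == "sub") {
      stopifnot(substr0(cur, pos, pos + 1L) == log$ref[i])
      substr(cur, pos + 1L, pos + 1L) <- log$alt[i]
    } else if (log$type[i] == "ins") {
      cur <- paste0(substr0(cur, 0L, pos), log$alt[i],
                    substr0(cur, pos, nchar(cur)))
    } else {
      w <- nchar(log$ref[i])
      stopifnot(substr0(cur, pos, pos + w) == log$ref[i])
      cur <- paste0(substr0(cur, 0L, pos), substr0(cur, pos + w, nchar(cur)))
    }
  }
  cur
}

#' Reduce a mutation log to its net indel set
#'
#' Composes the indel events of one branch's mutation log into the *net*
#' indels distinguishing the derived sequence from its ancestor: successive
#' insertions that stack at one locus (tandem-array growth) merge into a
#' single net insertion. Substitution events are ignored. Net insertion
#' positions are reported in derived-sequence coordinates (the sequence
#' carrying the fragment); net deletion positions in ancestor coordinates
#' (ditto). With these conventions a net indel compares directly against an
#' indel site detected in an alignment of derived versus ancestor.
#'
#' @param log A mutation-log tibble from [evolve_sequence()].
#' @return Tibble `type` (`ins`/`del`), `pos` (0-based), `seq`.
#' @export
log_to_indels <- function(log) {
  nets <- list()  # ins: pos in current coords; del: cur anchor + orig pos
  for (i in seq_len(nrow(log))) {
    type <- log$type[i]
    if (type == "sub") next
    pos <- log$pos[i]
    if (type == "ins") {
      piece <- log$alt[i]
      w <- nchar(piece)
      target <- NA_integer_
      for (k in seq_along(nets)) {
        nt <- nets[[k]]
        if (nt$type == "ins" && pos >= nt$pos &&
            pos <= nt$pos + nchar(nt$seq)) {
          target <- k
          break
        }
      }
      for (k in seq_along(nets)) {
        if (!is.na(target) && k == target) next
        if (nets[[k]]$cur >= pos) nets[[k]]$cur <- nets[[k]]$cur + w
        if (nets[[k]]$type == "ins" && nets[[k]]$pos >= pos) {
          nets[[k]]$pos <- nets[[k]]$pos + w
        }
      }
      if (!is.na(target)) {
        nt <- nets[[target]]
        off <- pos - nt$pos
        nt$seq <- paste0(substr0(nt$seq, 0L, off), piece,
                         substr0(nt$seq, off, nchar(nt$seq)))
        nets[[target]] <- nt
      } else {
        orig <- pos -
          sum(vapply(nets, function(nt)
            if (nt$type == "ins" && nt$pos < pos) nchar(nt$seq) else 0L,
            numeric(1))) +
          sum(vapply(nets, function(nt)
            if (nt$type == "del" && nt$cur <= pos) nchar(nt$seq) else 0L,
            numeric(1)))
        nets[[length(nets) + 1L]] <- list(type = "ins", pos = pos, cur = pos,
                                          orig = orig, seq = piece)
      }
    } else {  # del
      piece <- log$ref[i]
      w <- nchar(piece)
      orig <- pos -
        sum(vapply(nets, function(nt)
          if (nt$type == "ins" && nt$pos < pos) nchar(nt$seq) else 0L,
          numeric(1))) +
        sum(vapply(nets, function(nt)
          if (nt$type == "del" && nt$cur <= pos) nchar(nt$seq) else 0L,
          numeric(1)))
      for (k in seq_along(nets)) {
        if (nets[[k]]$cur >= pos + w) nets[[k]]$cur <- nets[[k]]$cur - w
        if (nets[[k]]$type == "ins" && nets[[k]]$pos >= pos + w) {
          nets[[k]]$pos <- nets[[k]]$pos - w
        }
      }
      nets[[length(nets) + 1L]] <- list(type = "del", pos = pos, cur = pos,
                                        orig = orig, seq = piece)
    }
  }
  if (length(nets) == 0) {
    return(tibble(type = character(0), pos = integer(0), seq = character(0)))
  }
  out <- tibble(
    type = vapply(nets, `[[`, character(1), "type"),
    pos = vapply(nets, function(nt)
      as.integer(if (nt$type == "ins") nt$pos else nt$orig), integer(1)),
    seq = vapply(nets, `[[`, character(1), "seq")
  )
  dplyr::arrange(out, .data$pos)
}

#' Generate a cohort of orthologous promoter pairs with ground truth
#'
#' Each pair is one ancestral promoter evolved independently along two
#' branches (A and B, emulating the two compared species). Deterministic
#' given `seed`.
#'
#' @param n Number of pairs.
#' @param config A [sim_config()] providing the ancestor model and the
#'   default branch parameters.
#' @param branch_a,branch_b Named lists of [sim_config()] fields overriding
#'   `config` on one branch (e.g. `list(sub_rate = 0)`).
#' @param seed Random seed (integer) or NULL to use the current RNG state.
#' @return Tibble with one row per pair: `pair`, `class_anc` (ancestral
#'   class), `ancestor`, `seq_a`, `seq_b`, `tss_a`, `tss_b` (0-based +1-base
#'   indices in the derived sequences) and list-columns `log_a`, `log_b`
#'   (mutation logs).
#' @export
generate_cohort <- function(n, config = sim_config(), branch_a = list(),
                            branch_b = list(), seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cfg_a <- merge_config(config, branch_a)
  cfg_b <- merge_config(config, branch_b)
  rows <- purrr::map(seq_len(n), function(i) {
    class <- if (runif(1) < config$island_fraction) "island" else "non_island"
    anc <- simulate_ancestor(class, config)
    a <- evolve_sequence(anc, cfg_a)
    b <- evolve_sequence(anc, cfg_b)
    tibble(pair = i, class_anc = class, ancestor = anc,
           seq_a = a$seq, seq_b = b$seq, tss_a = a$tss, tss_b = b$tss,
           log_a = list(a$log), log_b = list(b$log))
  })
  dplyr::bind_rows(rows)
}

merge_config <- function(config, overrides) {
  if (length(overrides) == 0) return(config)
  bad <- setdiff(names(overrides), names(config))
  if (length(bad)) abort(paste("unknown sim_config fields:",
                               paste(bad, collapse = ", ")))
  config[names(overrides)] <- overrides
  config
}
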