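---
title: "Methods: base-resolution comparison of orthologous promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: base-resolution comparison of orthologous promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promdiverge)
```

promdiverge compares orthologous promoter sequences between two closely
related genomes at single-base resolution. The design rests on two ideas:
the transcription start site (TSS) is used as an alignment anchor for
non-coding sequence, where no reading frame exists to anchor on; and
promoters are typed as CpG-island or non-CpG-island from the fixed-length
window around the TSS, so that the *changes* in type between species — and
the substitutions and indels behind them — can be characterised.

This vignette explains the models and conventions, the tunable parameters,
what the synthetic cohort generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## Promoter windows and the YR anchor

A promoter window is excised around a TSS in transcript orientation:
`upstream` bases, the +1 base, and `downstream` bases; the default 300/300
yields the 601-nt window whose centre (0-based index 300) is the TSS. On
the minus strand the window is the reverse complement of the mirrored
genomic slice. All coordinates in the package are 0-based and half-open;
TSS tables store the genomic index of the +1 base. Windows overlapping a
chromosome edge are dropped, not padded.

The minimal initiator signature is a pyrimidine–purine (YR) dinucleotide at
positions −1/0. `check_yr()` is deliberately conservative: `N` at either
position fails. The YR anchor is used twice: to validate the mapped
counterpart position when a candidate hit is extended to the full window
(`anchor_and_extend()`, which rejects with the reasons `unmapped`, `no-YR`
or `gap`), and as a final cross-species filter (`filter_pairs()`), which
discards refined pairs whose Y or R base differs between the species.

## CpG-island classification

`cpg_stats()` computes G+C content and the observed/expected CpG score
`n_CpG * N / (n_C * n_G)` over the full window length `N` (601 by
default). `N` bases are excluded from the counts but kept in the length,
matching the fixed-window convention; windows with assembly gaps are
expected to be rejected upstream, so this rule only guards synthetic edge
cases. A promoter is a CpG-island promoter iff `gc >= 0.5` **and**
`score >= 0.6`; both thresholds are inclusive and configurable. The two
comparisons define four quadrants (low/high G+C × low/high CpG); the
island quadrant is high/high. `count_type_changes()` tallies the 4×4
quadrant transition matrix between species and its 2×2 island collapse,
and `pair_group()` labels pairs `hCmC`, `hCmN`, `hNmC`, `hNmN`.

## Alignment and scoring

Candidate counterpart regions (PSL hits) are filtered on identity ≥ 0.90
and target span > 200 bp, keeping the longest passing hit. Identity is
computed as matches over the *target span*; the choice of denominator is a
package convention, documented here and pinned by tests.

Refined pairwise alignments are optimal global affine-gap alignments
(Needleman–Wunsch) computed with Biostrings' dynamic-programming engine
behind the `global_align()` surface. Default scores: match +1, mismatch
−1, gap open 10, gap extension 0.2 per gapped base — gaps rare but cheap
to extend, as suits diverged non-coding DNA. `N`
scores as a mismatch against everything, including `N`. Tie-breaking
between co-optimal alignments follows the engine's deterministic internal
rule; every statistic the pipeline derives from alignments is either
tie-invariant (the score) or interpreted per realised alignment (indel
placement, which is additionally left-normalised wherever two placements
are equivalent).

The *alignment score* used for the filters is percent identity over the
shorter ungapped sequence, a pairwise-score convention; pairs below 90
are discarded from the divergence analyses, and a relaxed cutoff of 80 is
used for the indel stage. Both cutoffs are configurable
(`pipeline_config()`).

## Divergence spectra

`dinuc_alteration_rates()` walks every overlapping dinucleotide of the
ungapped source row and calls it altered if either aligned counterpart
base differs, is a gap or is `N`, or if an insertion in the counterpart
intervenes. Occurrences are pooled across alignments (not averaged
per-pair); grouping follows source species × counterpart island status.
`cpg_fate_spectrum()` classifies each source CpG by its counterpart
dinucleotide: conserved `CpG`, the deamination products `TpG` and `CpA`,
`other`, or `gap`. `deamination_enrichment()` is the ratio of per-CpG
deamination-fate frequencies between a type-change group and the
island-conserved group, per direction; a zero denominator is reported as
an infinite ratio with a flag rather than an error.

## Recovering the deamination multiplier

The generator plants a known CpG-context transition multiplier `m`:
CpG cytosines mutate C→T (and the complementary-strand guanines G→A) at
`m` times the baseline per-site rate. `estimate_cpg_multiplier()` recovers
`m` from a cohort of alignments, and its construction is worth spelling
out because the obvious estimator is inconsistent:

* A CpG observed in the source species is conditioned on having survived
  its own branch, so its alteration rate reflects only the counterpart
  branch, while any background rate accumulates differences on both
  branches. Hazards must therefore be put on a common per-branch,
  per-base scale before forming a ratio.
* At high `m`, deamination products (T from CpG cytosines, A from CpG
  guanines) pervade the sequence, so *every* dinucleotide containing A or
  T receives influx whose aligned counterpart is still C or G; no row of
  the 16-dinucleotide spectrum is a clean background.

The estimator therefore uses two structurally clean channels. The
baseline hazard `b` comes from A/T-embedded sites (source base A or T,
both neighbours A/T in both species and identical across them), counting
only **A-versus-T** mismatches: deamination mismatches are always T:C or
A:G, so this channel cannot contain them. Under uniform baseline
mutation, the channel rate is `q(1 − q)` with `q = 2b/3`. The deamination
hazard `h` comes from the CpG fate channel, `f(TpG) + f(CpA) = 2h(1 − h)`
among gap-free ancestral source CpGs; the contribution of non-ancestral
CpGs (created by a baseline substitution on the source branch, whose
counterpart may legitimately read TG or CA) is estimated from the
counterpart species' dinucleotide composition (`C_TG · b/3` into the TpG
fate, and so on) and subtracted before inversion. The estimate `h/b` is
averaged over both directions. Under the generator's default island
conditions the estimator recovers a planted multiplier of 10 to within a
few percent at 500 pairs, which the acceptance suite checks at a 25%
tolerance.

## Indels

`detect_indels()` reports one site per maximal gap run; adjacent runs in
opposite rows are distinct sites (no merging). Flank conservation is
counted over 10 alignment columns on each side, gaps and `N` counting as
mismatches; edge-truncated flanks are flagged and always dropped by
`flank_filter()`. The default flank rule is ≥ 8 matches of 10; a stricter
9/10 variant is equally defensible, so the threshold is configurable and
the default is the laxer rule.

`cpg_delta()` counts CpGs over the gap run extended by one column on each
side — the minimal window that captures junction-spanning CpGs — in the
carrier row minus the other row, both ungapped. Wider windows are a
possible extension; one base is the smallest window that makes the
junction cases well defined.

Because gap placement inside a repeat is alignment-degenerate,
`left_normalize_indel()` shifts an indel to its leftmost equivalent
placement (rotating the fragment as it moves), and all recovery
comparisons normalise both the planted and the detected side.

`polarize_indel()` performs single-event parsimony on the fixed primate
topology `((((human,chimpanzee),gorilla),(macaque,baboon)),marmoset)`: an
event is assigned only when exactly one branch's descendant clade carries
the minority state; ties and multi-event patterns return `ambiguous`
rather than a guess. The complementary clades under the root are the one
structurally ambiguous pair.

## Dot plots and repeat association

`harr_plot()` slides a 5-bp window with a 1-bp stride and records exact
matches only (windows containing `N` never match); the reverse
orientation compares against reverse-complemented windows.
`repeat_association()` operationalises what was originally a visual
inspection: the carrier-row region spanning the indel ± 25 bp is
self-compared, and the site is tandem-associated if an off-diagonal dot's
window overlaps the indel interval (inverted: the same in
reverse-complement orientation). Both the neighbourhood and the window
are configurable; this rule is an interpretation, and its outputs should
be read as a screen, not a repeat annotation.

## Motif scans

`position_frequency_matrix()` computes per-position base frequencies and
information content `2 − H` bits from raw frequencies, without
small-sample correction — the contract is the matrix, not a rendered
logo. The logo window default is 34 nt upstream / 5 nt downstream
(40 nt total); both flanks are configurable. `tataaa_scan()` counts 5'-end
positions of exact `TATAAA` matches lying wholly within the 40-bp
upstream region; overlapping occurrences all count, and a match must end
by position −1.

## The synthetic cohort generator

`generate_cohort()` evolves each ancestral promoter independently along
two branches, emulating the two-species design without an explicit tree.
Defaults are the package's study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| length | 601 nt | fixed analysis window, TSS centred |
| island fraction | 0.67 | roughly two-thirds of real human promoter pairs are island-type |
| island composition | G+C 0.60, CpG score 0.8 | observed island cluster centre |
| non-island composition | G+C 0.42, CpG score 0.25 | CpG-depleted bulk genome |
| per-branch substitution rate | 0.025 | ~93% genome identity between the compared species, substitution share |
| CpG multiplier | 10 | order of magnitude of CpG hypermutability |
| slippage / tandem-dup / tandem-del | 0.3 / 0.05 / 0.05 events per branch | makes single-nucleotide indels the majority class |

Ancestors are first-order Markov sequences whose CpG transition weight is
solved analytically from the target obs/exp score, then
rejection-sampled to within ±0.05 of both composition targets; a YR
dinucleotide is planted at the centre. The central YR is exempt from
mutation by default so the YR-match filter does not confound recovery
experiments; a flag lifts the exemption to study filter attrition itself.

Indel events keep 12 bp clear of one another, of the central YR and of
the sequence ends, so that every planted event retains intact 10-bp
flanks and remains individually identifiable — the premise of the
exact-recovery tests. The one sanctioned exception is tandem-array
growth: successive duplications may keep extending one array, which is
precisely the repeat-expansion route to island gain. `log_to_indels()`
composes a branch's event log into the equivalent *net* indel set
(merging stacked insertions), which is what detection is compared
against.

What the generator does **not** emulate: context-dependent substitution
beyond the CpG multiplier, selection, rate heterogeneity along the
window, transposon insertion, gene conversion, or large structural
change. Consequently, passing recovery tests demonstrate that the
pipeline measures what the model plants — they do not certify rates on
real genomes. In particular the default conditions are more CpG-labile
than real conserved promoter sets (a 10× multiplier on ~7% total
divergence churns CpGs faster than real orthologous island promoters,
which retain ~86% of CpG sites), so the absolute conservation fractions
reported on synthetic cohorts are not comparable to published values on
real data.

## Problem sizes and numerical conventions

The test and acceptance runs use cohorts of up to 500 pairs and oracle
checks of 100–200 random cases — sizes at which the brute-force oracles
(exhaustive alignment enumeration at length ≤ 7; all-pairs window
comparison at length ≤ 60) stay exact and fast. Alignment scores are
compared to the oracle at 1e−5, absorbing the single-precision storage of
gap penalties in the alignment engine. Divergence and fate fractions are
exact rational counts; determinism is pinned by seeding every stochastic
stage, and `run_pipeline()` itself draws no random numbers, so identical
inputs yield byte-identical reports.

## Known limitations

* The alignment-score convention (percent identity over the shorter
  ungapped sequence) and the PSL identity denominator are package
  conventions pinned by tests, not values inherited from a published
  definition.
* Repeat association is a screen with a configurable, interpretive rule;
  it has no external gold standard here.
* The indel-polarity operation assumes presence/absence calls are given;
  deriving them from multi-species alignments is out of scope.
* Maximum detectable indel length is bounded by alignment quality at the
  80-score cutoff; large structural variants are out of scope.
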