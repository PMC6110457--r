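---
title: "Detecting recursive splice sites from nascent RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recursive splice sites from nascent RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratchetr)
```

## The problem

Very long introns — common in *Drosophila* and in the long genes of
mammalian nervous systems — are often removed piecewise.  An intronic
*recursive site* (RS) carries a juxtaposed 3' and 5' splice-site motif
around a central `AG|GT`: it first serves as an acceptor, excising the
upstream segment, and the splicing reaction regenerates a donor that
removes the remainder.  Because the intermediates are short-lived,
recursive splicing is essentially invisible in steady-state RNA-seq;
metabolically labeled (4sU) nascent RNA-seq captures it through three
weak but complementary signals, each of which this package turns into a
detector:

1. **Junction reads** (`find_ratchet_junctions()`): split reads whose
   upstream edge matches an annotated 5' splice site exactly and whose
   downstream edge lands on an intronic `AG|GT` upstream of the
   downstream-most 3' splice site sharing that donor.
2. **Spanning read pairs** (`select_spanning_pairs()`,
   `gem_infer_sites()`): pairs with one read just upstream of the donor
   and its mate deep in the intron.  Such a pair does not name a site;
   the site is inferred from the implied insert length under each
   candidate, via a sparse EM mixture model.
3. **Sawtooth coverage** (`mcmc_sawtooth()`, `call_peaks()`):
   co-transcriptional excision makes nascent read density decay
   linearly within each recursive segment and jump upward at each
   recursive site.  A Markov chain over site configurations, scored by
   piecewise heteroscedastic regression and BIC, converts the coverage
   profile into per-position site probabilities.

Calls from all detectors are merged, filtered, and tiered by
`run_ratchet_pipeline()`.

## Coordinates and containers

All intervals are 1-based closed, the native `GRanges`/`IRanges`
convention; rtracklayer performs the 0-based conversions at the BED and
bedGraph boundaries.  This was a deliberate choice over carrying
0-based half-open coordinates internally: the package leans on the
Bioconductor interval stack throughout, and a single convention with
I/O-side conversion avoids a class of off-by-one errors.  A splice
junction is stored as its removed gap `[gap_start, gap_end]`; a
recursive site coordinate is the first base of its GT on the
transcribed strand.

## The sawtooth model

Within a recursive segment the expected nascent coverage declines
linearly (polymerases are uniformly distributed along the gene; the
segment's RNA survives only until the next site is transcribed and the
segment spliced), so a configuration of \(N\) sites partitions the
binned intron profile into \(N+1\) linear pieces.  Counts are
overdispersed around the line with variance proportional to the mean,
which motivates the iteratively reweighted fit in
`heteroscedastic_regression()`: weights are updated to `1/fitted` until
no weight moves by more than `1e-3`.  The first pass is ordinary least
squares; on a noiseless line it converges immediately.  When a fit
predicts a non-positive density the weight is floored at `1e-6` to keep
the system finite.

A configuration \(M\) with \(N\) sites is scored by

\[ \mathrm{BIC}(M) = L \cdot \mathrm{RSS}(M) + 2\,(2N)\log L, \]

with \(L\) the intron length in nt and \(\mathrm{RSS}(M)\) the summed
weighted residuals of the per-segment fits ( \(2N\) free parameters: a
slope and intercept per extra segment).  The chain proposes adding a
site (probability 0.4), removing one (0.4), or shifting one locally by
1–5 bins (0.2).  Proposals whose fitted density does not rise at least
1.5-fold at every site are rejected outright — this is what confines
the model to sawtooth shapes rather than arbitrary piecewise trends.  A
lower-BIC proposal is accepted deterministically; a worse one with
probability \(\exp(-\Delta\mathrm{BIC}/T)\), \(T = 5\), halved when the
current state has no sites.  (Stated as a ratio of scores
\(e^{\mathrm{BIC}/T}\), the acceptance rule would exceed one for worse
states; the Metropolis form used here is the only self-consistent
reading and preserves the deterministic direction.)  After burn-in the
chain is sampled at a fixed stride and each bin's site probability is
its sample frequency.

Two guards are package choices: introns of 8 kb or less are skipped
(regressions over short segments chase count noise), and within an
intron, sites may not sit closer than 10 bins together or 5 bins from
an end, for the same reason at segment scale.

Peak calling thresholds the track at 0.08, merges regions within
500 nt, and scores every intronic `AG|GT` by
\(S(i) = P(i)\cdot\max(M(i)-0.8,\,0)\), where \(P\) is 1 inside a
region and decays logistically outside (0.5 at 500 nt, near zero at
1 kb) and \(M\) is the normalized motif score below.  The top-scoring
`AG|GT` per region is the call.  FDR comes from repositioning the
observed regions uniformly across the intron — count and lengths
preserved — and re-running the peak caller; the reported
`mcmc_probability` of a call is the maximum track probability in its
merged region, since the winning `AG|GT` can sit in a flank where its
own bin probability is zero.

## Motif scoring

PWMs are trained on the intronic portions of all annotated splice
sites: by default 20 nt ending in `AG` (3'SS) and 6 nt starting with
`GT` (5'SS), juxtaposed to a 26 nt recursive-site matrix.  The window
widths are configurable — the right extent for a compact-intron genome
is an empirical matter, and these defaults follow common fly splice-site
models.  A pseudocount of 1 per base per column keeps log
probabilities finite.  A window's bit score is the summed per-column
log2 probability, normalized by the attainable minimum and range so
scores live in \([0,1]\) with the consensus at exactly 1; `N` bases
contribute the column minimum (the conservative choice).

## The EM read-pair model

Candidate positions are the intronic `AG|GT`s with motif score above
0.8, with prior \(\Pi_i \propto \max(0, M(i) - 0.8)\).  The likelihood
of a pair under candidate \(m\) is the empirical fragment-length
probability of its implied insert — the portion upstream of the donor
plus the portion downstream of \(m\), the only fragment length
consistent with excision between donor and \(m\).  The fragment
distribution is a unit-width histogram over pairs (spans minus
completed annotated introns), smoothed with a Gaussian kernel of 10 nt
bandwidth because the raw histogram is sparse at small scale.  Each
M-step adds 5'SS–RS junction reads at a site into its effective count,
subtracts the sparsity penalty \(\alpha_s = \text{assigned reads}/40\)
and truncates at zero before renormalizing; junction reads are added
*before* sparsification (the alternative ordering is not determined by
the method's description; this composition preserves both stated
rules).  Convergence is declared when no prior moves by more than
`1e-5`, and pairs are then MAP-assigned.  Pairs whose insert is
impossible under every candidate contribute nothing — this is what lets
the sparsity penalty empty the model entirely when the data support no
site.  "Close upstream of the donor" is bounded at 300 nt, a plausible
fragment length.

Pairs explained by ordinary splicing are removed before inference: any
pair whose implied insert drops below 1 kb once some annotated intron
contained in its span is excised.  Skipped-exon (cassette) events are
not enumerated when applying this rule; the synthetic fixtures contain
none, and on real data this makes the selection slightly conservative
in genes with AG|GT-led cassette exons.

## Kinetics

Under progressive labeling for \(t\) minutes, transcript ages are
uniform on \([0, t]\); with first-order splicing at rate \(\lambda\)
the expected completed fraction is

\[ \theta(t) = 1 - \frac{1 - e^{-\lambda t}}{\lambda t}, \]

which is the model fitted by `estimate_half_life()` to the completed
fractions `ee/(ee+ie)` at 5, 10 and 20 minutes (bounded 1-D
least-squares over \(\lambda \in [10^{-4}, 10^{3}]\,\text{min}^{-1}\)).
Per-segment evidence counts straddling reads at the segment's
3'-bounding site as incomplete and junction reads ending at that site
as complete.  All-complete segments report the 0.1 min resolution
floor; all-incomplete segments report an infinite half-life, flagged.

The mean lifetime of a one-site intron is the expected maximum of the
two segment exponentials plus the first-segment transcription time:

\[ \tau = \frac{1}{\lambda_1} + \frac{1}{\lambda_2}
        - \frac{1}{\lambda_1+\lambda_2} + \frac{l_1}{1500}. \]

The minus sign follows from the expectation of a maximum of
independent exponentials (verified in the tests against a Monte-Carlo
oracle at \(10^6\) draws); a plus sign sometimes seen in print
contradicts that derivation.  The elongation rate is fixed at
1,500 nt/min and exposed as an argument.

## Confidence tiers

After filtering (gene TPM ≥ 1; at least 3 reads spanning the complete
junction of the largest donor-sharing intron; site not on an annotated
5' splice site), a call is **high** confidence when at least 2 methods
support it and either its junction-plus-pair support exceeds 5 reads or
its sawtooth FDR is ≤ 5%; **medium** when at least 1 method and the
same support or FDR ≤ 20%.  This parsing — method count AND (support OR
FDR) — is the only one under which each tier is strictly stronger than
the next.  Support sums junction reads and read pairs.  Manual
inspection of read densities is replaced by an automated check: the
fitted binned density must rise at least 1.5-fold at the call (computed
when a coverage profile exists; otherwise not gated).

## What the generator emulates — and what it does not

`simulate_ratchet_experiment()` builds a one-chromosome genome of
two-exon genes and plants, per recursive intron: sawtooth coverage
(linear decay from 20 reads/nt to half that per segment, Poisson noise,
a 2-fold jump at each site), 5'SS–RS junction reads (4/6/8 across the
5/10/20 min periods), RS–3'SS and complete junctions, 30 spanning pairs
with Normal(300, 50) fragments, and a 26 nt consensus element (one
random substitution) at each site; decoy `AG|GT`s within 50 nt of a
planted site are scrubbed.  Annotated splice sites carry the same
consensus so that PWMs trained on the synthetic annotation score
planted sites near 1 and background `AG|GT`s low.  These defaults are
the regime the detectors are specified for: ≥ 20× segment-start
coverage, ≥ 1.5-fold jumps, kb-scale segments.

Deliberately absent: repeat families and GC bias, multi-intron genes,
minus-strand fixture genes (the code paths are strand-aware and
unit-tested on minus-strand annotation, but fixtures and the lariat
search are plus-strand), expression heterogeneity, alignment error.
Passing tests therefore demonstrate correctness of the inference
machinery under its stated statistical assumptions, not robustness to
every artifact of real libraries.

## Problem sizes and numerical choices

Tests and the acceptance script run the chain at \(10^5\) iterations
with a \(10^4\) burn-in and a stride of 50 on 10–30 kb introns
(100–300 bins); the function defaults mirror a production schedule of
\(10^7\) iterations with a \(10^5\) burn-in, which the desk-scale runs
down-scale proportionally.  Segment fits are cached across the chain
(a proposal revisits mostly unchanged segments), which makes the R
implementation fast enough that no compiled code is needed.  Other
numerical constants: regression weight tolerance `1e-3`, weight floor
`1e-6`, EM prior tolerance `1e-5`, fragment-kernel bandwidth 10 nt,
shift move ±1–5 bins, FDR shuffles 200 by default.  Ties in the motif
scan and the lariat 7-mer scan break toward the leftmost position, so
all outputs are deterministic given a seed.

## Known limitations

* The sawtooth detector needs introns > 8 kb with at least one
  complete spanning junction read; shorter introns are reported as
  skipped rather than scanned.
* The lariat finder aligns half-reads exhaustively by Hamming match,
  which is exact but only practical on fixture-scale genomes; a
  genome-scale run would substitute an indexed aligner behind the same
  interface.
* Per-period output assumes the 5/10/20 min labeling design; other
  designs work throughout the kinetics functions via the `times`
  argument but the summary table's comma-lists are fixed to three
  periods plus a total.
* `recursive_index` in the summary table is reserved and emitted as
  `NA`.
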