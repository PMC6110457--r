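# ratchetr

Detection of recursive splice sites from nascent (4sU-labeled) RNA-seq.

Long introns are often removed in consecutive pieces: an intronic
element with juxtaposed 3' and 5' splice-site motifs around a central
`AG|GT` — a *recursive site* — first acts as an acceptor, then
regenerates a donor.  The intermediates are invisible at steady state,
so detection must work from the faint marks recursive splicing leaves
in nascent RNA-seq.  `ratchetr` implements the three complementary
detectors, their integration, and the downstream kinetics, for
computational biologists analyzing metabolic-labeling RNA-seq in
long-intron genomes (flies, mammalian neural genes):

* **Junction reads** — split reads joining an annotated 5' splice site
  to an intronic `AG|GT` (`find_ratchet_junctions()`), plus a search
  for alternative-order events (`find_alternative_order_junctions()`).
* **Spanning read pairs** — pairs straddling a recursive junction,
  assigned to candidate sites by a sparse EM mixture with a motif
  prior Π(i) ∝ max(0, M(i) − 0.8) and an empirical insert-length
  likelihood (`gem_infer_sites()`).
* **Sawtooth coverage** — MCMC over recursive-site configurations
  scored by BIC(M) = L·RSS(M) + 2(2N)·log L over piecewise
  heteroscedastic regressions, with a mandatory ≥ 1.5-fold fitted
  density jump at each site (`mcmc_sawtooth()`); peaks are called by
  S(i) = P(i)·max(M(i) − 0.8, 0) with a logistic position potential
  and FDR from uniformly repositioned null regions (`call_peaks()`,
  `estimate_sawtooth_fdr()`).

Supporting modules: juxtaposed splice-site PWMs with normalized bit
scores in [0, 1] (`build_pwms()`, `score_sites()`), lariat
(branchpoint-spanning) read rescue (`find_lariat_reads()`), splicing
half-lives from progressive labeling via
θ(t) = 1 − (1 − e^(−λt))/(λt) (`estimate_half_life()`), the one-site
intron lifetime τ = 1/λ₁ + 1/λ₂ − 1/(λ₁+λ₂) + l₁/1500
(`recursive_intron_lifetime()`), splicing accuracy from junction
dinucleotides (`splicing_accuracy()`), subsampling sensitivity and
iterative Fisher/BH GO enrichment, and a seed-deterministic synthetic
generator (`simulate_ratchet_experiment()`) so everything runs offline.

## Worked example

Simulate a four-gene experiment (two introns with planted recursive
sites, two decoys) and run the full pipeline:

```r
library(ratchetr)

expt <- simulate_ratchet_experiment(n_recursive = 2, n_decoy = 2, seed = 101)
calls <- run_ratchet_pipeline(expt$genome, expt$annotation,
                              expt$alignments, expt$expression,
                              coverage = expt$coverage,
                              fdr_shuffles = 100, seed = 5)
calls[c("intron_id", "recursive_site", "method", "junction_reads",
        "spanning_read_pairs", "mcmc_probability", "fdr",
        "motif_score", "confidence")]
```

```
          intron_id recursive_site                 method junction_reads
  chrS:1101-13100:+           7100 junction+pair+sawtooth     [4,6,8,18]
 chrS:14501-26500:+          20500 junction+pair+sawtooth     [4,6,8,18]
 spanning_read_pairs mcmc_probability fdr motif_score confidence
          [0,0,0,30]                1   0   0.9611238       high
          [0,0,0,30]                1   0   0.9611238       high
```

Both planted sites (truth: 7100 and 20500) are recovered by all three
detectors and no call is made in the decoy introns.  Reading the
columns: `junction_reads` and `spanning_read_pairs` are per-labeling
period comma lists `[5m,10m,20m,total]`; `mcmc_probability` is the
sawtooth chain's site probability in the called region; `fdr` the
shuffle-based false discovery rate of the sawtooth call; `motif_score`
the normalized PWM bit score of the 26-nt window (1 = consensus); and
`confidence` the tier (high: ≥ 2 methods and > 5 supporting reads or
FDR ≤ 5%).  `write_sites_tsv()` writes the full summary table;
`inst/scripts/ratchet.R` wraps simulation and the pipeline for shell
use.

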