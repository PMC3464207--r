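---
title: "Detecting differential cassette-exon splicing from exon-junction arrays"
author: "spliceScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential cassette-exon splicing from exon-junction arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceScreen)
```

## The problem and the model

Exon-junction microarrays measure pre-mRNA splicing by pairing probe sets
that report opposite outcomes of a cassette-exon choice. For one cassette
exon, four probe sets are laid out: one on the exon body, one on each of
the two inclusion junctions (upstream exon–cassette and cassette–downstream
exon), and one on the skipping junction formed when the cassette exon is
excluded. The exon and inclusion-junction signals rise with the exon
inclusion rate $\psi$; the skipping-junction signal rises with $1 - \psi$.

Because probe intensity confounds splicing with transcription, each
probe-set signal is divided by the expression signal of its gene, giving
the normalized splicing index

$$I_{\mathrm{norm}} = \frac{S_{\text{probe set}}}{S_{\text{gene}}},$$

with both signals background-corrected and on the linear scale. For a
constitutive probe set $I_{\mathrm{norm}}$ is genotype-invariant; for
cassette-exon probe sets it tracks $\psi$ directly (the package's no-noise
simulations reproduce mean $I_{\mathrm{norm}} \approx \psi$ across the
whole $[0,1]$ range, a property checked by the test suite).

### Preprocessing

The stage order is fixed: per-array background correction, quantile
normalization across arrays, log2 transform, and median-polish
summarization per probe set, after which signals return to the linear
scale. Background correction uses the normal + exponential convolution
model (observed = exponential signal + normal optical background) with the
standard mode/half-width heuristic: the background mean is the intensity
density mode, its spread is estimated from the intensities below the mode,
and the signal rate from the mean excess above it; the reported value is
the closed-form conditional expectation $E[\text{signal}\mid\text{observed}]$,
computed on the log scale so it remains strictly positive and monotone.
Quantile normalization forces identical column multisets, averaging the
reference values across tied ranks. Median polish fits
overall + probe + sample by iterated median sweeps (tolerance $10^{-6}$,
at most 10 sweeps) and keeps overall + sample effects — the probe-set
signal with per-probe affinities removed. The gene expression signal is
the median over the gene's exon-type (non-junction) probe sets; the median
is used because the aggregator is otherwise unspecified and a single
aberrant exon probe set (including the cassette exon itself) should not
drag the gene signal.

### Tiered event calling

Per probe set, the genotype difference in $I_{\mathrm{norm}}$ is tested
with a two-tailed pooled-variance Student $t$ test
($\mathrm{df} = n_a + n_b - 2$). Probe sets flagged constitutive,
multi-gene cross-hybridizing, or alternative-promoter measuring are
excluded from candidacy (constitutive sets still anchor the gene signal).
A probe set votes for its event when $P < \alpha$ (default 0.05). Votes
carry an implied inclusion direction — the sign of the mutant−control mean
$I_{\mathrm{norm}}$ for inclusion-reporting sets, the opposite sign for
the skipping junction — so probe sets that target competing isoforms must
move in opposite directions to agree. An event is **tier 1** with at least
two direction-concordant votes; discordant votes cancel the event
(ambiguous); a single vote yields a **tier-2 candidate** only when the
event is flagged both conserved and neuron-specific. $\alpha$ is a
screening threshold, deliberately uncorrected for multiplicity: the design
is screen-then-validate, and the validation arm (RT-PCR-style $\psi$, the
1.5-fold rule) carries the inferential weight. Direction consistency is
judged on voting probe sets only — a non-significant probe set does not
veto an otherwise concordant event.

### Validation-side inclusion rates

From two band intensities, $\psi = \mathrm{inc}/(\mathrm{inc} +
\mathrm{skip})$, undefined when both bands are zero. Replicate lanes are
aggregated by the mean $\psi$ per genotype (the aggregation rule is
otherwise unspecified; the mean is the conventional choice). Two
conditions differ when the $\psi$ ratio reaches 1.5-fold, boundary
inclusive ("at least"), with a $10^{-9}$ relative tolerance so that exact
boundary ratios such as $0.6/0.4$ are not lost to floating point; a
completely skipped exon in one condition always qualifies.

### Motif analysis

Analysis windows are the last 50 nt of the intron upstream of the 3'
splice site. The polypyrimidine tract is the maximal-scoring contiguous
segment under +1 per pyrimidine and −1.5 per purine, minimum length 8,
leftmost-then-longest on ties, found by a linear prefix-sum scan. The
weights are a design choice, exposed as arguments: one interior purine
survives if at least two pyrimidines follow (net +0.5), while purine runs
terminate the tract. k-mer enrichment contrasts window presence counts
between foreground and background sets with a two-sided Fisher exact test.
De novo discovery fits the zero-or-one-occurrence-per-sequence (ZOOPS)
model by EM against a fixed 0th-order background, with the classic
starting-point search: every distinct w-mer in the data seeds a candidate
matrix, each candidate gets a 5-iteration burn-in, and the three best are
refined to convergence (tolerance $10^{-6}$); the log-likelihood is
non-decreasing across iterations, which the suite asserts. RNA and DNA
alphabets are unified internally on RNA (T ≡ U); FASTA I/O stays DNA.
The point-substitution rule table for the functional GC element classifies
G→A at the G and C→U at the C as disrupting, substitutions of the
preceding U as neutral, and anything else as unknown rather than guessed.

### Expression and deletion mapping

Gene-level differential expression reuses the pooled $t$ on log2 gene
signals (the test is otherwise unspecified; using the same statistic as
the splicing screen keeps the two arms comparable), with
Benjamini-Hochberg q values and inclusive cutoffs of 1.5-fold and
FDR 0.15. Overrepresentation of a reference gene set among selected genes
uses Pearson's $\chi^2$ without continuity correction (df 1), falling back
to an additional Fisher exact P when an expected cell drops below 1.

The deletion mapper reconstructs the unique single deletion between a
wild-type and mutant sequence from the longest common prefix and suffix,
reports the leftmost placement (VCF-style left alignment) plus the number
of equivalent placements induced by repeated flanking bases, and verifies
the reconstruction exactly. `N` matches nothing, which is conservative
for breakpoint placement. Multi-variant differences are refused with the
first mismatch position rather than silently misassigned.

## What the simulator emulates

`simulateArray()` draws, per probe,
$\mathrm{affinity} \times \mathrm{expression} \times f(\psi)$ with
$f = \psi$, $1-\psi$, or $1$ by probe-set role, multiplies by
$2^{\mathcal{N}(0,\,\sigma_{\log_2})}$ and adds an exponential background —
exactly the convolution the preprocessing inverts. Affinities are
log-normal and fixed across samples, so median polish can remove them.
Defaults encode the benchmark conditions used throughout: 50 expressed
genes, 10 cassette events with $\psi$ 0.8 → 0.5, 4 replicates per
genotype, $\sigma_{\log_2} = 0.15$, background mean 20, affinity sd 0.25
(log2), 4 constitutive probe sets and 4 probes per set. Noise magnitudes
are conventional for oligonucleotide arrays, not fitted to any deposited
data set. Expression levels are log2-normal (mean 9, sd 1); an equal
number of silent genes accompanies the expressed ones so that, as on a
real whole-transcriptome array, the intensity mode sits at background
level — the regime the mode/half-width background estimator assumes.
Without those silent genes the estimator latches onto the signal bulk and
compresses low-$\psi$ splicing indices.

The simulator does **not** emulate probe-sequence effects (GC content,
cross-hybridization), spatial array artifacts, partial probe-set overlap
between events, correlated biological replicates, or annotation errors.
Passing the recovery benchmarks therefore demonstrates that the pipeline's
inference is correct under its own model assumptions at realistic noise,
not that real arrays of this design reach the same operating point.

Sequence simulation (`simulateSpliceSiteWindows()`) builds windows as
purine filler + pyrimidine tract + splice acceptor AG, planting the motif
at a configurable offset from the tract's 3' end in foreground windows
only. The default offset −4 keeps one pyrimidine after the motif, which
makes the tract scanner's end coincide with the generated tract end in
noise-free data; at −3 the scanner would legitimately stop the tract just
before the motif's purine. Background windows are motif-free by
construction (the filler contains no C and the tract no G), giving clean
presence/absence contrasts for the Fisher enrichment.

## Numerical choices and degenerate inputs

* Constant intensity column: background variance 0; fall back to
  subtracting the minimum and adding a floor of $10^{-8}$.
* Single-row matrix in quantile normalization: all columns become the row
  mean; a single column is returned unchanged.
* 1×1 median-polish block returns its value.
* Zero pooled variance in the $t$ test: equal means give $t=0, P=1$;
  unequal means report $P$ at the double minimum and an infinite $t$.
* Both RT-PCR bands zero: $\psi$ undefined (NA, flagged), never 0/0.
* Events with no post-filter probe sets: no call, never an error.
* EM uses a Dirichlet pseudocount of $10^{-3}$ per matrix cell, and
  $\gamma$ is clamped to $[10^{-6}, 1-10^{-6}]$.

## Problem sizes

The shipped benchmarks run at desk scale: arrays of 50 expressed + 50
silent genes (about 1,900 probes × 8 samples), 5-seed null studies,
30-sequence motif sets, and a 10-kb deletion substrate. These sizes give
stable pass/fail behavior for every property above while keeping the whole
suite in the minutes range.

## A worked run

```{r example, eval = FALSE}
cfg <- SimConfig(seed = 1)
se  <- simulateArray(cfg)
res <- screenSplicingEvents(se, alpha = 0.05)
tierPerformance(res$calls, simTruth(se))
#>         recall      precision        n_tier1 n_differential
#>              1              1             10             10
```

## Known limitations

* The tier-2 path depends entirely on input conservation/neuron-specific
  flags; the package does not compute conservation or EST support.
* The opposite-trend rule compares point estimates of voting probe sets;
  whether the original screen additionally required both competing probe
  sets to be individually significant is not specified, and this
  implementation's choice is recorded here rather than asserted as fact.
* The deletion mapper handles exactly one deletion; any additional variant
  between the sequences is an error by design.
* Absolute $I_{\mathrm{norm}}$ levels inherit a gene-wise scale from probe
  affinities and the background shift; all inference is therefore based on
  genotype contrasts, never on absolute index values.
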