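---
title: "Modeling UV-induced transcription inhibition and its 5' to 3' recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling UV-induced transcription inhibition and its 5' to 3' recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvtx)
```

## The model

UVC light deposits cyclobutane pyrimidine dimers and 6-4 photoproducts in
DNA. These lesions block elongating RNA polymerase II, so immediately after
irradiation nascent-RNA synthesis collapses in a gene-length-dependent way:
the chance that a transcription unit of length $L$ escapes damage on its
transcribed strand is $e^{-dL}$, where $d$ is the per-bp, per-strand lesion
density. Recovery of synthesis then depends on nucleotide excision repair:
transcription-coupled repair (TC-NER) clears the transcribed strand of
active genes starting at the 5' end, while global-genomic repair (GG-NER)
removes lesions anywhere. `uvtx` turns this picture into a quantitative,
testable pipeline with four layers:

1. **Lesions.** A dose of $D$ J/m$^2$ produces density
   $d = D/10 \times 1/14000$ lesions per bp per strand (`lesion_density()`),
   the standard UVC calibration of roughly one lesion per 7 kbp of duplex
   DNA per 10 J/m$^2$. Induction events are independent, so per gene and
   strand the lesion count is Poisson($dL$) with uniform positions
   (`place_lesions()`). CPDs and 6-4 photoproducts are pooled into one
   "transcription-blocking lesion" class; with separate densities the model
   would not be identifiable from coverage data. Dose scaling is linear (no
   saturation) and positions carry no dipyrimidine sequence bias.

2. **Repair.** `assign_removal_times()` gives every lesion a removal time:
   a deterministic TC-NER wave ($t = x/w$ for a transcribed-strand lesion
   at offset $x$; only genes with `basal_rate > 0`) and an independent
   Exponential($r$) GG-NER clock on both strands; the realized removal time
   is the pathway minimum. Genotype presets encode the classic fibroblast
   panel: wild type (both pathways), XP-C (TC-NER only), CS-B (GG-NER
   only), and NONE. Modeling TC-NER as a single wave from the TSS is the
   simplest mechanism that produces a 5'-to-3' recovery front; the data the
   model targets cannot distinguish one effective wave from repeated
   initiation-and-arrest cycles, so restarts of the wave are not modeled.

3. **Labeling.** `simulate_bru_window()` emulates a 30-minute bromouridine
   pulse beginning $t$ hours after irradiation. Polymerases initiate at the
   TSS as a Poisson process at the gene's basal rate (a pre-window
   steady state is included), elongate at constant speed, and arrest
   permanently at the first transcribed-strand lesion still present when
   they arrive — no resumption and no translesion bypass, so synthesis
   downstream of a block can only come from later initiations after repair.
   Only bases polymerized inside the window count as labeled.

4. **Sequencing.** `sample_reads()` allocates a fixed read total
   multinomially across all bins of all genes in proportion to expected
   labeled mass, and `simulate_experiment()` runs the full dose x time x
   genotype grid with one lesion realization per (gene, dose), shared
   across genotypes and timepoints so comparisons are paired.

### The arrest rule and the window expectation

Because initiation is Poisson, the expected labeled mass needs no
polymerase-level simulation. A polymerase initiating at time $s$ covers
position $x$ during the window $[t_0, t_0 + W]$ iff it arrives inside the
window ($s \in [t_0 - x/v,\ t_0 + W - x/v)$, with $v$ the elongation speed)
and no upstream lesion intercepts it. Lesion $j$ at position $x_j \le x$
with removal time $\rho_j$ arrests every polymerase arriving before
$\rho_j$, i.e. with $s < \rho_j - x_j/v$. The admissible initiation times
are therefore $s \ge S(x) = \max_{x_j \le x} (\rho_j - x_j/v)$, and the
expected coverage at $x$ is the initiation rate times

$$\max\!\big(0,\ (t_0 + W - x/v) - \max(t_0 - x/v,\ S(x))\big).$$

This is evaluated at bin midpoints (500 bp bins by default; the wave front
is therefore resolved to half a bin). One consequence deserves emphasis:
the occupancy that exists when the window opens is computed under the same
rule, so *all* coverage is carried by polymerases that traversed the
surviving lesion field from the TSS. Polymerases that happened to sit
downstream of a lesion at the moment of irradiation are not given an
escape route. This is exactly the no-resumption model — after UV, new
synthesis has to come from the beginning of genes — and it is what makes
the immediately-post-UV profile decay along the gene body with the
target-theory length dependence. A separate brute-force Monte Carlo
(`simulate_polymerases()`) draws independent lesion fields and runs one
polymerase against each; its survival fraction at $x$ reproduces
$e^{-dx}$ and serves as an independent check on the closed form.

Whether blocked polymerases backtrack, are degraded, or eventually resume
cannot be decided from coverage data; the simulator commits to permanent
arrest plus fresh initiation as a modeling choice, not a biological claim.
A per-gene `restart_competence` flag (default: all competent) reproduces
the occasional gene whose synthesis stays suppressed although its repair
is normal: when unset for a gene, lesions block its polymerases forever
even after removal.

## Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| lesion density at 10 J/m$^2$ | 1/14000 | per bp per strand | UVC calibration; linear in dose |
| `tc_wave_speed` | 6000 | bp/h | the wave covers ~144 kbp in 24 h, so TC-NER alone finishes typical long genes within a day but leaves the far 3' ends of the longest genes to GG-NER |
| `gg_rate` | 0.08 | /h | ~85% of lesions cleared in 24 h, so genotypes with GG-NER approach completion within the experiment |
| `elongation_speed` | 1500 | bp/min | a 30-min window covers at most 45 kbp of travel |
| `label_window` | 30 | min | the pulse length the assay emulates |
| `bin_width` | 500 | bp | resolves the 5' pile-up without inflating track size |

With these defaults, simulated aggregate recovery of genes >100 kbp
reaches roughly 93% (wild type), 76–80% (XP-C) and 45% (CS-B) by 24 h,
and XP-C tracks wild type closely at 6 h — the qualitative (and for XP-C
at 24 h, nearly quantitative) genotype pattern of the fibroblast panel.

## The synthetic gene set

`generate_gene_set()` emulates the statistical shape of a human
fibroblast nascent-transcription annotation rather than any real genome:

* lengths are log-normal (log-mean $\ln 30000$, log-sd 1.2), clipped to
  1 kbp–1 Mbp, spanning short (<20 kbp) and long (>100 kbp) genes;
* expression is gamma(shape 0.65, scale 2.8) with a 40% point mass at
  zero, calibrated once so the overall mean is ~1.09 and the overall
  median ~0.15 in RPKM-equivalent units — a transcriptome where most
  genes are lowly expressed;
* genes are non-overlapping on one synthetic chromosome with random
  intergenic gaps and random strands.

Because a simulated library contains only these genes, measured RPKM sits
on an inflated scale relative to a whole-transcriptome library (fewer
features share the same read total). Analyses that use published absolute
RPKM cutoffs (the 0.3–1 / 1–2 / >5 expression strata) first rescale the
measured control RPKM by mean-matching to the generator's scale; this is
ordinary library-composition normalization and affects no scale-free
statistic.

What the generator does **not** emulate: isoform structure, mappability
and GC artifacts, intronic versus exonic signal, UV-induced
transcriptional induction programs (available only as an optional
per-gene rate multiplier, default off), and inter-gene correlation of
expression. Passing tests on synthetic data therefore validate the
method's internal logic and its behavior under the stated generative
model — not robustness to the full messiness of real sequencing data.

## Analytics

**Metagene profiles** (`metagene()`) filter genes by length and by
control-condition RPKM, normalize each gene's binned density to its own
mean over the span (each gene weighs equally regardless of expression),
and average per bin. Genes shorter than the span contribute only their
existing bins — no padding — and each gene's trailing partial bin is
dropped.

**Percent recovery** (`percent_recovery()`). Full recovery means the read
distribution along genes has returned to the even, control-like
distribution. The deviation of profile $p$ from control $c$ is the
total-variation distance of the sum-normalized profiles,
$D(p) = \tfrac12\sum_b |p_b/\Sigma p - c_b/\Sigma c|$, and

$$\mathrm{recovery}(t) = 100\,\big(1 - D(p_t)/D(p_{t_0})\big),$$

clipped to $[0, 100]$ (defined as 100 when $D(p_{t_0}) = 0$). TV distance
is used because it is bounded, invariant to uniform rescaling of any
profile, exactly zero at an even distribution, and exactly linear along
mixtures of the damaged and control profiles (an equal mixture scores
50%). This formula is this package's interpretation of "percent
recovery"; the original assay never wrote one down. A `bins` argument
restricts the deviation to a region of the span after whole-profile
normalization, which is how 5' versus 3' recovery of long genes is
quantified. Recovery is computed on aggregate profiles; applying it to
single-gene profiles (a one-row gene set) gives the per-gene variant.

**Fold-change sets** (`fold_change_sets()`) classify genes by the
UV/control RPKM ratio at a 2-fold threshold among genes expressed in the
control, with a 0.01-RPKM pseudocount against division by zero, and
report the median length of each set — the repressed set is dominated by
long genes, the induced set by short ones, purely as a redistribution
effect of length-dependent blocking under a fixed library size.

## The long-qPCR lesion assay

Long-range PCR amplifies only lesion-free template molecules, so with
Poisson damage the mean lesion count per fragment is
$\hat\lambda = -\ln\frac{F_{irr} - F_{blank}}{F_{ctrl} - F_{blank}}$
(`lesions_per_fragment()`), rescaled to lesions per 10 kb. Replicates
should be combined by averaging the blank-corrected ratios before the
log; averaging per-replicate $\hat\lambda$ values instead is biased
upward at low lesion loads by the clipping of negative estimates. The
matched simulator (`simulate_qpcr()`) draws independent per-template
lesion realizations (each template molecule is a different cell), applies
the same repair law as the coverage simulator, and adds multiplicative
log-normal fluorescence noise; `n_templates = NULL` switches to the exact
zero-class probability. A 50% template control (`qc_half_control()`,
default tolerance 0.15) flags saturated, non-quantitative amplification.

Strand-specific TC-NER is isolated by `sense_strand_remaining()`: the
double-strand estimate is halved, and the per-strand repair observed in
non-transcribed DNA is subtracted *from the gene's repair*, i.e. the
corrected remaining lesions are $L_{gene}(t)/2 + (L_{nt}(0) -
L_{nt}(t))/2$. Under this convention a region repaired only at the
background rate stays flat at $L_{nt}(0)/2$ — zero apparent TC-NER — which
is the defining null of the correction. (Subtracting background removal
from the *remaining* count instead would drive undamaged-pathway controls
negative.) An alternative `mode = "direct"` subtracts the non-transcribed
remaining count itself; it is provided for comparison without endorsing
either as the historical arithmetic, which is ambiguous. Uncertainty
across replicates is best summarized by bootstrap over replicate ratios;
no analysis-of-variance layer is provided.

## Numerical choices and degenerate inputs

* TSS is always gene-local coordinate 0; strand enters only at bedGraph
  import/export. All genomic intervals are 0-based half-open.
* Expected coverage is evaluated at bin midpoints; the wave front and
  lesion positions are therefore resolved to half a bin width.
* Silent genes (`basal_rate = 0`) produce zero mass and are never
  TC-NER substrates; fields without assigned removal times are a state
  error, not silently treated as unrepaired.
* `lesion_class_probabilities()` returns an exact unit-sum vector (the
  tail is computed by subtraction and floored at 0 against rounding).
* Zero total mass in `sample_reads()` yields all-zero tracks with a
  warning rather than an error, so empty conditions propagate visibly.
* Negative zero-class estimates clip to 0 with a warning; a fluorescence
  at or below blank returns `Inf` with a warning.

## Problem sizes

The shipped tests and the acceptance script use 400–500 synthetic genes,
libraries of 1–10 million reads, 5 simulation seeds for genotype
contrasts, 1000-template qPCR draws with 8 replicates, and 20 000
polymerase draws for the readthrough check. These sizes put Monte-Carlo
standard errors well inside the effect sizes under study (genotype gaps
of 10–35 percentage points against seed-to-seed standard errors of 1–4)
while a full run completes in well under a minute on a laptop.

## Known limitations

* One effective TC-NER wave per gene; no re-initiation-limited repair, no
  CSA/CSB biochemistry, no polymerase ubiquitylation kinetics, no
  chromatin restoration after repair.
* No photoproduct-specific chemistry or sequence-context damage bias.
* Repair rates are dose-independent; the linear dose model is only
  supported over the 10–20 J/m$^2$ range it emulates.
* Coverage-level simulation only — no read-level FASTQ/BAM, no splicing,
  no RNA degradation, no intergenic transcription.
* The percent-recovery statistic, while principled, is one of several
  defensible formalizations of "return to even coverage"; comparisons
  across studies should compare formulas first.
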