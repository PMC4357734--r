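# uvtx

Simulation and analysis of how UVC-induced DNA damage shuts down nascent
RNA synthesis and how synthesis recovers as the damage is repaired.

## The problem

UVC light deposits transcription-blocking photolesions (cyclobutane
pyrimidine dimers and 6-4 photoproducts) at random along the genome. An
elongating RNA polymerase II that meets one arrests; in the model
implemented here it never resumes, so all downstream synthesis must come
from fresh initiations after the lesion is repaired. Two repair pathways
race to clear the template: transcription-coupled nucleotide excision
repair (TC-NER), which sweeps the transcribed strand of active genes from
the 5' end as a wave, and global-genomic repair (GG-NER), which removes
lesions anywhere at a constant per-lesion rate. The observable
consequences, which this package simulates and quantifies, are:

* **length-dependent inhibition** — a gene of length *L* stays fully
  active with probability `exp(-dL)` at per-bp transcribed-strand lesion
  density *d* (one lesion per 14 kb at 10 J/m², linear in dose), so long
  genes lose synthesis first and a Poisson lesion-class calculation
  predicts the fraction of cells with 0, 1, 2, ... lesions per gene;
* **a 5' to 3' recovery wave** — nascent-RNA coverage after UV shows a 5'
  pile-up that advances toward the 3' end as repair proceeds, at rates
  that depend on repair genotype (wild type, GG-NER-deficient XP-C,
  TC-NER-deficient CS-B);
* **strand-specific repair kinetics** measurable by long-range qPCR: only
  lesion-free fragments amplify, so lesions per fragment are estimated by
  the zero-class formula `-ln((F_irr - F_blank)/(F_ctrl - F_blank))`,
  halved to per-strand counts and corrected for background repair seen in
  non-transcribed DNA.

The package is aimed at people modeling DNA-damage/transcription
interplay or benchmarking recovery statistics for nascent-RNA
(Bru-seq-like) coverage data: it ships the mechanistic coverage
simulator, the metagene / percent-recovery / fold-change analytics, and
the qPCR estimator with a matched fluorescence simulator, all testable
end to end.

## Worked example

```r
library(uvtx)
genes <- generate_gene_set(400, seed = 1)            # synthetic annotation
cfg <- simulation_config(doses = c(0, 10), timepoints = c(0, 6, 24),
                         genotypes = "XPC", seed = 42)
ex <- simulate_experiment(genes, cfg)                # coverage + RPKM per condition
ctrl_rpkm <- ex$conditions$control$rpkm

fc <- fold_change_sets(ex$conditions$d10_t0_XPC$rpkm, ctrl_rpkm, genes)
cat(sprintf("repressed: %d genes, median length %.1f kbp\n",
            length(fc$repressed), fc$median_length_repressed / 1000))
cat(sprintf("induced:   %d genes, median length %.1f kbp\n",
            length(fc$induced), fc$median_length_induced / 1000))

mg <- function(cond) metagene(ex$conditions[[cond]]$tracks, genes, ctrl_rpkm,
                              min_length = 1e5, min_rpkm = 0.5, span = 2e5)
pc <- mg("control"); p0 <- mg("d10_t0_XPC")
for (t in c(6, 24)) {
  r <- percent_recovery(mg(sprintf("d10_t%d_XPC", t)), pc, p0)
  cat(sprintf("XP-C recovery at %2d h: %.1f%% (%d genes > 100 kbp)\n",
              t, r$percent_recovery, r$n_genes))
}
p <- lesion_class_probabilities(10800, lesion_density(10))
cat(sprintf("10.8 kbp gene at 10 J/m2: %.0f%% / %.0f%% / %.0f%% / %.0f%% with 0/1/2/3+ lesions\n",
            100 * p[1], 100 * p[2], 100 * p[3], 100 * p[4]))
```

```
repressed: 47 genes, median length 145.2 kbp
induced:   111 genes, median length 15.1 kbp
XP-C recovery at  6 h: 19.8% (43 genes > 100 kbp)
XP-C recovery at 24 h: 77.8% (43 genes > 100 kbp)
10.8 kbp gene at 10 J/m2: 46% / 36% / 14% / 4% with 0/1/2/3+ lesions
```

Read it as: two hours-scale facts and two desk calculations. Genes whose
relative synthesis drops more than 2-fold immediately after 10 J/m² are
an order of magnitude longer (median 145 kbp) than genes whose relative
synthesis rises (15 kbp) — pure length-dependent blocking plus a fixed
sequencing budget. An XP-C (TC-NER-only) cell line recovers long-gene
synthesis to ~20% by 6 h and ~78% by 24 h, the 24 h shortfall being the
slow 3'-end repair that GG-NER would normally finish. And a 10.8 kbp gene
at this dose leaves about 46% of cells lesion-free, with 36/14/4%
carrying one/two/three-or-more lesions.

The per-condition outputs are ordinary bedGraph + TSV files when
`simulate_experiment(..., out_dir = ...)` is given a directory, and
`inst/cli/uvtx.R` wraps the simulate / metagene / recovery / foldsets /
qpcr steps for shell use.

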