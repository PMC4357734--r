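# single-gene fixture: one transcription unit on a toy chromosome
toy_gene <- function(id = "g1", len = 10000, strand = "+", rate = 1,
                     start = 1000, chrom = "chr1") {
  gene_set(data.frame(gene_id = id, chrom = chrom, start = start,
                      end = start + len, strand = strand,
                      basal_rate = rate))
}

# small deterministic multi-gene set with controlled lengths/rates
toy_gene_set <- function(lens = c(5000, 20000, 150000),
                         rates = c(2, 1, 1), strands = NULL) {
  n <- length(lens)
  if (is.null(strands)) strands <- rep(c("+", "-"), length.out = n)
  start <- cumsum(c(10000, head(lens, -1) + 10000))
  gene_set(data.frame(gene_id = paste0("g", seq_len(n)), chrom = "chrT",
                      start = start, end = start + lens, strand = strands,
                      basal_rate = rates))
}

# default small simulated experiment shared by analysis tests
run_small_experiment <- function(n_genes = 300, seed = 5,
                                 genotypes = "WT",
                                 timepoints = c(0, 6, 24),
                                 reads = 1e6) {
  genes <- generate_gene_set(n_genes, seed = seed)
  cfg <- simulation_config(doses = c(0, 10), timepoints = timepoints,
                           genotypes = genotypes,
                           reads_per_condition = reads, seed = seed + 50)
  list(genes = genes, cfg = cfg,
       ex = simulate_experiment(genes, cfg))
}

# replicate-averaged zero-class estimate from simulated qPCR measurements:
# ratios are averaged before the log, as with replicate fluorescence means
qpcr_lambda <- function(field, gene, amplicon, t, params, n_rep = 8,
                        n_templates = 1000, noise_cv = 0.1, seed0 = 1) {
  ms <- lapply(seq_len(n_rep), function(i)
    simulate_qpcr(field, gene, amplicon, t, params,
                  n_templates = n_templates, noise_cv = noise_cv,
                  seed = seed0 + i))
  f_irr <- mean(vapply(ms, `[[`, numeric(1), "f_irradiated"))
  f_ctrl <- mean(vapply(ms, `[[`, numeric(1), "f_control"))
  lesions_per_fragment(f_irr, f_ctrl, ms[[1]]$f_blank)
}
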