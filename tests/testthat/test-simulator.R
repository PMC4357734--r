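cfg0 <- simulation_config(seed = 1)

test_that("undamaged genes are covered evenly across full bins", {
  g <- toy_gene(len = 20000, rate = 2)  # shorter than one window of travel
  f <- assign_removal_times(place_lesions(g, 0, seed = 1), g,
                            genotype_presets("NONE"), seed = 1)
  mass <- simulate_bru_window(g, f, 0, cfg0)
  expect_length(mass, 40)
  expect_equal(var(mass), 0)
  # rate (per hour) x window (h) x bin width
  expect_equal(mass[1], 2 * 60 * 0.5 * 500)
  # partial trailing bin scales with its width
  g2 <- toy_gene(len = 1250, rate = 1)
  f2 <- assign_removal_times(place_lesions(g2, 0, seed = 1), g2,
                             genotype_presets("NONE"), seed = 1)
  m2 <- simulate_bru_window(g2, f2, 0, cfg0)
  expect_equal(m2[3] / m2[1], 0.5)
})

test_that("silent genes and unassigned fields are handled", {
  g <- toy_gene(rate = 0)
  f <- assign_removal_times(place_lesions(g, 1e-4, seed = 1), g,
                            genotype_presets("NONE"), seed = 1)
  expect_equal(sum(simulate_bru_window(g, f, 0, cfg0)), 0)
  expect_error(simulate_bru_window(toy_gene(), place_lesions(toy_gene(), 0),
                                   0, cfg0), "not assigned")
})

test_that("without repair, suppression is identical at 0 and 24 hours", {
  g <- toy_gene(len = 150000, rate = 1)
  f <- assign_removal_times(place_lesions(g, 1 / 14000, seed = 9), g,
                            genotype_presets("NONE"), seed = 1)
  expect_equal(simulate_bru_window(g, f, 24, cfg0),
               simulate_bru_window(g, f, 0, cfg0))
})

test_that("polymerase readthrough matches the closed form", {
  d <- 1 / 14000
  far <- simulate_polymerases(1e5, d, n = 20000, seed = 13)
  for (x in c(7000, 14000, 50000)) {
    p <- exp(-d * x)
    expect_lt(abs(mean(far >= x) - p), 3 * sqrt(p * (1 - p) / 20000))
  }
  # and the binned expected mass decays accordingly at t = 0: averaged over
  # lesion realizations, bin mass ~ readthrough at the bin midpoint
  g <- toy_gene(len = 50000, rate = 1)
  acc <- 0
  nrep <- 300
  for (s in seq_len(nrep)) {
    f <- assign_removal_times(place_lesions(g, d, seed = 200 + s), g,
                              genotype_presets("NONE"), seed = 1)
    acc <- acc + simulate_bru_window(g, f, 0, cfg0) / nrep
  }
  mids <- (seq_len(100) - 0.5) * 500
  expected <- 1 * 60 * 0.5 * 500 * expected_readthrough(mids, d)
  expect_lt(max(abs(acc - expected) / expected[1]), 0.05)
})

test_that("read sampling conserves totals and converges to mass proportions", {
  masses <- list(a = c(0, 10, 0), b = c(5, 5, 20, 10))
  tr <- sample_reads(masses, 1000, 500, seed = 3)
  expect_equal(sum(tr$a$counts) + sum(tr$b$counts), 1000)
  expect_equal(tr$a$counts[c(1, 3)], c(0, 0))
  expect_identical(sample_reads(masses, 1000, 500, seed = 3)$b$counts,
                   tr$b$counts)
  # all mass in one bin -> all reads there
  one <- sample_reads(list(a = c(0, 7)), 500, 500, seed = 1)
  expect_equal(one$a$counts, c(0, 500))
  # law of large numbers at 1e6 reads, 1% tolerance on proportions
  big <- sample_reads(masses, 1e6, 500, seed = 4)
  prop <- c(big$a$counts, big$b$counts) / 1e6
  expect_lt(max(abs(prop - unlist(masses) / 50)), 0.01)
  expect_warning(sample_reads(list(a = c(0, 0)), 10, 500), "zero")
})

test_that("simulated experiments are reproducible and complete", {
  genes <- generate_gene_set(30, seed = 2)
  cfg <- simulation_config(doses = c(0, 10), timepoints = c(0, 6),
                           genotypes = "WT", reads_per_condition = 1e5,
                           seed = 8)
  ex1 <- simulate_experiment(genes, cfg)
  ex2 <- simulate_experiment(genes, cfg)
  expect_identical(ex1$conditions$d10_t6_WT$rpkm,
                   ex2$conditions$d10_t6_WT$rpkm)
  expect_setequal(names(ex1$conditions),
                  c("control", "d10_t0_WT", "d10_t6_WT"))
  for (cond in ex1$conditions)
    expect_equal(sum(vapply(cond$tracks, function(tr) sum(tr$counts),
                            numeric(1))), 1e5)
  # bedGraph and RPKM outputs are written when requested
  out <- withr::local_tempdir()
  simulate_experiment(genes, cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "d10_t0_WT.bedGraph")))
  expect_true(file.exists(file.path(out, "control.rpkm.tsv")))
  expect_true(file.exists(file.path(out, "manifest.yaml")))
})

test_that("dose suppresses long-gene bodies monotonically", {
  genes <- generate_gene_set(150, seed = 6)
  cfg <- simulation_config(doses = c(0, 10, 20), timepoints = 0,
                           genotypes = "WT", reads_per_condition = 5e5,
                           seed = 4)
  ex <- simulate_experiment(genes, cfg)
  long_expr <- genes$gene_id[gene_length(genes) > 20000 &
                             genes$basal_rate > 0.2]
  body_to_5p <- function(cond) {
    r <- vapply(long_expr, function(id) {
      ct <- ex$conditions[[cond]]$tracks[[id]]$counts
      nb <- length(ct)
      body <- mean(ct[seq(max(2, ceiling(nb / 2)), nb)])
      head5 <- mean(ct[1:2])
      if (head5 <= 0) NA_real_ else body / head5
    }, numeric(1))
    mean(r, na.rm = TRUE)
  }
  ratios <- c(body_to_5p("control"), body_to_5p("d10_t0_WT"),
              body_to_5p("d20_t0_WT"))
  expect_false(is.unsorted(rev(ratios)))
})

test_that("restart-incompetent genes stay suppressed while others recover", {
  genes <- generate_gene_set(40, seed = 12)
  long_ids <- genes$gene_id[gene_length(genes) > 50000 &
                            genes$basal_rate > 0.3]
  stuck <- long_ids[1]
  rc <- stats::setNames(rep(TRUE, nrow(genes)), genes$gene_id)
  rc[stuck] <- FALSE
  cfg <- simulation_config(doses = c(0, 10), timepoints = c(0, 24),
                           genotypes = "WT", reads_per_condition = 5e5,
                           restart_competence = rc, seed = 3)
  ex <- simulate_experiment(genes, cfg)
  rel <- function(cond, id) {
    ctrl <- ex$conditions$control$rpkm
    uv <- ex$conditions[[cond]]$rpkm
    uv$rpkm[uv$gene_id == id] / ctrl$rpkm[ctrl$gene_id == id]
  }
  others <- setdiff(long_ids, stuck)
  expect_lt(rel("d10_t24_WT", stuck), 0.5)
  expect_gt(mean(vapply(others, function(id) rel("d10_t24_WT", id),
                        numeric(1))), 0.8)
})
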