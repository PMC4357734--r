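test_that("rpkm follows the reads-per-kb-per-million definition", {
  g <- toy_gene(len = 10000)
  tr <- coverage_track("g1", c(400, 300, 300), 4000, 1e6)
  expect_equal(rpkm(tr, g), 100)
  expect_equal(rpkm(coverage_track("g1", c(0, 0, 0), 4000, 1e6), g), 0)
  tr2 <- coverage_track("g1", c(400, 300, 300), 4000, 2e6)
  expect_equal(rpkm(tr2, g), 50)  # doubling library size halves RPKM
})

test_that("metagene normalizes genes to their own mean", {
  genes <- toy_gene_set(lens = c(4000, 8000), rates = c(1, 1))
  tracks <- list(g1 = coverage_track("g1", rep(25, 8), 500, 1e4),
                 g2 = coverage_track("g2", rep(80, 16), 500, 1e4))
  prof <- metagene(tracks, genes, span = 4000)
  expect_equal(prof$values, rep(1, 8))  # uniform tracks -> flat at 1.0
  expect_equal(prof$n_genes, 2)
  # a single gene with all reads in bin 0 -> delta profile
  d <- metagene(list(g1 = coverage_track("g1", c(80, 0, 0, 0, 0, 0, 0, 0),
                                         500, 1e4)),
                genes[1, ], span = 4000)
  expect_equal(d$values, c(8, rep(0, 7)))
  # genes shorter than the span contribute only their own bins
  p2 <- metagene(tracks, genes, span = 8000)
  expect_equal(p2$n_contributing[1], 2)
  expect_equal(p2$n_contributing[16], 1)
  expect_error(metagene(tracks, genes, min_length = 1e6), "no genes pass")
})

test_that("unirradiated simulated metagenes are flat", {
  # deep library and a span every contributing gene covers in full, so
  # bin noise is pure multinomial sampling
  sm <- run_small_experiment(n_genes = 150, seed = 31, timepoints = 0,
                             reads = 1e7)
  r_ctrl <- sm$ex$conditions$control$rpkm
  prof <- metagene(sm$ex$conditions$control$tracks, sm$genes, r_ctrl,
                   min_length = 30000, min_rpkm = 20, span = 3e4)
  rms <- sqrt(mean((prof$values - 1)^2))
  expect_lt(rms, 0.02)
})

test_that("fold-change sets classify by ratio and report median lengths", {
  genes <- toy_gene_set(lens = c(5000, 200000, 30000), rates = c(1, 1, 1))
  ctrl <- data.frame(gene_id = c("g1", "g2", "g3"), rpkm = c(2, 5, 1))
  # identical tables -> both sets empty
  fc0 <- fold_change_sets(ctrl, ctrl, genes)
  expect_length(fc0$induced, 0)
  expect_length(fc0$repressed, 0)
  uv <- data.frame(gene_id = c("g1", "g2", "g3"), rpkm = c(6, 2, 1))
  fc <- fold_change_sets(uv, ctrl, genes)
  expect_equal(fc$induced, "g1")
  expect_equal(fc$repressed, "g2")
  expect_equal(fc$median_length_induced, 5000)
  expect_equal(fc$median_length_repressed, 200000)
  # genes below the control expression floor are excluded
  fc2 <- fold_change_sets(uv, ctrl, genes, min_rpkm = 3)
  expect_equal(fc2$ratios$gene_id, "g2")
  expect_error(fold_change_sets(uv, data.frame(gene_id = "zz", rpkm = 1),
                                genes), "no gene ids")
})

make_profile <- function(values, bw = 500) {
  structure(list(values = values, bin_width = bw, span = bw * length(values),
                 n_genes = 10, condition = list(), gene_filter = ""),
            class = "metagene_profile")
}

test_that("percent recovery interpolates between damaged and control", {
  ctrl <- make_profile(rep(1, 10))
  t0 <- make_profile(c(4, 3, 1, 0.5, rep(0.2, 6)))
  expect_equal(percent_recovery(ctrl, ctrl, t0)$percent_recovery, 100)
  expect_equal(percent_recovery(t0, ctrl, t0)$percent_recovery, 0)
  # equal mixture of normalized profiles recovers exactly half
  mix <- make_profile(0.5 * t0$values / sum(t0$values) +
                      0.5 * ctrl$values / sum(ctrl$values))
  expect_equal(percent_recovery(mix, ctrl, t0)$percent_recovery, 50)
  # invariant to uniform rescaling of any input
  expect_equal(
    percent_recovery(make_profile(7 * mix$values), make_profile(3 * ctrl$values),
                     make_profile(0.1 * t0$values))$percent_recovery, 50)
  # degenerate: undamaged baseline defines recovery as complete
  expect_equal(percent_recovery(ctrl, ctrl, ctrl)$percent_recovery, 100)
  expect_error(percent_recovery(make_profile(rep(1, 5)), ctrl, t0), "share")
})

test_that("recovery can be restricted to a region of the span", {
  ctrl <- make_profile(rep(1, 10))
  t0 <- make_profile(c(4, 3, rep(0.1, 8)))
  part <- make_profile(c(1.2, 1.1, 1, 1, 1, 0.1, 0.1, 0.1, 0.1, 0.1))
  r5 <- percent_recovery(part, ctrl, t0, bins = 1:2)$percent_recovery
  r3 <- percent_recovery(part, ctrl, t0, bins = 9:10)$percent_recovery
  expect_gt(r5, 60)
  expect_lt(r3, 30)
})

test_that("recovery increases with time in wild-type simulations", {
  sm <- run_small_experiment(n_genes = 250, seed = 17)
  r_ctrl <- sm$ex$conditions$control$rpkm
  mg <- function(cond) metagene(sm$ex$conditions[[cond]]$tracks, sm$genes,
                                r_ctrl, min_length = 5e4, min_rpkm = 0.5,
                                span = 1.5e5)
  pc <- mg("control"); p0 <- mg("d10_t0_WT")
  recs <- c(0,
            percent_recovery(mg("d10_t6_WT"), pc, p0)$percent_recovery,
            percent_recovery(mg("d10_t24_WT"), pc, p0)$percent_recovery)
  expect_false(is.unsorted(recs))
  expect_gt(recs[3], 50)
})

test_that("expression bins partition by control RPKM and preserve gaps", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    rpkm = c(0.5, 1.5, 3, 7, 0.1))
  bins <- expression_bins(tab)
  expect_equal(bins$low, "a")
  expect_equal(bins$medium, "b")
  expect_equal(bins$high, "d")
  expect_false("c" %in% unlist(bins))  # the 2-5 RPKM gap is preserved
  expect_false("e" %in% unlist(bins))
  expect_error(expression_bins(tab, cutoffs = list(a = c(1, 0.5))),
               "increasing")
  expect_error(expression_bins(tab, cutoffs = list(a = c(0.3, 2),
                                                   b = c(1, 5))),
               "non-overlapping")
})
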