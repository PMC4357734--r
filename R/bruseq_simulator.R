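#' Simulation configuration
#'
#' Experimental grid and kinetic parameters for the nascent-RNA labeling
#' simulator: cells are irradiated at time 0, allowed to recover for each
#' `timepoints` entry, then labeled with bromouridine for `label_window`
#' minutes; only RNA synthesized inside the window is counted.
#'
#' @param doses UVC doses in J/m2; dose 0 (unirradiated control) is always
#'   added if absent.
#' @param timepoints recovery times in hours before labeling.
#' @param genotypes repair genotype labels (see [genotype_presets()]).
#' @param label_window labeling window in minutes (default 30).
#' @param elongation_speed polymerase elongation speed in bp per minute
#'   (default 1500, so a 30-min window covers at most 45 kbp of travel).
#' @param reads_per_condition sequencing depth per condition.
#' @param bin_width gene-local bin width in bp (default 500).
#' @param tc_wave_speed,gg_rate repair kinetics passed to
#'   [genotype_presets()].
#' @param restart_competence optional named logical vector; genes flagged
#'   `FALSE` never resume synthesis past a lesion even after repair
#'   (emulates genes whose transcription does not recover despite normal
#'   repair). Default: all genes restart-competent.
#' @param seed master seed; the whole experiment is reproducible from
#'   (config, seed).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(doses = c(0, 10), timepoints = c(0, 6, 24),
                              genotypes = "WT", label_window = 30,
                              elongation_speed = 1500,
                              reads_per_condition = 2e6, bin_width = 500,
                              tc_wave_speed = 6000, gg_rate = 0.08,
                              restart_competence = NULL, seed = 1L) {
  if (label_window <= 0) stop("label_window must be > 0")
  if (elongation_speed <= 0) stop("elongation_speed must be > 0")
  if (reads_per_condition < 1) stop("reads_per_condition must be >= 1")
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (any(doses < 0) || any(timepoints < 0)) stop("doses and timepoints must be >= 0")
  structure(list(doses = sort(unique(c(0, doses))), timepoints = timepoints,
                 genotypes = genotypes, label_window = label_window,
                 elongation_speed = elongation_speed,
                 reads_per_condition = reads_per_condition,
                 bin_width = bin_width, tc_wave_speed = tc_wave_speed,
                 gg_rate = gg_rate, restart_competence = restart_competence,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Read a simulation configuration from YAML
#' @param path YAML file whose keys match the arguments of
#'   [simulation_config()].
#' @return A [simulation_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(simulation_config)))
  do.call(simulation_config, vals[keep])
}

# Initiation-time measure (hours) for which a polymerase covers position x
# inside the labeling window [t0, t0 + W], given transcribed-strand lesions
# at `pos` (sorted) with removal times `rt`.
#
# A polymerase initiating at time s covers x during the window iff it
# arrives there inside the window, s in A = [t0 - x/v, t0 + W - x/v), and
# it was not arrested upstream: lesion j (pos_j <= x) arrests every
# polymerase arriving before its removal, i.e. s < rt_j - pos_j/v. So the
# admissible initiation times are s >= S(x) = max_j (rt_j - pos_j/v), the
# time by which the slowest-repaired upstream lesion has cleared. All
# coverage is carried by polymerases that traversed the surviving lesion
# field from the TSS (synthesis restarts from the beginning of genes).
window_measure <- function(xs, pos, rt, v, t0, W) {
  if (length(pos) == 0) return(rep(W, length(xs)))
  thr <- cummax(rt - pos / v)
  n_up <- findInterval(xs, pos)
  S <- c(-Inf, thr)[n_up + 1]
  pmax(0, (t0 + W - xs / v) - pmax(t0 - xs / v, S))
}

#' Expected labeled nascent-RNA mass per bin for one labeling window
#'
#' Polymerases initiate at the TSS as a Poisson process at the gene's basal
#' rate (including a pre-window steady state: polymerases already in
#' transit when labeling starts), travel at the configured elongation
#' speed, and arrest permanently at the first transcribed-strand lesion
#' still present when they arrive -- no resumption and no translesion
#' bypass, so synthesis downstream of an arrest can only come from newly
#' initiated polymerases after repair. Only bases polymerized inside the
#' window `[t_start, t_start + label_window]` count as labeled; an
#' already-arrested polymerase contributes nothing. The expectation over
#' the initiation process is computed in closed form conditional on the
#' lesion realization, evaluated at bin midpoints.
#'
#' @param gene single-row [gene_set()] slice.
#' @param field a [lesion_field()] for the gene with removal times
#'   assigned.
#' @param t_start hours after irradiation at which labeling starts.
#' @param config a [simulation_config()].
#' @param restart_competent if `FALSE`, lesions block polymerases forever
#'   even after repair (synthesis never recovers past the first lesion).
#' @return numeric vector of expected labeled mass per bin (arbitrary
#'   units, proportional to expected read counts).
#' @export
simulate_bru_window <- function(gene, field, t_start, config,
                                restart_competent = TRUE) {
  if (!isTRUE(attr(field, "removal_assigned")))
    stop("removal times not assigned; call assign_removal_times() first")
  if (!identical(field$gene_id, gene$gene_id))
    stop("lesion field belongs to a different gene")
  len <- gene$end - gene$start
  bw <- config$bin_width
  nb <- n_bins(len, bw)
  if (gene$basal_rate <= 0) return(numeric(nb))
  v <- config$elongation_speed * 60        # bp per hour
  W <- config$label_window / 60            # hours
  bin_start <- (seq_len(nb) - 1) * bw
  bin_end <- pmin(bin_start + bw, len)
  mids <- (bin_start + bin_end) / 2
  rt <- field$ts$removal_time
  if (!restart_competent) rt <- rep(Inf, length(rt))
  meas <- window_measure(mids, field$ts$position, rt, v, t_start, W)
  rate_h <- gene$basal_rate * 60
  rate_h * meas * (bin_end - bin_start)
}

#' Sample sequencing reads over expected coverage
#'
#' Allocates `reads_per_condition` reads multinomially across all bins of
#' all genes, proportional to expected labeled mass, emulating fixed-depth
#' sequencing of a pooled library.
#'
#' @param masses named list (gene id -> per-bin expected mass vector).
#' @param reads_per_condition total reads to allocate.
#' @param bin_width bin width in bp of the mass vectors.
#' @param condition condition annotation stored on each track.
#' @param seed integer seed.
#' @return named list of [coverage_track()]; counts over all genes sum to
#'   `reads_per_condition` exactly (all zero, with a warning, if total
#'   mass is zero).
#' @export
sample_reads <- function(masses, reads_per_condition, bin_width,
                         condition = list(dose = 0, time = 0, genotype = "WT"),
                         seed = 1L) {
  lens <- lengths(masses)
  flat <- unlist(masses, use.names = FALSE)
  total <- sum(flat)
  if (total <= 0) {
    warning("total expected mass is zero; returning all-zero tracks")
    counts <- rep(0, length(flat))
  } else {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    counts <- as.numeric(stats::rmultinom(1, reads_per_condition, flat / total))
  }
  split_idx <- rep(seq_along(masses), lens)
  out <- lapply(seq_along(masses), function(i) {
    coverage_track(names(masses)[i], counts[split_idx == i], bin_width,
                   reads_per_condition, condition)
  })
  names(out) <- names(masses)
  out
}

#' Simulate a full Bru-seq-like experiment
#'
#' Runs the irradiation / recovery / labeling grid of the configuration:
#' one lesion realization per (gene, dose), reused across genotypes and
#' timepoints of that dose (paired design, with shared GG-NER removal
#' draws so pathway comparisons are pathwise); an unirradiated control
#' (dose 0, labeled `"control"`) is always included. Per condition the
#' result holds coverage tracks and a per-gene RPKM table
#' (`counts * 1e9 / (length * library_size)`).
#'
#' @param genes a [gene_set()].
#' @param config a [simulation_config()].
#' @param out_dir optional directory; if given, writes one bedGraph and
#'   one RPKM TSV per condition plus a `manifest.yaml` with the full
#'   configuration and seeds.
#' @return A `bru_experiment`: list with `conditions` (named list of
#'   `condition`, `tracks`, `rpkm`), `genes`, `config`.
#' @export
simulate_experiment <- function(genes, config, out_dir = NULL) {
  stopifnot(inherits(genes, "gene_set"))
  base_seed <- config$seed %% 100000L
  restart_ok <- function(id) {
    rc <- config$restart_competence
    if (is.null(rc) || is.na(rc[id])) TRUE else isTRUE(rc[[id]])
  }
  grid <- expand.grid(genotype = config$genotypes,
                      time = config$timepoints,
                      dose = setdiff(config$doses, 0),
                      stringsAsFactors = FALSE)
  labels <- c("control",
              sprintf("d%g_t%g_%s", grid$dose, grid$time, grid$genotype))
  if (anyDuplicated(labels)) stop("duplicate condition labels in config")

  conditions <- list()
  # shared per-(gene, dose) lesion realizations
  dose_idx <- seq_along(config$doses)
  fields <- list()
  for (di in dose_idx) {
    d <- config$doses[di]
    dens <- lesion_density(d)
    fields[[as.character(d)]] <- lapply(seq_len(nrow(genes)), function(gi) {
      place_lesions(genes[gi, ], dens,
                    seed = base_seed + 104729L * di + gi)
    })
  }

  run_condition <- function(label, dose, time, genotype, params, cseed) {
    di <- match(dose, config$doses)
    flds <- fields[[as.character(dose)]]
    masses <- lapply(seq_len(nrow(genes)), function(gi) {
      g <- genes[gi, ]
      f <- assign_removal_times(flds[[gi]], g, params,
                                seed = base_seed + 104729L * di + gi + 31L)
      simulate_bru_window(g, f, time, config,
                          restart_competent = restart_ok(g$gene_id))
    })
    names(masses) <- genes$gene_id
    cond <- list(dose = dose, time = time, genotype = genotype)
    tracks <- sample_reads(masses, config$reads_per_condition,
                           config$bin_width, cond, seed = cseed)
    counts <- vapply(tracks, function(tr) sum(tr$counts), numeric(1))
    rpkm <- data.frame(gene_id = genes$gene_id,
                       rpkm = counts * 1e9 /
                         (gene_length(genes) * config$reads_per_condition))
    list(condition = cond, tracks = tracks, rpkm = rpkm)
  }

  conditions[["control"]] <- run_condition(
    "control", 0, 0, "control", genotype_presets("NONE"),
    cseed = base_seed + 900001L)
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    params <- genotype_presets(g$genotype, config$tc_wave_speed,
                               config$gg_rate)
    conditions[[labels[k + 1]]] <- run_condition(
      labels[k + 1], g$dose, g$time, g$genotype,
      params, cseed = base_seed + 900001L + 37L * k)
  }

  out <- structure(list(conditions = conditions, genes = genes,
                        config = config), class = "bru_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (lab in names(conditions)) {
      write_coverage(conditions[[lab]]$tracks, genes,
                     file.path(out_dir, paste0(lab, ".bedGraph")))
      write_rpkm_table(conditions[[lab]]$rpkm,
                       file.path(out_dir, paste0(lab, ".rpkm.tsv")))
    }
    yaml::write_yaml(c(unclass(config), list(conditions = names(conditions))),
                     file.path(out_dir, "manifest.yaml"))
  }
  out
}

#' Monte-Carlo polymerase readthrough simulation
#'
#' Brute-force check of the target-theory readthrough law: each of `n`
#' polymerases faces an independent Poisson lesion realization on the
#' transcribed strand (no repair, immediately after irradiation) and runs
#' from the TSS to the first lesion. The fraction whose furthest position
#' is at least `x` should match [expected_readthrough()] `= exp(-density * x)`.
#'
#' @param gene_length bp.
#' @param density transcribed-strand lesions per bp.
#' @param n number of polymerases (independent lesion realizations).
#' @param seed integer seed.
#' @return numeric vector of furthest positions reached (capped at
#'   `gene_length`).
#' @export
simulate_polymerases <- function(gene_length, density, n, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  counts <- stats::rpois(n, density * gene_length)
  furthest <- rep(gene_length, n)
  has <- counts > 0
  if (any(has)) {
    pos <- stats::runif(sum(counts[has]), 0, gene_length)
    first <- vapply(split(pos, rep(which(has), counts[has])), min, numeric(1))
    furthest[as.integer(names(first))] <- first
  }
  furthest
}
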