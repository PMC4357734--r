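#' Lesions per fragment from long-qPCR fluorescence
#'
#' Long-range PCR only amplifies template molecules free of
#' transcription-blocking lesions, so under Poisson-distributed damage the
#' mean lesion count per fragment is the negative natural log of the
#' blank-corrected amplification ratio:
#' `-ln((f_irr - f_blank) / (f_ctrl - f_blank))` (zero-class estimator).
#' Negative estimates (ratio > 1, sampling noise) are clipped to 0 with a
#' warning; `f_irr <= f_blank` (no amplification at all) yields `Inf` with
#' a warning.
#'
#' @param f_irr,f_ctrl,f_blank fluorescence of the irradiated sample, the
#'   unirradiated control and the no-template blank; vectorized.
#' @return lesions per fragment (>= 0, possibly `Inf`).
#' @export
lesions_per_fragment <- function(f_irr, f_ctrl, f_blank = 0) {
  if (any(f_ctrl <= f_blank)) stop("f_ctrl must exceed f_blank")
  ratio <- (f_irr - f_blank) / (f_ctrl - f_blank)
  no_amp <- ratio <= 0
  out <- rep(Inf, length(ratio))
  out[!no_amp] <- -log(ratio[!no_amp])
  if (any(no_amp))
    warning("sample(s) with no amplification (f_irr <= f_blank); returning Inf")
  if (any(out < 0)) {
    warning("negative lesion estimate(s) clipped to 0")
    out[out < 0] <- 0
  }
  out
}

#' Rescale a per-fragment lesion count to lesions per 10 kb
#' @param lesions_per_fragment lesions per fragment.
#' @param fragment_length fragment length in bp (> 0).
#' @return `lesions_per_fragment * 10000 / fragment_length`.
#' @export
lesions_per_10kb <- function(lesions_per_fragment, fragment_length) {
  if (any(fragment_length <= 0)) stop("fragment_length must be > 0")
  lesions_per_fragment * 10000 / fragment_length
}

#' Sense-strand remaining lesions corrected for background repair
#'
#' The double-stranded per-fragment estimate is halved (sense and
#' antisense strands carry damage equally) and the per-strand repair
#' observed in non-transcribed DNA over the same interval is subtracted
#' from the gene's repair, isolating transcription-coupled repair of the
#' sense strand. Expressed as remaining lesions that is
#' `L_gene_t / 2 + (L_nt_0 - L_nt_t) / 2`: a region repaired only at the
#' background rate stays constant at `L_nt_0 / 2` (no apparent TC-NER).
#' The alternative reading `mode = "direct"` subtracts the non-transcribed
#' remaining lesions themselves (`L_gene_t / 2 - L_nt_t / 2`, clipped
#' at 0).
#'
#' @param l_gene_t double-strand lesions in the gene fragment at time t
#'   (per 10 kb or per fragment; all inputs on the same scale).
#' @param l_nt_t,l_nt_0 lesions in the non-transcribed reference region at
#'   time t and time 0.
#' @param mode `"background_repair"` (default) or `"direct"`.
#' @param noise_tol warn when `l_nt_t` exceeds `l_nt_0` by more than this
#'   (apparent negative background repair).
#' @return corrected per-strand remaining lesions (>= 0).
#' @export
sense_strand_remaining <- function(l_gene_t, l_nt_t, l_nt_0,
                                   mode = c("background_repair", "direct"),
                                   noise_tol = 0.05) {
  mode <- match.arg(mode)
  if (any(c(l_gene_t, l_nt_t, l_nt_0) < 0)) stop("inputs must be >= 0")
  if (any(l_nt_t > l_nt_0 + noise_tol))
    warning("non-transcribed lesions increased over time beyond tolerance")
  out <- if (mode == "background_repair")
    l_gene_t / 2 + (l_nt_0 - l_nt_t) / 2
  else l_gene_t / 2 - l_nt_t / 2
  pmax(0, out)
}

#' QC on the 50% DNA control
#'
#' Quantitative amplification requires that halving the template halves
#' the signal; a half-input control far from 50% of the full-input signal
#' flags saturated, non-quantitative PCR.
#'
#' @param f_half,f_full blank-corrected fluorescence at half and full
#'   template input.
#' @param tolerance allowed absolute deviation of `f_half/f_full` from 0.5
#'   (default 0.15).
#' @return `TRUE` (pass) or `FALSE`.
#' @export
qc_half_control <- function(f_half, f_full, tolerance = 0.15) {
  if (any(f_full <= 0)) stop("f_full must be > 0")
  abs(f_half / f_full - 0.5) <= tolerance
}

#' Simulate a long-qPCR measurement on damaged DNA
#'
#' Each template molecule comes from an independent cell, so templates
#' carry independent Poisson lesion realizations at the field's per-strand
#' density over the amplicon (both strands pooled: a lesion on either
#' strand blocks the long-range polymerase). Removal times follow the
#' repair genotype: a TC-NER wave from the TSS on the transcribed strand
#' of expressed genes plus exponential GG-NER on both strands. Expected
#' fluorescence is proportional to the fraction of templates with zero
#' unrepaired lesions at time `t`, estimated from `n_templates` draws
#' (or computed exactly when `n_templates = NULL`), with multiplicative
#' log-normal noise of coefficient of variation `noise_cv`.
#'
#' @param field a [lesion_field()] supplying the lesion density.
#' @param gene the gene carrying the amplicon (single-row [gene_set()]
#'   slice); use `basal_rate = 0` genes for non-transcribed reference
#'   regions.
#' @param amplicon `c(start, end)` in gene-local bp (within the gene).
#' @param t hours after irradiation.
#' @param params a [repair_params()].
#' @param n_templates template draws (default 1000; `NULL` = exact
#'   zero-class probability).
#' @param noise_cv coefficient of variation of the fluorescence noise.
#' @param amplitude,f_blank full-amplification fluorescence and blank.
#' @param seed integer seed.
#' @return A `qpcr_measurement`: list with `amplicon_id`, `gene_id`,
#'   `fragment_length`, `f_irradiated`, `f_control`, `f_blank`,
#'   `timepoint`.
#' @export
simulate_qpcr <- function(field, gene, amplicon, t, params,
                          n_templates = 1000, noise_cv = 0.1,
                          amplitude = 1000, f_blank = 5, seed = 1L) {
  a <- amplicon[1]; b <- amplicon[2]
  len_gene <- gene$end - gene$start
  if (a < 0 || b > len_gene || b <= a)
    stop("amplicon must lie within the gene and have positive length")
  frag <- b - a
  d <- field$density
  tc_on <- params$tc_active && gene$basal_rate > 0
  w <- params$tc_wave_speed
  gg_surv <- if (params$gg_active && params$gg_rate > 0)
    exp(-params$gg_rate * t) else 1
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  if (is.null(n_templates)) {
    # exact: surviving TS lesions are those past the wave front, thinned
    # by GG-NER survival; NTS lesions thinned by GG-NER only
    ts_len <- if (tc_on) max(0, b - max(a, w * t)) else frag
    p0 <- exp(-d * gg_surv * (ts_len + frag))
  } else {
    n_ts <- stats::rpois(n_templates, d * frag)
    n_nts <- stats::rpois(n_templates, d * frag)
    survives <- logical(n_templates)
    tot_ts <- sum(n_ts)
    pos_ts <- stats::runif(tot_ts, a, b)
    ggt_ts <- if (gg_surv < 1) stats::rexp(tot_ts, params$gg_rate) else
      rep(Inf, tot_ts)
    rt_ts <- if (tc_on) pmin(pos_ts / w, ggt_ts) else ggt_ts
    alive_ts <- rt_ts > t
    idx <- rep(seq_len(n_templates), n_ts)
    ts_hit <- tapply(alive_ts, factor(idx, levels = seq_len(n_templates)), any)
    ts_hit[is.na(ts_hit)] <- FALSE
    nts_hit <- if (gg_surv < 1)
      stats::rbinom(n_templates, n_nts, gg_surv) > 0 else n_nts > 0
    p0 <- mean(!ts_hit & !nts_hit)
  }
  noise <- function() {
    if (noise_cv <= 0) return(1)
    sdlog <- sqrt(log(1 + noise_cv^2))
    stats::rlnorm(1, -sdlog^2 / 2, sdlog)
  }
  structure(list(amplicon_id = sprintf("%s:%d-%d", gene$gene_id, a, b),
                 gene_id = gene$gene_id, fragment_length = frag,
                 f_irradiated = f_blank + amplitude * p0 * noise(),
                 f_control = f_blank + amplitude * noise(),
                 f_blank = f_blank, timepoint = t),
            class = "qpcr_measurement")
}

#' Read/write qPCR measurement tables (TSV)
#'
#' Columns: amplicon_id, gene_id, fragment_length, f_irradiated,
#' f_control, f_blank, timepoint, replicate.
#'
#' @param path TSV file.
#' @return data.frame of measurements.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("amplicon_id", "fragment_length", "f_irradiated", "f_control",
            "f_blank", "timepoint")
  if (!all(need %in% names(df)))
    stop("measurement table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' @rdname read_qpcr_table
#' @param measurements data.frame (or list of `qpcr_measurement`).
#' @export
write_qpcr_table <- function(measurements, path) {
  if (is.list(measurements) && !is.data.frame(measurements))
    measurements <- do.call(rbind, lapply(measurements, function(m)
      as.data.frame(unclass(m))))
  utils::write.table(measurements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Lesion estimates from a measurement table
#'
#' Applies the zero-class estimator and per-10 kb scaling to each row.
#'
#' @param measurements data.frame as in [read_qpcr_table()].
#' @return data.frame with `amplicon_id`, `timepoint`,
#'   `lesions_per_fragment`, `lesions_per_10kb`.
#' @export
estimate_lesions <- function(measurements) {
  lpf <- lesions_per_fragment(measurements$f_irradiated,
                              measurements$f_control,
                              measurements$f_blank)
  data.frame(amplicon_id = measurements$amplicon_id,
             timepoint = measurements$timepoint,
             lesions_per_fragment = lpf,
             lesions_per_10kb = lesions_per_10kb(
               lpf, measurements$fragment_length))
}
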