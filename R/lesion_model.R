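#' Photolesion density per strand for a UVC dose
#'
#' Transcription-blocking photolesions (cyclobutane pyrimidine dimers plus
#' other UV photoproducts, pooled) are induced at roughly one lesion per
#' 7 kbp of double-stranded DNA -- i.e. one per 14 kb on the transcribed
#' strand -- per 10 J/m2 of UVC, and linearly in dose.
#'
#' @param dose UVC fluence in J/m2 (>= 0).
#' @return Lesions per bp per strand: `dose / 10 / 14000`.
#' @export
lesion_density <- function(dose) {
  if (any(dose < 0)) stop("dose must be >= 0")
  dose / 10 * (1 / 14000)
}

#' Construct a lesion field
#'
#' Per-gene, per-strand positions (bp offsets from the TSS) of
#' transcription-blocking lesions, with removal times in hours (`Inf`
#' until assigned by [assign_removal_times()]).
#'
#' @param gene_id gene the field belongs to.
#' @param gene_length gene length in bp.
#' @param density lesions per bp per strand used to draw the field.
#' @param ts_positions,nts_positions lesion offsets on the transcribed and
#'   non-transcribed strand (sorted ascending, within `[0, gene_length)`).
#' @param ts_removal,nts_removal removal times (hours, `Inf` = never).
#' @return A `lesion_field`.
#' @export
lesion_field <- function(gene_id, gene_length, density,
                         ts_positions = numeric(), nts_positions = numeric(),
                         ts_removal = rep(Inf, length(ts_positions)),
                         nts_removal = rep(Inf, length(nts_positions))) {
  stopifnot(density >= 0, gene_length > 0)
  check_pos <- function(p, lab) {
    if (is.unsorted(p)) stop(lab, " positions must be sorted ascending")
    if (any(p < 0 | p >= gene_length))
      stop(lab, " positions must lie in [0, gene length)")
  }
  check_pos(ts_positions, "transcribed-strand")
  check_pos(nts_positions, "non-transcribed-strand")
  if (any(c(ts_removal, nts_removal) < 0)) stop("removal times must be >= 0")
  structure(list(gene_id = gene_id, gene_length = gene_length,
                 density = density,
                 ts = data.frame(position = ts_positions,
                                 removal_time = ts_removal),
                 nts = data.frame(position = nts_positions,
                                  removal_time = nts_removal)),
            removal_assigned = FALSE,
            class = "lesion_field")
}

#' Place lesions on a gene by Poisson sampling
#'
#' Lesion induction events are independent, so per strand the lesion count
#' is Poisson(`density * length`) with positions i.i.d. uniform along the
#' gene. Removal times are `Inf` until a repair model assigns them.
#'
#' @param gene single-row [gene_set()] slice (or list with `gene_id`,
#'   `start`, `end`).
#' @param density lesions per bp per strand (>= 0).
#' @param seed integer seed; fixed seed gives identical positions.
#' @return A [lesion_field()].
#' @export
place_lesions <- function(gene, density, seed = 1L) {
  if (density < 0) stop("density must be >= 0")
  len <- gene$end - gene$start
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  draw <- function() sort(stats::runif(stats::rpois(1, density * len), 0, len))
  ts <- draw()
  nts <- draw()
  lesion_field(gene$gene_id, len, density, ts, nts)
}

#' Poisson lesion-class probabilities for a gene
#'
#' Probability that a cell carries k = 0, 1, ..., `k_max - 1` lesions in a
#' gene, plus the tail mass P(k >= `k_max`), under a Poisson model with
#' mean `gene_length * density`. For CDKN1A (10.8 kbp) at 10 J/m2
#' (1 lesion per 14 kb on the transcribed strand) this gives about
#' 46/36/14/4% of cells with 0/1/2/3+ lesions.
#'
#' @param gene_length bp.
#' @param density lesions per bp (use the per-strand density for
#'   strand-specific questions).
#' @param k_max number of explicit classes (>= 1); the returned vector has
#'   `k_max + 1` entries and sums to 1 exactly.
#' @return named numeric vector `k0, k1, ..., k{k_max-1}, tail`.
#' @export
lesion_class_probabilities <- function(gene_length, density, k_max = 3) {
  if (gene_length < 0 || density < 0) stop("inputs must be >= 0")
  if (k_max < 1) stop("k_max must be >= 1")
  lambda <- gene_length * density
  p <- stats::dpois(0:(k_max - 1), lambda)
  out <- c(p, 1 - sum(p))
  out[out < 0] <- 0  # guard tiny negative rounding of the tail
  names(out) <- c(paste0("k", 0:(k_max - 1)), "tail")
  out
}

#' Probability a polymerase reads through to position x
#'
#' Immediately after irradiation, a polymerase starting at the TSS reaches
#' position `x` only if no transcribed-strand lesion fell in `[0, x)`;
#' under Poisson placement that probability is `exp(-density * x)` -- the
#' target-theory form that makes transcription inhibition proportional to
#' gene size.
#'
#' @param x distance from the TSS in bp (>= 0); vectorized.
#' @param density transcribed-strand lesions per bp.
#' @return `exp(-density * x)`.
#' @export
expected_readthrough <- function(x, density) {
  if (any(x < 0)) stop("x must be >= 0")
  if (any(density < 0)) stop("density must be >= 0")
  exp(-density * x)
}

#' Serialize lesion fields to TSV
#'
#' Columns: gene_id, strand (`TS`/`NTS`), position, removal_time
#' (`Inf` written as "Inf").
#'
#' @param fields list of [lesion_field()] (or a single field).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_lesion_fields <- function(fields, path) {
  if (inherits(fields, "lesion_field")) fields <- list(fields)
  rows <- lapply(fields, function(f) {
    rbind(
      if (nrow(f$ts)) data.frame(gene_id = f$gene_id, strand = "TS", f$ts),
      if (nrow(f$nts)) data.frame(gene_id = f$gene_id, strand = "NTS", f$nts))
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(gene_id = character(), strand = character(),
                     position = numeric(), removal_time = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
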