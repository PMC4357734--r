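#' RPKM of a coverage track
#'
#' Reads per thousand base pairs of transcription unit per million
#' sequenced reads: `sum(counts) * 1e9 / (length_bp * library_size)`.
#'
#' @param track a [coverage_track()].
#' @param gene the matching single-row [gene_set()] slice.
#' @return RPKM value.
#' @export
rpkm <- function(track, gene) {
  len <- gene$end - gene$start
  if (len <= 0) stop("zero-length gene")
  if (track$library_size <= 0) stop("library_size must be > 0")
  sum(track$counts) * 1e9 / (len * track$library_size)
}

#' RPKM table for a set of tracks
#' @param tracks named list of [coverage_track()].
#' @param genes a [gene_set()].
#' @return data.frame with columns `gene_id`, `rpkm`.
#' @export
rpkm_table <- function(tracks, genes) {
  data.frame(gene_id = genes$gene_id,
             rpkm = vapply(genes$gene_id, function(id)
               rpkm(tracks[[id]], genes[genes$gene_id == id, ]), numeric(1)),
             row.names = NULL)
}

#' TSS-anchored metagene profile
#'
#' Averages normalized coverage across a gene set aligned at the TSS.
#' Genes are filtered by length and by expression in the control
#' condition; each passing gene's per-bin density is normalized to its own
#' mean over the span (so genes of very different expression weigh
#' equally), and the profile is the per-bin mean across genes. Bins beyond
#' a gene's end are excluded from that gene's contribution (no padding);
#' each gene's trailing partial bin is dropped to avoid edge artifacts.
#'
#' @param tracks named list of [coverage_track()] for one condition.
#' @param genes a [gene_set()].
#' @param rpkm_ctrl optional control-condition RPKM table (columns
#'   `gene_id`, `rpkm`) used for the expression filter.
#' @param min_length keep genes with length > `min_length` (bp).
#' @param min_rpkm keep genes with control RPKM > `min_rpkm` (requires
#'   `rpkm_ctrl`).
#' @param span profile span in bp from the TSS (default: length of the
#'   longest passing gene).
#' @return A `metagene_profile`: list with `values` (mean normalized
#'   density per bin), `bin_width`, `span`, `n_genes`, `condition`,
#'   `gene_filter`.
#' @export
metagene <- function(tracks, genes, rpkm_ctrl = NULL, min_length = 0,
                     min_rpkm = 0, span = NULL) {
  keep <- gene_length(genes) > min_length
  if (!is.null(rpkm_ctrl)) {
    ctrl <- rpkm_ctrl$rpkm[match(genes$gene_id, rpkm_ctrl$gene_id)]
    keep <- keep & !is.na(ctrl) & ctrl > min_rpkm
  } else if (min_rpkm > 0) {
    stop("min_rpkm filter requires rpkm_ctrl")
  }
  sel <- genes[keep, , drop = FALSE]
  if (nrow(sel) == 0) stop("no genes pass the metagene filters")
  bw <- unique(vapply(tracks, `[[`, numeric(1), "bin_width"))
  if (length(bw) != 1) stop("tracks must share bin_width")
  if (is.null(span)) span <- max(gene_length(sel))
  nb <- as.integer(span %/% bw)
  if (nb < 1) stop("span smaller than one bin")
  sums <- numeric(nb)
  ngene <- numeric(nb)
  for (k in seq_len(nrow(sel))) {
    g <- sel[k, ]
    tr <- tracks[[g$gene_id]]
    if (is.null(tr)) stop("no track for gene ", g$gene_id)
    full <- (g$end - g$start) %/% bw     # complete bins only
    use <- min(full, nb)
    if (use < 1) next
    vals <- tr$counts[seq_len(use)]
    m <- mean(vals)
    if (m <= 0) next                     # gene silent over the span
    sums[seq_len(use)] <- sums[seq_len(use)] + vals / m
    ngene[seq_len(use)] <- ngene[seq_len(use)] + 1
  }
  if (all(ngene == 0)) stop("no genes contributed coverage to the profile")
  values <- ifelse(ngene > 0, sums / pmax(ngene, 1), NA_real_)
  structure(list(values = values, bin_width = bw, span = span,
                 n_genes = nrow(sel), n_contributing = ngene,
                 condition = tracks[[1]]$condition,
                 gene_filter = sprintf("length > %g bp, control RPKM > %g",
                                       min_length, min_rpkm)),
            class = "metagene_profile")
}

#' Fold-change gene sets after UV, with median lengths
#'
#' Classifies genes by the ratio of UV to control RPKM (with a small
#' pseudocount to avoid division by zero): induced if ratio >= threshold,
#' repressed if ratio <= 1/threshold. Restricted to genes expressed in the
#' control (`ctrl RPKM >= min_rpkm` and > 0).
#'
#' @param rpkm_uv,rpkm_ctrl RPKM tables (columns `gene_id`, `rpkm`)
#'   sharing gene ids.
#' @param genes a [gene_set()] supplying lengths.
#' @param threshold fold threshold (> 1, default 2).
#' @param min_rpkm minimum control RPKM (default 0.5).
#' @param pseudocount added to both RPKM values in the ratio.
#' @return list with `induced`, `repressed` (gene id vectors),
#'   `median_length_induced`, `median_length_repressed` (bp, `NA` when a
#'   set is empty) and the `ratios` table.
#' @export
fold_change_sets <- function(rpkm_uv, rpkm_ctrl, genes, threshold = 2,
                             min_rpkm = 0.5, pseudocount = 0.01) {
  if (threshold <= 1) stop("threshold must be > 1")
  ids <- intersect(rpkm_uv$gene_id, rpkm_ctrl$gene_id)
  if (length(ids) == 0) stop("RPKM tables share no gene ids")
  uv <- rpkm_uv$rpkm[match(ids, rpkm_uv$gene_id)]
  ctrl <- rpkm_ctrl$rpkm[match(ids, rpkm_ctrl$gene_id)]
  keep <- ctrl >= min_rpkm & ctrl > 0
  ids <- ids[keep]; uv <- uv[keep]; ctrl <- ctrl[keep]
  ratio <- (uv + pseudocount) / (ctrl + pseudocount)
  induced <- ids[ratio >= threshold]
  repressed <- ids[ratio <= 1 / threshold]
  len <- function(set) if (length(set) == 0) NA_real_ else
    stats::median(gene_length(genes[genes$gene_id %in% set, , drop = FALSE]))
  list(induced = induced, repressed = repressed,
       median_length_induced = len(induced),
       median_length_repressed = len(repressed),
       ratios = data.frame(gene_id = ids, ratio = ratio,
                           rpkm_uv = uv, rpkm_ctrl = ctrl))
}

# total-variation distance between two profiles after sum-normalization
# (restricted afterwards to `bins`, so regional deviations keep the
# whole-profile scale); bins where either value is missing are dropped
profile_tv <- function(p, q, bins = NULL) {
  ok <- is.finite(p) & is.finite(q)
  p[!ok] <- 0; q[!ok] <- 0
  if (sum(p) <= 0 || sum(q) <= 0) stop("profiles must have positive mass")
  dev <- 0.5 * abs(p / sum(p) - q / sum(q))
  if (is.null(bins)) sum(dev) else sum(dev[bins])
}

#' Percent recovery of RNA synthesis
#'
#' Full recovery means the read distribution along genes has returned to
#' the even (control) distribution. Deviation from control is measured as
#' the total-variation distance between sum-normalized profiles,
#' `D(p) = 0.5 * sum |p_b/sum(p) - c_b/sum(c)|`, and recovery at time t is
#' `100 * (1 - D(p_t) / D(p_t0))`, clipped to `[0, 100]`; if the
#' immediately-after-UV profile already equals the control (`D(p_t0) = 0`)
#' recovery is defined as 100. The statistic is invariant to uniform
#' rescaling of any profile.
#'
#' @param profile_t metagene profile at the queried recovery time.
#' @param profile_ctrl unirradiated control profile.
#' @param profile_t0 profile immediately after irradiation (t = 0).
#' @param bins optional integer vector of bin indices: the deviation is
#'   restricted to these bins (after whole-profile normalization), giving
#'   a regional recovery, e.g. of the first versus the last fifth of the
#'   span.
#' @return A `recovery_report`: list with `percent_recovery`, `condition`,
#'   `gene_filter`, `n_genes` and the two deviations `d_t`, `d_t0`.
#' @export
percent_recovery <- function(profile_t, profile_ctrl, profile_t0,
                             bins = NULL) {
  profs <- list(profile_t, profile_ctrl, profile_t0)
  bw <- unique(vapply(profs, `[[`, numeric(1), "bin_width"))
  nb <- unique(vapply(profs, function(p) length(p$values), integer(1)))
  if (length(bw) != 1 || length(nb) != 1)
    stop("profiles must share bin width and span")
  d_t <- profile_tv(profile_t$values, profile_ctrl$values, bins)
  d_t0 <- profile_tv(profile_t0$values, profile_ctrl$values, bins)
  rec <- if (d_t0 == 0) 100 else 100 * (1 - d_t / d_t0)
  rec <- min(100, max(0, rec))
  structure(list(percent_recovery = rec, d_t = d_t, d_t0 = d_t0,
                 condition = profile_t$condition,
                 gene_filter = profile_t$gene_filter,
                 n_genes = profile_t$n_genes),
            class = "recovery_report")
}

#' Stratify genes into expression bins
#'
#' Partitions genes by control RPKM into low / medium / high groups; the
#' default ranges (0.3, 1), (1, 2) and (5, Inf) deliberately leave gaps,
#' so genes outside any range stay unassigned.
#'
#' @param rpkm_ctrl control RPKM table (columns `gene_id`, `rpkm`).
#' @param cutoffs named list of `c(lower, upper)` ranges (open lower,
#'   closed-nowhere: membership is `lower < rpkm < upper`), in strictly
#'   increasing, non-overlapping order.
#' @return named list of gene-id vectors, one per range.
#' @export
expression_bins <- function(rpkm_ctrl,
                            cutoffs = list(low = c(0.3, 1),
                                           medium = c(1, 2),
                                           high = c(5, Inf))) {
  lo <- vapply(cutoffs, `[[`, numeric(1), 1)
  hi <- vapply(cutoffs, `[[`, numeric(1), 2)
  if (any(hi <= lo) || is.unsorted(lo, strictly = TRUE) ||
      any(lo[-1] < hi[-length(hi)]))
    stop("cutoffs must be strictly increasing, non-overlapping ranges")
  out <- lapply(seq_along(cutoffs), function(i)
    rpkm_ctrl$gene_id[rpkm_ctrl$rpkm > lo[i] & rpkm_ctrl$rpkm < hi[i]])
  names(out) <- names(cutoffs)
  out
}
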