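#' Repair parameters
#'
#' Two pathways remove transcription-blocking lesions: transcription-coupled
#' nucleotide excision repair (TC-NER), modeled as a deterministic 5'-to-3'
#' wave along the transcribed strand of expressed genes (a lesion at offset
#' x is cleared at `x / tc_wave_speed` hours), and global-genomic NER
#' (GG-NER), modeled as strand-agnostic exponential removal at `gg_rate`
#' per hour. A lesion's removal time is the minimum over active pathways.
#'
#' @param tc_active,gg_active pathway flags.
#' @param tc_wave_speed TC-NER wave speed in bp per hour (> 0).
#' @param gg_rate GG-NER per-lesion removal rate per hour (>= 0).
#' @param genotype_label one of `"WT"`, `"XPC"`, `"CSB"`, `"NONE"`.
#' @return A `repair_params` list.
#' @export
repair_params <- function(tc_active, gg_active, tc_wave_speed = 6000,
                          gg_rate = 0.08, genotype_label = "custom") {
  if (tc_wave_speed <= 0) stop("tc_wave_speed must be > 0")
  if (gg_rate < 0) stop("gg_rate must be >= 0")
  structure(list(tc_active = isTRUE(tc_active), gg_active = isTRUE(gg_active),
                 tc_wave_speed = tc_wave_speed, gg_rate = gg_rate,
                 genotype_label = genotype_label),
            class = "repair_params")
}

#' Genotype presets for repair
#'
#' Wild-type fibroblasts are proficient in both TC-NER and GG-NER; XP-C
#' cells (XPC mutation) lack GG-NER but retain TC-NER; CS-B cells (CSB
#' mutation) lack TC-NER but retain GG-NER; `NONE` disables both (all
#' removal times stay infinite).
#'
#' @param label `"WT"`, `"XPC"`, `"CSB"` or `"NONE"`.
#' @param tc_wave_speed,gg_rate defaults as in [repair_params()].
#' @return A [repair_params()].
#' @export
genotype_presets <- function(label, tc_wave_speed = 6000, gg_rate = 0.08) {
  flags <- switch(label,
                  WT = c(TRUE, TRUE),
                  XPC = c(TRUE, FALSE),
                  CSB = c(FALSE, TRUE),
                  NONE = c(FALSE, FALSE),
                  stop("unknown genotype label: ", label))
  repair_params(flags[1], flags[2], tc_wave_speed, gg_rate,
                genotype_label = label)
}

#' Assign lesion removal times under a repair genotype
#'
#' Transcribed-strand lesions of expressed genes (`basal_rate > 0`) get the
#' TC-NER wave time `x / tc_wave_speed` when TC-NER is active; every lesion
#' on both strands additionally gets an Exponential(`gg_rate`) GG-NER time
#' when GG-NER is active. The assigned removal time is the minimum of the
#' two (infinite where a pathway does not apply). Silent genes and the
#' non-transcribed strand are never repaired by TC-NER.
#'
#' @param field a [lesion_field()] for `gene`.
#' @param gene the matching single-row [gene_set()] slice.
#' @param params a [repair_params()].
#' @param seed integer seed for the exponential GG-NER draws; with the
#'   same field and seed the draws are identical across genotypes, so
#'   wild-type removal times are pathwise below single-pathway ones.
#' @return The field with `removal_time` columns filled.
#' @export
assign_removal_times <- function(field, gene, params, seed = 1L) {
  if (!identical(field$gene_id, gene$gene_id))
    stop("lesion field belongs to gene ", field$gene_id,
         ", not ", gene$gene_id)
  if (field$gene_length != gene$end - gene$start)
    stop("lesion field length does not match gene length")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n_ts <- nrow(field$ts); n_nts <- nrow(field$nts)
  gg <- function(n) {
    if (params$gg_active && params$gg_rate > 0) stats::rexp(n, params$gg_rate)
    else rep(Inf, n)
  }
  t_gg_ts <- gg(n_ts)
  t_gg_nts <- gg(n_nts)
  t_tc <- if (params$tc_active && gene$basal_rate > 0)
    field$ts$position / params$tc_wave_speed else rep(Inf, n_ts)
  field$ts$removal_time <- pmin(t_tc, t_gg_ts)
  field$nts$removal_time <- t_gg_nts
  attr(field, "removal_assigned") <- TRUE
  field
}

#' Lesions remaining at a time point
#'
#' @param field a [lesion_field()] with removal times assigned.
#' @param t hours after irradiation.
#' @param strand `"transcribed"`, `"non_transcribed"` or `"both"`.
#' @return list with `count` and `positions` of lesions whose removal time
#'   exceeds `t`.
#' @export
remaining_lesions <- function(field, t, strand = c("both", "transcribed",
                                                   "non_transcribed")) {
  strand <- match.arg(strand)
  if (!isTRUE(attr(field, "removal_assigned")))
    stop("removal times not assigned; call assign_removal_times() first")
  pos <- switch(strand,
    transcribed = field$ts$position[field$ts$removal_time > t],
    non_transcribed = field$nts$position[field$nts$removal_time > t],
    both = sort(c(field$ts$position[field$ts$removal_time > t],
                  field$nts$position[field$nts$removal_time > t])))
  list(count = length(pos), positions = pos)
}
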