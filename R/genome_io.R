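#' Construct a gene set
#'
#' A gene set is a data frame of transcription units with one row per gene
#' and columns `gene_id`, `chrom`, `start`, `end` (0-based half-open),
#' `strand` (`+`/`-`) and `basal_rate` (transcription initiation rate in
#' arbitrary RPKM-equivalent units; 0 means silent).
#'
#' @param genes data.frame with the columns above (`basal_rate` optional,
#'   defaults to 0).
#' @param provenance free-text record of where the set came from (file path
#'   or generator parameters plus seed).
#' @return A `gene_set` (a validated data.frame subclass).
#' @export
gene_set <- function(genes, provenance = "") {
  stopifnot(is.data.frame(genes))
  required <- c("gene_id", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0)
    stop("gene set is missing columns: ", paste(missing, collapse = ", "))
  if (is.null(genes$basal_rate)) genes$basal_rate <- rep(0, nrow(genes))
  genes <- genes[, c(required, "basal_rate")]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  genes$strand <- as.character(genes$strand)
  validate_gene_set(genes)
  rownames(genes) <- NULL
  structure(genes, provenance = provenance,
            class = c("gene_set", "data.frame"))
}

validate_gene_set <- function(genes) {
  if (nrow(genes) == 0) return(invisible(genes))
  bad <- which(genes$end <= genes$start)
  if (length(bad) > 0)
    stop("gene(s) with end <= start: ", paste(genes$gene_id[bad], collapse = ", "))
  if (any(genes$end - genes$start < 200))
    stop("gene(s) shorter than 200 bp: ",
         paste(genes$gene_id[genes$end - genes$start < 200], collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(genes$basal_rate < 0))
    stop("basal_rate must be >= 0")
  # overlap within a chromosome: generator guarantees none; readers only warn
  for (chr in unique(genes$chrom)) {
    g <- genes[genes$chrom == chr, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
      warning("overlapping genes on ", chr,
              "; downstream simulation treats genes independently")
  }
  invisible(genes)
}

#' Gene length in bp
#' @param genes a `gene_set` or compatible data.frame.
#' @return numeric vector of `end - start`.
#' @export
gene_length <- function(genes) genes$end - genes$start

#' Generate a synthetic gene annotation
#'
#' Draws a non-overlapping gene set emulating the length and expression
#' structure of a human fibroblast nascent-transcription annotation: gene
#' lengths log-normal (clipped to 1 kbp--1 Mbp, so the set spans short
#' <20 kbp and long >100 kbp genes) and basal expression a gamma
#' distribution with a point mass at zero for silent genes. With the
#' defaults the overall expression has mean about 1.09 and median about
#' 0.15 in RPKM-equivalent units, i.e. most genes are lowly expressed.
#'
#' @param n_genes number of genes (>= 1).
#' @param length_log_mean,length_log_sd log-normal parameters of gene
#'   length in bp (defaults `log(30000)` and 1.2).
#' @param expression_shape,expression_scale gamma parameters of the
#'   expressed-gene basal rate (RPKM-equivalent units).
#' @param silent_fraction fraction of genes with basal rate exactly 0.
#' @param seed integer seed; identical seed gives an identical set.
#' @return A [gene_set()] on one synthetic chromosome `"chrS"`, genes
#'   separated by random intergenic gaps, strands random.
#' @export
generate_gene_set <- function(n_genes,
                              length_log_mean = log(30000),
                              length_log_sd = 1.2,
                              expression_shape = 0.65,
                              expression_scale = 2.8,
                              silent_fraction = 0.4,
                              seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1)
    stop("n_genes must be a single integer >= 1")
  if (length_log_sd <= 0 || expression_shape <= 0 || expression_scale <= 0)
    stop("distribution parameters must be positive")
  if (silent_fraction < 0 || silent_fraction >= 1)
    stop("silent_fraction must be in [0, 1)")
  n_genes <- as.integer(n_genes)
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  len <- round(pmin(pmax(stats::rlnorm(n_genes, length_log_mean, length_log_sd),
                         1000), 1e6))
  rate <- stats::rgamma(n_genes, shape = expression_shape,
                        scale = expression_scale)
  rate[stats::runif(n_genes) < silent_fraction] <- 0
  gaps <- round(stats::rexp(n_genes, rate = 1 / 10000)) + 1000
  start <- cumsum(c(0, len[-n_genes])) + cumsum(gaps)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  gene_set(data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
                      chrom = "chrS", start = start, end = start + len,
                      strand = strand, basal_rate = rate),
           provenance = sprintf(
             "generate_gene_set(n=%d, seed=%d, length_log_mean=%.4f, length_log_sd=%g, shape=%g, scale=%g, silent=%g)",
             n_genes, seed, length_log_mean, length_log_sd,
             expression_shape, expression_scale, silent_fraction))
}

# seed handling: save/restore the global RNG state so library calls are
# reproducible without clobbering the caller's stream
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Read gene annotations from a BED file
#'
#' Accepts BED6 or BED12 (0-based half-open); BED12 thick/block fields are
#' ignored. `basal_rate` defaults to 0 and can be populated from an RPKM
#' table (`rpkm` argument or [read_rpkm_table()]).
#'
#' @param path BED file.
#' @param rpkm optional data.frame with columns `gene_id`, `rpkm` used to
#'   fill `basal_rate`.
#' @return A [gene_set()].
#' @export
read_genes <- function(path, rpkm = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  keep <- !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(gene_set(data.frame(gene_id = character(), chrom = character(),
                               start = numeric(), end = numeric(),
                               strand = character()),
                    provenance = path))
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("malformed BED line ", which(nf < 6)[1],
         ": expected at least 6 fields, got ", nf[which(nf < 6)[1]])
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyNA(starts) || anyNA(ends))
    stop("malformed BED line ", which(is.na(starts) | is.na(ends))[1],
         ": non-numeric start/end")
  if (any(ends <= starts))
    stop("BED line ", which(ends <= starts)[1], ": end <= start")
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(gene_id = gr$name,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)))
  if (any(df$strand == "*"))
    stop("BED records must carry a '+' or '-' strand")
  genes <- gene_set(df, provenance = path)
  if (!is.null(rpkm)) {
    idx <- match(genes$gene_id, rpkm$gene_id)
    genes$basal_rate <- ifelse(is.na(idx), 0, rpkm$rpkm[idx])
  }
  genes
}

#' Write a gene set to BED6
#'
#' The BED score field is 0; `basal_rate` is not representable in BED and
#' should be written separately with [write_rpkm_table()].
#'
#' @param genes a [gene_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  df <- data.frame(genes$chrom, format(genes$start, scientific = FALSE, trim = TRUE),
                   format(genes$end, scientific = FALSE, trim = TRUE),
                   genes$gene_id, 0L, genes$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write an RPKM table (TSV with columns gene_id, rpkm)
#' @param path TSV file.
#' @return data.frame with columns `gene_id`, `rpkm`.
#' @export
read_rpkm_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "rpkm") %in% names(df)))
    stop("RPKM table must have columns gene_id and rpkm")
  df
}

#' @rdname read_rpkm_table
#' @param table data.frame with columns `gene_id`, `rpkm`.
#' @export
write_rpkm_table <- function(table, path) {
  utils::write.table(table[, c("gene_id", "rpkm")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a coverage track
#'
#' Binned nascent-RNA read density over gene-local coordinates for one
#' condition. Bin 0 starts at the TSS regardless of strand; the last bin
#' may be shorter than `bin_width`.
#'
#' @param gene_id gene the track belongs to.
#' @param counts non-negative numeric vector, one value per bin.
#' @param bin_width bin width in bp.
#' @param library_size total reads in the experiment (> 0).
#' @param condition list with elements `dose` (J/m2), `time` (hours) and
#'   `genotype`.
#' @return A `coverage_track`.
#' @export
coverage_track <- function(gene_id, counts, bin_width, library_size,
                           condition = list(dose = 0, time = 0, genotype = "WT")) {
  if (any(counts < 0)) stop("counts must be >= 0")
  if (library_size <= 0) stop("library_size must be > 0")
  structure(list(gene_id = gene_id, counts = as.numeric(counts),
                 bin_width = bin_width, library_size = library_size,
                 condition = condition),
            class = "coverage_track")
}

n_bins <- function(length_bp, bin_width) as.integer(ceiling(length_bp / bin_width))

#' Write coverage tracks to bedGraph
#'
#' Bins are mapped back to genomic coordinates using the gene annotation;
#' for minus-strand genes bin 0 (the TSS bin) sits at the 3'-most genomic
#' coordinates, so intervals still ascend genomically as bedGraph requires.
#'
#' @param tracks named list of [coverage_track()] (names are gene ids), all
#'   with the same bin width.
#' @param genes the [gene_set()] the tracks refer to.
#' @param path output bedGraph path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(tracks, genes, path) {
  bw <- unique(vapply(tracks, `[[`, numeric(1), "bin_width"))
  if (length(bw) != 1) stop("tracks must share bin_width")
  rows <- lapply(tracks, function(tr) {
    g <- genes[genes$gene_id == tr$gene_id, ]
    if (nrow(g) != 1) stop("track gene ", tr$gene_id, " not in gene set")
    nb <- length(tr$counts)
    i <- seq_len(nb) - 1
    if (g$strand == "+") {
      s <- g$start + i * bw
      e <- pmin(g$start + (i + 1) * bw, g$end)
    } else {
      s <- pmax(g$end - (i + 1) * bw, g$start)
      e <- g$end - i * bw
    }
    data.frame(chrom = g$chrom, start = s, end = e, score = tr$counts)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start), ]
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end),
                               score = df$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read coverage tracks from bedGraph
#'
#' Inverse of [write_coverage()]: intervals are assigned to genes by
#' position and folded back to gene-local bins (bin 0 at the TSS).
#'
#' @param path bedGraph file.
#' @param genes the [gene_set()] used when writing.
#' @param bin_width bin width in bp used when writing.
#' @param library_size total reads of the experiment the track belongs to.
#' @param condition condition list stored on each track.
#' @return named list of [coverage_track()].
#' @export
read_coverage <- function(path, genes, bin_width, library_size = 1e6,
                          condition = list(dose = 0, time = 0, genotype = "WT")) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   score = gr$score)
  out <- list()
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    nb <- n_bins(g$end - g$start, bin_width)
    counts <- numeric(nb)
    sel <- df$chrom == g$chrom & df$start >= g$start & df$end <= g$end
    sub <- df[sel, ]
    if (nrow(sub) > 0) {
      bin <- if (g$strand == "+") (sub$start - g$start) %/% bin_width
             else (g$end - sub$end) %/% bin_width
      ok <- bin >= 0 & bin < nb
      counts[bin[ok] + 1] <- sub$score[ok]
    }
    out[[g$gene_id]] <- coverage_track(g$gene_id, counts, bin_width,
                                       library_size, condition)
  }
  out
}
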