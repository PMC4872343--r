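#' Read an expression matrix and its design
#'
#' The expression matrix is a tab-separated table with a `gene_id` column and
#' one column per sample; the design maps each sample column to a stage and
#' replicate. All abundances must be positive (linear scale).
#'
#' @param path Path to the expression TSV.
#' @return A tibble with `gene_id` plus one numeric column per sample.
#' @export
read_expression_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(x)) abort("expression matrix must have a `gene_id` column")
  if (anyDuplicated(x$gene_id)) abort("duplicate gene ids in expression matrix")
  x
}

#' @rdname read_expression_matrix
#' @param design_path Path to a design TSV with columns `sample`, `stage`,
#'   `replicate`. Stage order in the file defines the biological order; the
#'   first stage is the baseline.
#' @export
read_design <- function(design_path) {
  d <- readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "stage", "replicate")
  if (!all(need %in% names(d))) abort("design needs columns sample, stage, replicate")
  d$stage <- factor(d$stage, levels = unique(d$stage))
  d
}

#' Read a BED6 file of transcription start sites
#'
#' Each record is a single-base interval (0-based, half-open) whose start is
#' the TSS; `name` carries the gene id.
#'
#' @param path Path to a BED6 file.
#' @return Tibble with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss_bed <- function(path) {
  b <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    show_col_types = FALSE, progress = FALSE
  )
  tibble(gene_id = b$name, chrom = b$chrom, tss = b$start, strand = b$strand)
}

#' @rdname read_tss_bed
#' @param tss Tibble as returned by [read_tss_bed()].
#' @export
write_tss_bed <- function(tss, path) {
  readr::write_tsv(
    tibble(
      chrom = tss$chrom, start = tss$tss, end = tss$tss + 1L,
      name = tss$gene_id, score = 0L, strand = tss$strand
    ),
    path,
    col_names = FALSE
  )
  invisible(path)
}

#' Read a narrowPeak-like peak file
#'
#' Columns: chrom, start, end, name, score, strand, signal, -log10(p),
#' -log10(q), summit offset from `start`. A missing (`-1` or `NA`) summit is
#' replaced by the interval midpoint, which accommodates broad-peak callers
#' that do not report summits.
#'
#' @param path Path to the peak file.
#' @param target,stage Optional labels attached to every row (the file format
#'   itself is per-target, per-stage).
#' @return Tibble of peaks with an absolute `summit` column.
#' @export
read_narrowpeak <- function(path, target = NA_character_, stage = NA_character_) {
  p <- readr::read_tsv(path,
    col_names = c(
      "chrom", "start", "end", "name", "score", "strand",
      "signal", "neg_log10_p", "neg_log10_q", "summit_offset"
    ),
    show_col_types = FALSE, progress = FALSE
  )
  off <- p$summit_offset
  off[is.na(off) | off < 0] <- ((p$end - p$start) %/% 2L)[is.na(off) | off < 0]
  p$summit <- p$start + off
  p$target <- target
  p$stage <- stage
  as_tibble(p)
}

#' @rdname read_narrowpeak
#' @param peaks Peak tibble (one target/stage).
#' @export
write_narrowpeak <- function(peaks, path) {
  readr::write_tsv(
    peaks[, c(
      "chrom", "start", "end", "name", "score", "strand",
      "signal", "neg_log10_p", "neg_log10_q", "summit_offset"
    )],
    path,
    col_names = FALSE
  )
  invisible(path)
}

#' Read a GMT-like regulon file
#'
#' One line per transcription factor: TF id, a free-text description, then the
#' tab-separated target genes.
#'
#' @param path Path to the GMT file.
#' @return Long tibble with columns `tf`, `target`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  purrr::map_dfr(parts, function(p) {
    if (length(p) < 3) abort("GMT line with no targets (empty regulon)")
    tibble(tf = p[[1]], target = unique(p[-(1:2)]))
  })
}

#' @rdname read_gmt
#' @param regulons Long tibble `tf`, `target`.
#' @param descriptions Optional named character vector of per-TF descriptions.
#' @export
write_gmt <- function(regulons, path, descriptions = NULL) {
  split_targets <- split(regulons$target, regulons$tf)
  tfs <- names(split_targets)
  desc <- if (is.null(descriptions)) rep("regulon", length(tfs)) else descriptions[tfs]
  lines <- vapply(seq_along(tfs), function(i) {
    paste(c(tfs[[i]], desc[[i]], split_targets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read / write a SIF interaction edge list
#'
#' Simple interaction format: `source <TAB> type <TAB> target`, one edge per
#' line.
#'
#' @param path Path to the SIF file.
#' @return Tibble with columns `from`, `type`, `to`.
#' @export
read_sif <- function(path) {
  s <- readr::read_tsv(path,
    col_names = c("from", "type", "to"),
    show_col_types = FALSE, progress = FALSE
  )
  as_tibble(s)
}

#' @rdname read_sif
#' @param edges Tibble with columns `from`, `type`, `to`.
#' @export
write_sif <- function(edges, path) {
  readr::write_tsv(edges[, c("from", "type", "to")], path, col_names = FALSE)
  invisible(path)
}

#' Read a binned coverage (bedGraph-like) file into a track
#'
#' @param path Path to a 4-column TSV: chrom, start, end, intensity; bins must
#'   be non-overlapping and uniform.
#' @return Tibble with columns `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "score"),
    show_col_types = FALSE, progress = FALSE
  )
}

write_bedgraph <- function(bins, score, path) {
  readr::write_tsv(
    tibble(chrom = bins$chrom, start = bins$start, end = bins$end, score = score),
    path,
    col_names = FALSE
  )
  invisible(path)
}
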