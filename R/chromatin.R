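#' ChIP-seq track container: binned coverage for several targets and stages
#'
#' Holds read-count intensities over one shared grid of non-overlapping,
#' uniform bins (100 bp by default), for any number of (target, stage) tracks.
#' The raw counts are kept alongside the working intensities so that
#' count-based robustness checks (subsampling dispersion) remain available
#' after normalization.
#'
#' @param bins Tibble of bin coordinates `chrom`, `start`, `end` (0-based,
#'   half-open), tiling without overlap.
#' @param scores Numeric matrix, one row per bin, one column per track.
#' @param meta Tibble with one row per track: `track_id`, `target`, `stage`.
#' @return A `chip_tracks` object.
#' @export
chip_tracks <- function(bins, scores, meta) {
  if (nrow(bins) != nrow(scores)) abort("bins and scores disagree on bin count")
  if (ncol(scores) != nrow(meta)) abort("scores and meta disagree on track count")
  width <- bins$end - bins$start
  if (length(unique(width)) != 1) abort("bins must be uniform")
  colnames(scores) <- meta$track_id
  structure(
    list(
      bins = as_tibble(bins), scores = scores, raw = scores,
      meta = as_tibble(meta) %>% mutate(status = "raw"),
      bin_size = width[[1]]
    ),
    class = "chip_tracks"
  )
}

#' @export
print.chip_tracks <- function(x, ...) {
  cat(
    "<chip_tracks> ", nrow(x$bins), " bins of ", x$bin_size, " bp, ",
    nrow(x$meta), " tracks (", paste(unique(x$meta$status), collapse = "/"),
    ")\n",
    sep = ""
  )
  invisible(x)
}

# global bin index of a genomic position; NA outside the grid
bin_index <- function(tracks, chrom, pos) {
  bins <- tracks$bins
  offsets <- cumsum(c(0, rle(bins$chrom)$lengths))
  starts <- tapply(bins$start, bins$chrom, min)
  chroms <- rle(bins$chrom)$values
  idx <- rep(NA_integer_, length(pos))
  for (i in seq_along(chroms)) {
    sel <- chrom == chroms[[i]]
    if (!any(sel)) next
    local <- (pos[sel] - starts[[chroms[[i]]]]) %/% tracks$bin_size + 1L
    n_local <- offsets[i + 1] - offsets[i]
    local[local < 1 | local > n_local] <- NA_integer_
    idx[sel] <- offsets[i] + local
  }
  idx
}

#' Quantile-normalize tracks of the same target
#'
#' Rank-based normalization across the stages of each target: read-count
#' intensities are sorted and ranked per sample and corresponding ranked
#' values are replaced by their cross-sample mean (ties receive the mean of
#' the tied ranks' reference values). Afterwards the sorted intensity
#' multisets of all samples of a target are identical. Computed with
#' [limma::normalizeQuantiles()].
#'
#' @param tracks A `chip_tracks` object.
#' @return The object with intensities replaced by their quantile-normalized
#'   values (`status = "quantile"`).
#' @export
quantile_normalize <- function(tracks) {
  stopifnot(inherits(tracks, "chip_tracks"))
  for (tg in unique(tracks$meta$target)) {
    cols <- tracks$meta$track_id[tracks$meta$target == tg]
    tracks$scores[, cols] <- limma::normalizeQuantiles(tracks$scores[, cols, drop = FALSE])
  }
  tracks$meta$status <- "quantile"
  tracks
}

#' Bring all tracks to a common scale by z-score normalization
#'
#' Each track is centred and scaled to mean 0, sd 1, so a single threshold
#' (z > 1.65, the ~95th percentile under normality) is comparable across
#' targets.
#'
#' @param tracks A `chip_tracks` object, normally quantile-normalized first.
#' @return The object with z-scaled intensities (`status = "z"`).
#' @export
zscore_scale <- function(tracks) {
  stopifnot(inherits(tracks, "chip_tracks"))
  mu <- colMeans(tracks$scores)
  sds <- apply(tracks$scores, 2, sd)
  if (any(sds == 0)) abort("zero-variance track cannot be z-scaled")
  tracks$scores <- sweep(sweep(tracks$scores, 2, mu), 2, sds, "/")
  tracks$meta$status <- "z"
  tracks
}

#' Subsampling dispersion of a peak's intensity
#'
#' Robustness check for peak signal: the read counts backing a peak are
#' randomly thinned to the stated fractions (binomial per-read retention,
#' emulating sequencing-depth subsampling), the recovered peak intensity is
#' rescaled by the sampling fraction, and dispersion is the coefficient of
#' variation (sd/mean) of the recovered intensities across all subsamples.
#' Low-count, fragile peaks disperse strongly; deep, genuine peaks barely
#' move.
#'
#' @param counts Non-negative read counts in the bins backing the peak.
#' @param fractions Subsampling fractions (defaults 0.9, 0.7, 0.5).
#' @param reps Subsample replicates per fraction.
#' @param seed Optional seed for reproducible thinning.
#' @return Dispersion as a fraction (`Inf` for an all-zero peak).
#' @export
subsample_dispersion <- function(counts, fractions = c(0.9, 0.7, 0.5),
                                 reps = 3, seed = NULL) {
  if (length(counts) == 0) abort("empty coverage at peak")
  counts <- round(counts)
  if (any(counts < 0)) abort("negative counts")
  if (sum(counts) == 0) return(Inf)
  with_seed(seed, {
    vals <- unlist(lapply(fractions, function(f) {
      vapply(seq_len(reps), function(i) sum(rbinom(length(counts), counts, f)) / f, numeric(1))
    }))
    sd(vals) / mean(vals)
  })
}

# vectorized thinning over a candidate x bin count matrix; returns CV per row
dispersion_rows <- function(count_mat, fractions, reps) {
  count_mat <- round(count_mat)
  vals <- matrix(NA_real_, nrow(count_mat), length(fractions) * reps)
  k <- 0L
  for (f in fractions) {
    for (i in seq_len(reps)) {
      k <- k + 1L
      thinned <- matrix(
        rbinom(length(count_mat), as.integer(count_mat), f),
        nrow = nrow(count_mat)
      )
      vals[, k] <- rowSums(thinned) / f
    }
  }
  out <- apply(vals, 1, sd) / rowMeans(vals)
  out[rowSums(count_mat) == 0] <- Inf
  out
}

#' Call mark presence at promoters
#'
#' A histone mark or RNA Pol II is tagged present at a gene's TSS for a given
#' stage iff all three criteria hold: (i) a peak summit lies within `window`
#' bp up- or downstream of the TSS (boundaries inclusive); (ii) the z-scaled
#' intensity of the track at the summit exceeds `zmin` (default 1.65, the 95th
#' percentile); (iii) the subsampling dispersion of the peak's raw counts is
#' below `max_dispersion`. When several peaks qualify for criterion (i) the
#' one with the highest z backs the call. The reported summit offset is signed
#' in the gene's 5'-to-3' orientation (the window itself is symmetric, so
#' strand affects reporting only).
#'
#' @param peaks Peak tibble with `target`, `stage`, `chrom`, `summit` columns
#'   (see [read_narrowpeak()]).
#' @param tracks A z-scaled `chip_tracks` object covering the same targets and
#'   stages.
#' @param tss TSS annotation from [read_tss_bed()].
#' @param genes Genes to call; all must be present in `tss`. Defaults to every
#'   annotated gene.
#' @param window Half-width of the promoter window in bp.
#' @param zmin Minimum z-score of the backing peak.
#' @param max_dispersion Maximum subsampling dispersion (fraction).
#' @param fractions,reps Passed to the dispersion check.
#' @param disp_flank Half-width (bp) of the raw-count window around the summit
#'   used for the dispersion check.
#' @param seed Optional seed making the dispersion subsampling reproducible.
#' @return A `promoter_marks` tibble: one row per gene x target x stage with
#'   `present` and the backing evidence (`offset`, `z`, `dispersion`).
#' @export
call_presence <- function(peaks, tracks, tss, genes = tss$gene_id,
                          window = 500, zmin = 1.65, max_dispersion = 0.15,
                          fractions = c(0.9, 0.7, 0.5), reps = 3,
                          disp_flank = 250, seed = NULL) {
  stopifnot(inherits(tracks, "chip_tracks"))
  if (!all(tracks$meta$status == "z")) {
    abort("tracks must be z-scaled; run quantile_normalize() then zscore_scale()")
  }
  missing_genes <- setdiff(genes, tss$gene_id)
  if (length(missing_genes)) {
    abort(paste("gene(s) without TSS annotation:", paste(head(missing_genes, 5), collapse = ", ")))
  }
  tss <- tss[match(genes, tss$gene_id), ]

  promoters <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(pmax(tss$tss - window, 0) + 1, tss$tss + window + 1)
  )
  summits <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(peaks$summit + 1, peaks$summit + 1))
  hits <- GenomicRanges::findOverlaps(summits, promoters)
  cand <- tibble(
    peak_row = S4Vectors::queryHits(hits),
    gene_row = S4Vectors::subjectHits(hits)
  ) %>%
    mutate(
      gene_id = tss$gene_id[.data$gene_row],
      strand = tss$strand[.data$gene_row],
      tss_pos = tss$tss[.data$gene_row],
      target = peaks$target[.data$peak_row],
      stage = peaks$stage[.data$peak_row],
      chrom = peaks$chrom[.data$peak_row],
      summit = peaks$summit[.data$peak_row]
    ) %>%
    filter(abs(.data$summit - .data$tss_pos) <= window)

  if (nrow(cand)) {
    track_id <- paste(cand$target, cand$stage, sep = ":")
    known <- track_id %in% tracks$meta$track_id
    if (!all(known)) {
      abort(paste("peaks reference unknown track(s):", paste(unique(track_id[!known]), collapse = ", ")))
    }
    bin_i <- bin_index(tracks, cand$chrom, cand$summit)
    cand$z <- tracks$scores[cbind(bin_i, match(track_id, tracks$meta$track_id))]

    # best candidate per gene x track backs the call
    cand <- cand %>%
      group_by(.data$gene_id, .data$target, .data$stage) %>%
      slice(which.max(.data$z)) %>%
      ungroup()

    n_flank <- as.integer(disp_flank %/% tracks$bin_size)
    bin_best <- bin_index(tracks, cand$chrom, cand$summit)
    rel <- seq(-n_flank, n_flank)
    idx <- outer(bin_best, rel, "+")
    idx[idx < 1 | idx > nrow(tracks$bins)] <- NA_integer_
    col_best <- match(paste(cand$target, cand$stage, sep = ":"), tracks$meta$track_id)
    count_mat <- matrix(0, nrow(cand), length(rel))
    for (j in seq_along(rel)) {
      ok <- !is.na(idx[, j])
      count_mat[ok, j] <- tracks$raw[cbind(idx[ok, j], col_best[ok])]
    }
    cand$dispersion <- with_seed(seed, dispersion_rows(count_mat, fractions, reps))
    cand <- cand %>%
      mutate(
        offset = dplyr::if_else(.data$strand == "-",
          .data$tss_pos - .data$summit, .data$summit - .data$tss_pos
        ),
        present = .data$z > zmin & .data$dispersion < max_dispersion
      ) %>%
      select("gene_id", "target", "stage", "present", "offset", "z", "dispersion")
  } else {
    cand <- tibble(
      gene_id = character(), target = character(), stage = character(),
      present = logical(), offset = numeric(), z = numeric(), dispersion = numeric()
    )
  }

  grid <- tidyr::expand_grid(
    gene_id = genes,
    tracks$meta %>% select("target", "stage") %>% distinct()
  )
  out <- grid %>%
    left_join(cand, by = c("gene_id", "target", "stage")) %>%
    mutate(present = !is.na(.data$present) & .data$present)
  structure(out, class = c("promoter_marks", class(out)))
}

#' The seven promoter chromatin states
#'
#' @return Character vector of the state labels.
#' @export
chromatin_states <- function() {
  c(
    "active", "weakly_active", "transcription_prone", "bivalent",
    "ambiguous", "empty", "repressed"
  )
}

#' Classify a promoter's chromatin state from five marks
#'
#' Total function over the 32 presence/absence combinations of the three
#' active histone marks (H3K4me3, H3K9ac, H3K27ac), RNA Pol II, and the
#' repressive mark H3K27me3. With A = number of active marks present, P =
#' Pol II present, R = H3K27me3 present:
#'
#' * R absent: `active` if P and A >= 2; `weakly_active` if P and A = 1;
#'   `transcription_prone` if no P and A >= 2; `ambiguous` if exactly one of
#'   (single active mark, Pol II alone); `empty` if nothing.
#' * R present: `repressed` if A = 0 and no P; otherwise `bivalent`.
#'
#' The bivalent closure (any active evidence plus H3K27me3 is bivalent)
#' extends the active/weakly-active/transcription-prone cases to single-mark
#' and Pol II-only evidence; set `bivalent_closure = FALSE` to classify those
#' eleven combinations as `ambiguous` instead.
#'
#' @param h3k4me3,h3k9ac,h3k27ac,rnapii,h3k27me3 Logical vectors (recycled to
#'   a common length).
#' @param bivalent_closure Logical; see above.
#' @return Character vector of state labels.
#' @examples
#' classify_state(TRUE, TRUE, FALSE, TRUE, FALSE) # "active"
#' classify_state(FALSE, FALSE, FALSE, FALSE, TRUE) # "repressed"
#' @export
classify_state <- function(h3k4me3, h3k9ac, h3k27ac, rnapii, h3k27me3,
                           bivalent_closure = TRUE) {
  n <- max(lengths(list(h3k4me3, h3k9ac, h3k27ac, rnapii, h3k27me3)))
  a <- rep_len(as.logical(h3k4me3), n) + rep_len(as.logical(h3k9ac), n) +
    rep_len(as.logical(h3k27ac), n)
  p <- rep_len(as.logical(rnapii), n)
  r <- rep_len(as.logical(h3k27me3), n)

  base <- dplyr::case_when(
    p & a >= 2 ~ "active",
    p & a == 1 ~ "weakly_active",
    !p & a >= 2 ~ "transcription_prone",
    (!p & a == 1) | (p & a == 0) ~ "ambiguous",
    TRUE ~ "empty"
  )
  if (bivalent_closure) {
    dplyr::case_when(
      r & (a > 0 | p) ~ "bivalent",
      r ~ "repressed",
      TRUE ~ base
    )
  } else {
    dplyr::case_when(
      r & ((p & a >= 1) | (!p & a >= 2)) ~ "bivalent",
      r & (a > 0 | p) ~ "ambiguous",
      r ~ "repressed",
      TRUE ~ base
    )
  }
}

#' Chromatin-state calls per gene and stage
#'
#' @param marks A `promoter_marks` tibble from [call_presence()].
#' @param bivalent_closure Passed to [classify_state()].
#' @return Tibble `gene_id`, `stage`, `state`, plus the observed mark
#'   combination as a 5-character presence string (K4/K9ac/K27ac/PolII/K27me3).
#' @export
state_calls <- function(marks, bivalent_closure = TRUE) {
  wide <- marks %>%
    select("gene_id", "stage", "target", "present") %>%
    tidyr::pivot_wider(names_from = "target", values_from = "present", values_fill = FALSE)
  need <- c("H3K4me3", "H3K9ac", "H3K27ac", "RNAPII", "H3K27me3")
  for (m in setdiff(need, names(wide))) wide[[m]] <- FALSE
  wide %>%
    mutate(
      state = classify_state(
        .data$H3K4me3, .data$H3K9ac, .data$H3K27ac, .data$RNAPII, .data$H3K27me3,
        bivalent_closure = bivalent_closure
      ),
      combination = paste0(
        .data$H3K4me3 + 0, .data$H3K9ac + 0, .data$H3K27ac + 0,
        .data$RNAPII + 0, .data$H3K27me3 + 0
      )
    ) %>%
    select("gene_id", "stage", "state", "combination")
}

#' Chromatin-state trajectories across the three stages
#'
#' One trajectory per gene: the ordered triple of states. Identical triples
#' form one transition cluster (at most 343 = 7^3 clusters are possible).
#'
#' @param states Tibble from [state_calls()].
#' @param stages Stage labels in biological order.
#' @return A `state_trajectories` object: tibble `gene_id`,
#'   `state_stage1..3`, `cluster` plus a `census` attribute counting genes per
#'   observed cluster.
#' @export
state_trajectories <- function(states, stages = unique(states$stage)) {
  if (length(stages) != 3) abort("exactly three stages expected")
  wide <- states %>%
    select("gene_id", "stage", "state") %>%
    tidyr::pivot_wider(names_from = "stage", values_from = "state")
  missing <- setdiff(stages, names(wide))
  if (length(missing) || anyNA(wide[stages])) {
    abort("every gene needs a state at all three stages")
  }
  out <- tibble(
    gene_id = wide$gene_id,
    state_stage1 = wide[[stages[[1]]]],
    state_stage2 = wide[[stages[[2]]]],
    state_stage3 = wide[[stages[[3]]]]
  ) %>%
    mutate(cluster = paste(.data$state_stage1, .data$state_stage2, .data$state_stage3, sep = ">"))
  census <- out %>%
    count(.data$cluster, name = "n_genes") %>%
    arrange(desc(.data$n_genes))
  structure(out, census = census, class = c("state_trajectories", class(out)))
}

#' @rdname state_trajectories
#' @param trajectories A `state_trajectories` object.
#' @export
cluster_census <- function(trajectories) {
  attr(trajectories, "census")
}

#' Median signal profile around TSSs for a gene cluster
#'
#' Per mark and stage, the median z-scaled intensity across the cluster's
#' genes in each 100-bp bin within `flank` bp of the TSS, oriented 5' to 3'
#' by gene strand.
#'
#' @param tracks A z-scaled `chip_tracks` object.
#' @param tss TSS annotation.
#' @param genes Genes in the cluster (non-empty).
#' @param flank Half-width of the profiled window in bp.
#' @return Tibble `target`, `stage`, `rel_pos` (bp, bin start relative to
#'   TSS), `median_z`.
#' @export
median_profile <- function(tracks, tss, genes, flank = 1500) {
  if (length(genes) == 0) abort("empty cluster")
  sel <- tss[match(genes, tss$gene_id), ]
  if (anyNA(sel$gene_id)) abort("cluster gene(s) missing from TSS annotation")
  n_flank <- as.integer(flank %/% tracks$bin_size)
  rel <- seq(-n_flank, n_flank)
  i0 <- bin_index(tracks, sel$chrom, sel$tss)
  idx <- outer(i0, rel, "+")
  idx[idx < 1 | idx > nrow(tracks$bins)] <- NA_integer_
  neg <- sel$strand == "-"
  idx[neg, ] <- idx[neg, rev(seq_along(rel)), drop = FALSE]

  purrr::map_dfr(seq_len(nrow(tracks$meta)), function(k) {
    col <- tracks$scores[, k]
    prof <- matrix(col[idx], nrow = nrow(idx))
    tibble(
      target = tracks$meta$target[[k]],
      stage = tracks$meta$stage[[k]],
      rel_pos = rel * tracks$bin_size,
      median_z = apply(prof, 2, median, na.rm = TRUE)
    )
  })
}

#' Write / read a promoter mark matrix
#' @param marks A `promoter_marks` tibble.
#' @param path Output TSV path.
#' @export
write_promoter_marks <- function(marks, path) {
  readr::write_tsv(as_tibble(marks), path)
  invisible(path)
}

#' @rdname write_promoter_marks
#' @export
read_promoter_marks <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  structure(x, class = c("promoter_marks", class(x)))
}
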