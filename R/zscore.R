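#' Build a regulatory-region mask from TSS sites
#'
#' Expands each (single-base) transcription start site by `flank` bp in both
#' directions, clips at chromosome bounds and merges overlaps — the region
#' set within which the background-ensemble z-score analysis operates.
#'
#' @param tss [interval_set()] of TSS positions (single-base intervals
#'   `[pos, pos + 1)`; wider intervals are flanked on both ends).
#' @param flank Expansion in bp on either side (default 100000).
#' @param layout A [genome_layout()].
#' @return Merged, sorted [interval_set()].
#' @export
regulatory_mask <- function(tss, flank = 100000L, layout) {
  stopifnot(flank >= 0L)
  validate_intervals(tss, layout)
  if (nrow(tss) == 0L) return(empty_intervals())
  len <- chrom_length(layout, tss$chrom)
  expanded <- interval_set(tss$chrom,
                           pmax(tss$start - as.integer(flank), 0L),
                           pmin(tss$end + as.integer(flank), len),
                           layout = layout)
  merge_intervals(expanded)
}

#' Normalize a track to a target total coverage
#'
#' Scales all values so the genome-wide total equals `target_total`, making
#' ensemble members and samples comparable across sequencing depths.
#'
#' @param track A [dense_track()] with positive total.
#' @param target_total Desired genome-wide total.
#' @return The scaled [dense_track()].
#' @export
normalize_by_coverage <- function(track, target_total) {
  tot <- track_total(track)
  if (tot <= 0) stop("cannot normalize a zero-total track")
  f <- target_total / tot
  dense_track(track$layout, lapply(track$values, function(v) v * f))
}

#' Per-base background statistics over an ensemble of tracks
#'
#' Computes, for every base inside the mask, the sample mean and standard
#' deviation of coverage across `B >= 2` (normalized) background tracks.
#'
#' @param background_tracks List of [dense_track()]s on one layout.
#' @param mask [interval_set()] restricting the computation.
#' @return A `background_ensemble`: layout, mask, per-chromosome `mu` and
#'   `sigma` dense vectors (zero outside the mask), mask logicals, and `B`.
#' @export
ensemble_stats <- function(background_tracks, mask) {
  B <- length(background_tracks)
  if (B < 2L) stop("need at least 2 background tracks")
  layout <- background_tracks[[1]]$layout
  for (tr in background_tracks) {
    if (!identical(tr$layout, layout)) stop("ensemble layout mismatch")
  }
  ml <- mask_logical(mask, layout)
  mu <- lapply(stats::setNames(layout$length, layout$chrom), numeric)
  sigma <- mu
  for (ch in layout$chrom) {
    sel <- ml[[ch]]
    if (!any(sel)) next
    m <- do.call(rbind, lapply(background_tracks,
                               function(tr) tr$values[[ch]][sel]))
    cm <- colMeans(m)
    cs <- sqrt(colSums(sweep(m, 2, cm)^2) / (B - 1))
    mu[[ch]][sel] <- cm
    sigma[[ch]][sel] <- cs
  }
  structure(list(layout = layout, mask = mask, mask_logical = ml,
                 mu = mu, sigma = sigma, B = B),
            class = "background_ensemble")
}

#' Per-base z-scores of a sample against a background ensemble
#'
#' `z = (x - mu) / sigma` on masked bases with `sigma > 0`; bases with
#' `sigma = 0` get `z = 0` (their count is attached as attribute
#' `sigma_zero`), and everything outside the mask is 0. The sample track
#' should be normalized to the same total as the ensemble members.
#'
#' @param sample_track Normalized sample [dense_track()].
#' @param ensemble A `background_ensemble` from [ensemble_stats()].
#' @return A [dense_track()] of z-scores.
#' @export
zscore_track <- function(sample_track, ensemble) {
  if (!identical(sample_track$layout, ensemble$layout)) {
    stop("sample and ensemble layouts differ")
  }
  n_zero <- 0L
  vals <- stats::setNames(
    lapply(ensemble$layout$chrom, function(ch) {
      z <- numeric(length(sample_track$values[[ch]]))
      sel <- ensemble$mask_logical[[ch]]
      s <- ensemble$sigma[[ch]]
      ok <- sel & s > 0
      n_zero <<- n_zero + sum(sel & s == 0)
      z[ok] <- (sample_track$values[[ch]][ok] - ensemble$mu[[ch]][ok]) / s[ok]
      z
    }), ensemble$layout$chrom)
  out <- dense_track(ensemble$layout, vals)
  attr(out, "sigma_zero") <- n_zero
  out
}

#' Call significantly differential regions from a z-score track
#'
#' Selects bases with `|z| > z_cut`, merges selected bases within
#' `merge_dist` bp of each other into regions, assigns each region the
#' signed z of the maximal `|z|` (leftmost tie), converts to two-sided
#' normal p-values, applies Benjamini-Hochberg across all regions and keeps
#' `q < fdr`, then drops regions whose maximum sample coverage is below
#' `min_coverage`.
#'
#' @param z_track Z-score [dense_track()] from [zscore_track()].
#' @param sample_track The (normalized) sample coverage [dense_track()].
#' @param z_cut Absolute z threshold (default 2).
#' @param merge_dist Merge distance in bp (default 200).
#' @param fdr FDR threshold (default 0.05).
#' @param min_coverage Minimum sample coverage in a region (default 1
#'   normalized read-unit).
#' @return data.frame of region calls: chrom, start, end, peak_z, p, q,
#'   max_cov; sorted and disjoint.
#' @export
call_significant_regions <- function(z_track, sample_track, z_cut = 2,
                                     merge_dist = 200L, fdr = 0.05,
                                     min_coverage = 1) {
  stopifnot(identical(z_track$layout, sample_track$layout))
  parts <- list()
  for (ch in z_track$layout$chrom) {
    z <- z_track$values[[ch]]
    pos <- which(abs(z) > z_cut) - 1L  # 0-based qualifying bases
    if (length(pos) == 0L) next
    brk <- which(diff(pos) > merge_dist)
    seg_s <- pos[c(1L, brk + 1L)]
    seg_e <- pos[c(brk, length(pos))] + 1L
    pz <- numeric(length(seg_s)); mc <- numeric(length(seg_s))
    for (i in seq_along(seg_s)) {
      zz <- z[(seg_s[i] + 1L):seg_e[i]]
      pz[i] <- zz[which.max(abs(zz))]
      mc[i] <- max(sample_track$values[[ch]][(seg_s[i] + 1L):seg_e[i]])
    }
    parts[[ch]] <- data.frame(chrom = ch, start = seg_s, end = seg_e,
                              peak_z = pz, max_cov = mc,
                              stringsAsFactors = FALSE)
  }
  if (length(parts) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      peak_z = numeric(), p = numeric(), q = numeric(),
                      max_cov = numeric(), stringsAsFactors = FALSE))
  }
  calls <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  calls$p <- 2 * stats::pnorm(abs(calls$peak_z), lower.tail = FALSE)
  calls$q <- stats::p.adjust(calls$p, method = "BH")
  calls <- calls[calls$q < fdr & calls$max_cov >= min_coverage, , drop = FALSE]
  rownames(calls) <- NULL
  calls[, c("chrom", "start", "end", "peak_z", "p", "q", "max_cov")]
}
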