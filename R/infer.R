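#' Denoise a genome with a trained model
#'
#' Tiles the genome, runs the model forward on each padded window, and
#' keeps only the central interval of each output, so every base is
#' predicted exactly once. With `pad` at least half the model's receptive
#' field, the stitched result equals a whole-chromosome forward pass.
#'
#' @param model A `trained_model`.
#' @param noisy_track Noisy coverage [dense_track()].
#' @param extra_channels List of additional input [dense_track()]s (must
#'   match the model's channel count).
#' @param tiling A [tiling_spec()]; a warning is issued when `pad` is
#'   smaller than half the receptive field of the probability output.
#' @return List with `denoised` (nonnegative [dense_track()]) and `prob`
#'   (probability [dense_track()] in (0, 1)).
#' @export
denoise_genome <- function(model, noisy_track, extra_channels = list(),
                           tiling = tiling_spec()) {
  stopifnot(inherits(model, "trained_model"),
            inherits(noisy_track, "dense_track"))
  if (1L + length(extra_channels) != model$config$in_channels) {
    stop("model expects ", model$config$in_channels, " channels, got ",
         1L + length(extra_channels))
  }
  half_rf <- (full_receptive_field(model$config) - 1L) %/% 2L
  if (tiling$pad < half_rf) {
    warning("tiling pad (", tiling$pad, ") is smaller than half the ",
            "receptive field (", half_rf, "); window boundaries may show ",
            "edge effects")
  }
  layout <- noisy_track$layout
  tiles <- tile_genome(layout, tiling)
  den <- lapply(stats::setNames(layout$length, layout$chrom), numeric)
  prb <- lapply(stats::setNames(layout$length, layout$chrom), numeric)
  pad <- tiling$pad
  for (i in seq_len(nrow(tiles))) {
    ch <- tiles$chrom[i]
    s <- tiles$start[i]; e <- tiles$end[i]
    len <- chrom_length(layout, ch)
    # clip the padded window at the chromosome so boundary behavior matches
    # a whole-chromosome forward pass (per-layer zero padding)
    lo <- max(0L, s - pad); hi <- min(len, e + pad)
    rng <- (lo + 1L):hi
    X <- do.call(cbind, c(list(noisy_track$values[[ch]][rng]),
                          lapply(extra_channels,
                                 function(tr) tr$values[[ch]][rng])))
    fwd <- nn_forward(model$params, model$config, X)
    central <- (s - lo + 1L):(e - lo)
    idx <- (s + 1L):e
    den[[ch]][idx] <- as.numeric(fwd$signal)[central]
    prb[[ch]][idx] <- as.numeric(fwd$prob)[central]
  }
  list(denoised = dense_track(layout, den), prob = dense_track(layout, prb))
}

#' Call segments from a per-base score or probability track
#'
#' Bases with value strictly greater than `threshold` form runs; runs
#' separated by at most `max_gap` bp are merged; merged runs shorter than
#' `min_len` are discarded. Each surviving segment is annotated with its
#' maximum value and the leftmost position attaining it (the summit). The
#' same procedure produces training labels from -log10 p-value tracks
#' (threshold 3) and peak calls from probability tracks (threshold 0.5).
#'
#' @param track A [dense_track()].
#' @param threshold Inclusion threshold (strict inequality).
#' @param min_len Minimum segment length in bp (default 200).
#' @param max_gap Maximum gap merged into one segment (default 30).
#' @return An [interval_set()] with `score` (max value) and a `summit`
#'   column (absolute 0-based position of the leftmost maximum).
#' @export
call_segments <- function(track, threshold, min_len = 200L, max_gap = 30L) {
  stopifnot(inherits(track, "dense_track"), min_len >= 1L, max_gap >= 0L)
  parts <- list()
  for (ch in track$layout$chrom) {
    v <- track$values[[ch]]
    r <- rle(v > threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    rs <- starts[r$values]; re <- ends[r$values]
    if (length(rs) == 0L) next
    # merge runs whose separating gap is <= max_gap
    ms <- rs[1]; me <- re[1]
    seg_s <- integer(); seg_e <- integer()
    for (i in seq_along(rs)[-1]) {
      if (rs[i] - me <= max_gap) me <- re[i] else {
        seg_s <- c(seg_s, ms); seg_e <- c(seg_e, me); ms <- rs[i]; me <- re[i]
      }
    }
    seg_s <- c(seg_s, ms); seg_e <- c(seg_e, me)
    keep <- (seg_e - seg_s) >= min_len
    seg_s <- seg_s[keep]; seg_e <- seg_e[keep]
    if (length(seg_s) == 0L) next
    summit <- integer(length(seg_s)); mx <- numeric(length(seg_s))
    for (i in seq_along(seg_s)) {
      w <- v[(seg_s[i] + 1L):seg_e[i]]
      j <- which.max(w)  # leftmost maximum
      summit[i] <- seg_s[i] + j - 1L
      mx[i] <- w[j]
    }
    parts[[ch]] <- data.frame(chrom = ch, start = seg_s, end = seg_e,
                              score = mx, summit = summit,
                              stringsAsFactors = FALSE)
  }
  if (length(parts) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric(), summit = integer(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  }
  structure(out, class = c("interval_set", "data.frame"))
}

#' Call peaks from a probability track
#'
#' Convenience wrapper: [call_segments()] on the per-base peak-probability
#' track at the standard 0.5 cutoff.
#'
#' @param prob_track Probability [dense_track()] (e.g. from
#'   [denoise_genome()]).
#' @param threshold Probability cutoff (default 0.5).
#' @param min_len,max_gap Passed to [call_segments()].
#' @return An [interval_set()] of peaks with summit and max-probability.
#' @export
call_peaks <- function(prob_track, threshold = 0.5, min_len = 200L,
                       max_gap = 30L) {
  call_segments(prob_track, threshold = threshold, min_len = min_len,
                max_gap = max_gap)
}
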