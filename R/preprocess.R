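#' Convert reads to Tn5 cut sites
#'
#' Each read is reduced to the single genomic position of its first aligned
#' base, shifted to the Tn5 insertion center: +4 bp on the plus strand and
#' -5 bp from the rightmost aligned base (`end - 1` in half-open
#' coordinates) on the minus strand, the standard correction for the 9 bp
#' duplication created by Tn5. Sites shifted outside the chromosome are
#' clipped to its boundary.
#'
#' @param reads Read data.frame (chrom, start, end, strand).
#' @param layout A [genome_layout()].
#' @param plus_offset Offset added to plus-strand starts (default +4).
#' @param minus_offset Offset added to minus-strand first bases (default -5).
#' @return data.frame of cut sites (chrom, pos, strand), 0-based.
#' @export
cut_sites_from_reads <- function(reads, layout, plus_offset = 4L,
                                 minus_offset = -5L) {
  if (nrow(reads) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  if (!all(reads$strand %in% c("+", "-"))) {
    stop("unknown strand: ", setdiff(unique(reads$strand), c("+", "-"))[1])
  }
  pos <- ifelse(reads$strand == "+",
                reads$start + plus_offset,
                (reads$end - 1L) + minus_offset)
  len <- chrom_length(layout, reads$chrom)
  pos <- pmax(0L, pmin(as.integer(pos), len - 1L))
  data.frame(chrom = reads$chrom, pos = pos, strand = reads$strand,
             stringsAsFactors = FALSE)
}

#' Build a coverage track from extended cut sites
#'
#' Every cut site adds +1 over the `2 * extension + 1` bases centered on it
#' (inclusive on both sides), truncated at chromosome boundaries;
#' overlapping windows sum.
#'
#' @param sites Cut-site data.frame (chrom, pos).
#' @param extension Extension in bp on either side (>= 0); 100 for standard
#'   accessibility tracks, 5 for footprinting-resolution tracks.
#' @param layout A [genome_layout()].
#' @return A [dense_track()] of per-base counts.
#' @export
coverage_from_cutsites <- function(sites, extension, layout) {
  stopifnot(extension >= 0)
  extension <- as.integer(extension)
  vals <- lapply(stats::setNames(layout$length, layout$chrom), numeric)
  for (ch in unique(sites$chrom)) {
    len <- chrom_length(layout, ch)
    pos <- sites$pos[sites$chrom == ch]
    if (any(pos < 0L | pos >= len)) stop("cut site outside chromosome ", ch)
    # difference array: +1 at window start, -1 one past window end
    lo <- pmax(pos - extension, 0L)
    hi <- pmin(pos + extension + 1L, len)
    d <- numeric(len + 1L)
    add <- tabulate(lo + 1L, nbins = len + 1L)
    sub <- tabulate(hi + 1L, nbins = len + 1L)
    vals[[ch]] <- as.numeric(cumsum(add - sub))[seq_len(len)]
  }
  dense_track(layout, vals)
}

#' Per-base Poisson -log10 p-value scores
#'
#' Scores each base of a clean coverage track against a uniform Poisson
#' background: `score = -log10 P(X >= round(obs))` for `X ~ Poisson(lambda)`.
#' The default `lambda` is the genome-wide mean of the track, i.e. the
#' equal-coverage control a peak caller would be given. Observed values are
#' rounded to integers before the tail probability; scores are capped.
#'
#' @param clean_track A nonnegative [dense_track()].
#' @param lambda Background rate (> 0); default genome-wide mean.
#' @param cap Maximum score (default 350, a double-underflow guard).
#' @return A [dense_track()] of -log10 p-values.
#' @export
poisson_label_scores <- function(clean_track, lambda = NULL, cap = 350) {
  stopifnot(inherits(clean_track, "dense_track"))
  if (is.null(lambda)) {
    lambda <- track_total(clean_track) /
      sum(as.numeric(clean_track$layout$length))
  }
  if (!(lambda > 0)) stop("lambda must be > 0")
  vals <- lapply(clean_track$values, function(v) {
    if (any(v < 0)) stop("clean track must be nonnegative")
    k <- round(v)
    uk <- sort(unique(k))
    # -log10 P(X >= k); k = 0 gives 0 exactly
    s <- -stats::ppois(uk - 1, lambda, lower.tail = FALSE, log.p = TRUE) / log(10)
    s <- pmin(s, cap)
    s[match(k, uk)]
  })
  dense_track(clean_track$layout, vals)
}

#' Label peaks by thresholding a score track
#'
#' Thresholds a -log10 p-value track at `cutoff` and merges/filters runs via
#' the shared segment caller ([call_segments()]); the result is the source
#' of binary training labels.
#'
#' @param score_track A [dense_track()] of scores.
#' @param cutoff Score threshold (default 3, i.e. p < 1e-3).
#' @param min_len Minimum labeled interval length in bp (default 200).
#' @param max_gap Merge runs separated by at most this many bp (default 30).
#' @return An [interval_set()] of labeled peak intervals.
#' @export
label_peaks <- function(score_track, cutoff = 3, min_len = 200L,
                        max_gap = 30L) {
  calls <- call_segments(score_track, threshold = cutoff, min_len = min_len,
                         max_gap = max_gap)
  if (nrow(calls) == 0L) return(empty_intervals())
  interval_set(calls$chrom, calls$start, calls$end,
               layout = score_track$layout)
}

#' Genome tiling specification
#' @param interval_len Central interval length in bp (default 50000).
#' @param pad Padding added on either side of each interval (default 5000).
#' @return A `tiling_spec` object.
#' @export
tiling_spec <- function(interval_len = 50000L, pad = 5000L) {
  stopifnot(interval_len > 0L, pad >= 0L)
  structure(list(interval_len = as.integer(interval_len),
                 pad = as.integer(pad)), class = "tiling_spec")
}

#' Tile a genome into non-overlapping central intervals
#'
#' Each chromosome is split into consecutive intervals of
#' `tiling$interval_len` bp; the final partial interval is kept, so the
#' tiling is an exact partition of the genome.
#'
#' @param layout A [genome_layout()].
#' @param tiling A [tiling_spec()].
#' @param exclude_chroms Chromosomes to skip.
#' @return An [interval_set()] of central (unpadded) intervals.
#' @export
tile_genome <- function(layout, tiling = tiling_spec(),
                        exclude_chroms = character()) {
  stopifnot(inherits(tiling, "tiling_spec"))
  L <- tiling$interval_len
  parts <- list()
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]
    if (ch %in% exclude_chroms) next
    len <- layout$length[i]
    start <- seq.int(0L, len - 1L, by = L)
    parts[[ch]] <- data.frame(chrom = ch, start = start,
                              end = pmin(start + L, len),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  structure(out, class = c("interval_set", "data.frame"))
}

# values of a track window [lo, hi) in 0-based coords, zero-filled outside
# the chromosome
window_values <- function(v, lo, hi) {
  n <- hi - lo
  out <- numeric(n)
  a <- max(lo, 0L); b <- min(hi, length(v))
  if (b > a) out[(a - lo + 1L):(b - lo)] <- v[(a + 1L):b]
  out
}

#' Extract padded training windows
#'
#' For each tiling interval, builds the padded window
#' `[start - pad, end + pad)` with zero fill beyond chromosome bounds, and
#' assembles the model input channels (noisy coverage first, then any extra
#' channels such as strand-specific motif indicators), the clean target
#' signal, and the 0/1 rasterization of the label intervals.
#'
#' @param noisy_track Noisy coverage [dense_track()] (input channel 0).
#' @param clean_track Clean target [dense_track()], or `NULL` at inference.
#' @param label_intervals [interval_set()] of peak labels, or `NULL`.
#' @param extra_channels List of additional [dense_track()]s (e.g. from
#'   [motif_channels()]).
#' @param tiling A [tiling_spec()].
#' @param intervals Tiling intervals (default: [tile_genome()] of the
#'   track's layout).
#' @return List of training examples; each has `chrom`, `start`, `end`
#'   (central interval), `input` (W x C matrix, one column per channel,
#'   noisy coverage first), `target` (length-W numeric or NULL) and
#'   `labels` (length-W 0/1 or NULL), W = interval_len + 2*pad.
#' @export
extract_examples <- function(noisy_track, clean_track = NULL,
                             label_intervals = NULL,
                             extra_channels = list(),
                             tiling = tiling_spec(), intervals = NULL) {
  layout <- noisy_track$layout
  if (!is.null(clean_track) && !identical(clean_track$layout, layout)) {
    stop("noisy and clean tracks have different layouts")
  }
  for (tr in extra_channels) {
    if (!identical(tr$layout, layout)) stop("extra channel layout mismatch")
  }
  if (is.null(intervals)) intervals <- tile_genome(layout, tiling)
  label_track <- if (!is.null(label_intervals)) {
    rasterize_intervals(label_intervals, layout)
  }
  pad <- tiling$pad
  lapply(seq_len(nrow(intervals)), function(i) {
    ch <- intervals$chrom[i]
    s <- intervals$start[i]; e <- intervals$end[i]
    lo <- s - pad; hi <- e + pad
    chans <- c(list(window_values(noisy_track$values[[ch]], lo, hi)),
               lapply(extra_channels,
                      function(tr) window_values(tr$values[[ch]], lo, hi)))
    list(chrom = ch, start = s, end = e,
         input = do.call(cbind, chans),
         target = if (!is.null(clean_track)) {
           window_values(clean_track$values[[ch]], lo, hi)
         },
         labels = if (!is.null(label_track)) {
           window_values(label_track$values[[ch]], lo, hi)
         })
  })
}

#' Binary motif-position channels
#'
#' Rasterizes forward- and reverse-strand motif site intervals into two 0/1
#' tracks, the extra input channels used for cross-modality prediction
#' (e.g. predicting CTCF occupancy from accessibility plus motif locations).
#'
#' @param fwd_sites,rev_sites [interval_set()]s of motif sites by strand.
#' @param layout A [genome_layout()].
#' @return List of two binary [dense_track()]s named `fwd` and `rev`.
#' @export
motif_channels <- function(fwd_sites, rev_sites, layout) {
  list(fwd = rasterize_intervals(fwd_sites, layout),
       rev = rasterize_intervals(rev_sites, layout))
}
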