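#' Specification for a synthetic ATAC-seq fixture genome
#'
#' Describes a genome with non-overlapping enriched peak regions over a
#' uniform background, from which reads (as Tn5 cut-site anchors) are drawn.
#' Everything downstream of the spec is deterministic given `seed`.
#'
#' The defaults describe a desk-scale fixture: two chromosomes of 1.5 Mb,
#' 60 peaks of 500-2000 bp per chromosome, per-peak read-rate enrichments
#' drawn log-uniformly from 2-20x (real accessibility peaks have a
#' long-tailed strength distribution, so a fixture with many weak peaks is
#' what makes peak classification non-trivial), and 200,000 reads, so that
#' a small model trains on one CPU in minutes while keeping realistic peak
#' geometry (peaks cover a few percent of the genome at elevated rate, as
#' in ATAC-seq libraries).
#'
#' @param layout A [genome_layout()].
#' @param n_peaks Peaks per chromosome.
#' @param peak_width Length-2 vector, min/max peak width in bp.
#' @param enrichment Read-rate multiplier inside peaks (>= 1): a single
#'   value applied to every peak, or a length-2 range from which per-peak
#'   multipliers are drawn log-uniformly.
#' @param n_reads Total reads drawn across the genome.
#' @param read_length Fixed read length in bp.
#' @param thinning_p Default thinning probability for the noisy counterpart.
#' @param n_cells If not `NULL`, reads carry barcodes drawn uniformly from
#'   this many cells (aggregate / single-cell mode).
#' @param motif_width,n_motifs Motif geometry for the cross-modality /
#'   footprinting fixture (see [simulate_footprint_tracks()]).
#' @param seed Integer seed; same spec + seed gives byte-identical output.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(layout = genome_layout(c("chrA", "chrB"),
                                                  c(1500000L, 1500000L)),
                           n_peaks = 60L,
                           peak_width = c(500L, 2000L),
                           enrichment = c(2, 20),
                           n_reads = 200000L,
                           read_length = 50L,
                           thinning_p = 0.1,
                           n_cells = NULL,
                           motif_width = 20L,
                           n_motifs = 30L,
                           seed = 1L) {
  stopifnot(inherits(layout, "genome_layout"),
            n_peaks >= 0L, length(peak_width) == 2L,
            peak_width[1] <= peak_width[2], peak_width[1] >= 1L,
            length(enrichment) %in% 1:2, all(enrichment >= 1),
            n_reads >= 0L, read_length >= 1L,
            thinning_p > 0, thinning_p <= 1)
  structure(list(layout = layout, n_peaks = as.integer(n_peaks),
                 peak_width = as.integer(peak_width), enrichment = enrichment,
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 thinning_p = thinning_p,
                 n_cells = if (is.null(n_cells)) NULL else as.integer(n_cells),
                 motif_width = as.integer(motif_width),
                 n_motifs = as.integer(n_motifs), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# non-overlapping peak placement by rejection sampling with a retry cap
place_peaks <- function(layout, n_peaks, peak_width, max_tries = 1000L) {
  out <- list()
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]; len <- layout$length[i]
    starts <- integer(); ends <- integer()
    for (k in seq_len(n_peaks)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        w <- sample.int(peak_width[2] - peak_width[1] + 1L, 1L) +
          peak_width[1] - 1L
        if (w >= len) next
        s <- sample.int(len - w, 1L) - 1L
        e <- s + w
        if (!any(s < ends & e > starts)) {
          starts <- c(starts, s); ends <- c(ends, e); placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place ", n_peaks, " non-overlapping peaks on ", ch,
             " after ", max_tries, " tries each")
      }
    }
    o <- order(starts)
    out[[ch]] <- data.frame(chrom = ch, start = starts[o], end = ends[o],
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  structure(df, class = c("interval_set", "data.frame"))
}

#' Simulate reads from a peak-enriched genome
#'
#' Read start positions follow a mixture: uniform over the chromosome at
#' the background rate, plus, inside each truth peak, extra mass raising
#' that peak's rate to its enrichment multiplier. Strands are
#' Bernoulli(0.5); read length is fixed (clipped at the chromosome end).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `reads` (data.frame: chrom, start, end, strand, and
#'   barcode when `n_cells` is set) and `truth_peaks` (an [interval_set()]
#'   with a `score` column holding each peak's enrichment).
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    peaks <- if (spec$n_peaks > 0L) {
      place_peaks(spec$layout, spec$n_peaks, spec$peak_width)
    } else empty_intervals()
    if (nrow(peaks) > 0L) {
      e <- spec$enrichment
      peaks$score <- if (length(e) == 1L) rep(e, nrow(peaks)) else {
        exp(stats::runif(nrow(peaks), log(e[1]), log(e[2])))
      }
    }
    layout <- spec$layout
    # per-chromosome rate mass: len (uniform background over everything)
    # plus (e_i - 1) * width_i of extra mass per peak
    extra <- vapply(layout$chrom, function(ch) {
      p <- peaks[peaks$chrom == ch, , drop = FALSE]
      if (nrow(p) == 0L) 0 else sum((p$score - 1) * (p$end - p$start))
    }, numeric(1))
    mass <- layout$length + extra
    n_by_chrom <- as.vector(stats::rmultinom(1, spec$n_reads, mass))
    rows <- vector("list", nrow(layout))
    for (i in seq_len(nrow(layout))) {
      ch <- layout$chrom[i]; len <- layout$length[i]; n <- n_by_chrom[i]
      if (n == 0L) next
      p <- peaks[peaks$chrom == ch, , drop = FALSE]
      prob_peak <- extra[[ch]] / mass[[ch]]
      in_peak <- stats::runif(n) < prob_peak
      pos <- integer(n)
      pos[!in_peak] <- sample.int(len, sum(!in_peak), replace = TRUE) - 1L
      if (any(in_peak) && nrow(p) > 0L) {
        # pick a peak proportional to its extra mass, then uniform within
        wts <- (p$score - 1) * (p$end - p$start)
        j <- sample.int(nrow(p), sum(in_peak), replace = TRUE, prob = wts)
        w <- p$end[j] - p$start[j]
        pos[in_peak] <- p$start[j] +
          as.integer(floor(stats::runif(sum(in_peak)) * w))
      }
      start <- pmin(pos, len - 1L)
      end <- pmin(start + spec$read_length, len)
      strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
      d <- data.frame(chrom = ch, start = start, end = end, strand = strand,
                      stringsAsFactors = FALSE)
      if (!is.null(spec$n_cells)) {
        d$barcode <- sprintf("cell%04d", sample.int(spec$n_cells, n,
                                                    replace = TRUE))
      }
      rows[[i]] <- d[order(d$start), , drop = FALSE]
    }
    reads <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                              list(make.row.names = FALSE)))
    if (is.null(reads)) {
      reads <- data.frame(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          stringsAsFactors = FALSE)
    }
    list(reads = reads, truth_peaks = peaks)
  })
}

#' Thin reads by independent Bernoulli sampling
#'
#' Emulates downsampling a library to a fraction `p` of its reads. With
#' `pair_aware`, reads sharing a `pair_id` are kept or dropped together, so
#' read pairs are never split.
#'
#' @param reads Read data.frame (needs a `pair_id` column when `pair_aware`).
#' @param p Keep probability in (0, 1].
#' @param seed Integer seed.
#' @param pair_aware Keep/drop whole pairs (default FALSE).
#' @return The kept reads, original order preserved.
#' @export
thin_reads <- function(reads, p, seed = 1L, pair_aware = FALSE) {
  if (!(p > 0 && p <= 1)) stop("thinning probability must be in (0, 1]")
  if (p == 1) return(reads)
  withr::with_seed(as.integer(seed), {
    if (pair_aware) {
      if (is.null(reads$pair_id)) stop("pair_aware thinning needs a pair_id column")
      ids <- unique(reads$pair_id)
      keep_ids <- ids[stats::runif(length(ids)) < p]
      reads[reads$pair_id %in% keep_ids, , drop = FALSE]
    } else {
      reads[stats::runif(nrow(reads)) < p, , drop = FALSE]
    }
  })
}

#' Sample whole cells from barcoded reads
#'
#' Draws `n_cells` barcodes uniformly without replacement and returns all
#' and only their reads (the aggregate used for low-coverage single-cell
#' fixtures; repeated with different seeds to build diverse subsamples).
#'
#' @param reads Read data.frame with a `barcode` column.
#' @param n_cells Number of barcodes to keep.
#' @param seed Integer seed.
#' @return The selected reads, original order preserved.
#' @export
sample_cells <- function(reads, n_cells, seed = 1L) {
  if (is.null(reads$barcode)) stop("reads have no barcode column")
  bcs <- unique(reads$barcode)
  if (length(bcs) < n_cells) {
    stop("only ", length(bcs), " distinct barcodes, need ", n_cells)
  }
  withr::with_seed(as.integer(seed), {
    keep <- sample(bcs, n_cells)
    reads[reads$barcode %in% keep, , drop = FALSE]
  })
}

#' Simulate clean tracks with transcription-factor footprints
#'
#' Builds a deterministic clean coverage track of flat peak plateaus over a
#' low background, carves a dip of configurable depth at the center of each
#' motif site (the accessibility footprint of a bound factor), and returns
#' the motif locations split by strand for use as extra input channels.
#'
#' @param spec A [synthetic_spec()]; uses `motif_width`, `n_motifs`,
#'   `peak_width`, `enrichment` and `seed`.
#' @param dip Dip factor in `[0, 1]`: coverage at the motif center is
#'   `dip` times the plateau (1 = no dip, 0 = zero at the center), with a
#'   triangular profile across the motif.
#' @param background Background coverage level (default 1).
#' @return List with `clean` ([dense_track()]), `fwd` and `rev` motif
#'   [interval_set()]s, and `peaks`.
#' @export
simulate_footprint_tracks <- function(spec, dip = 0.3, background = 1) {
  stopifnot(inherits(spec, "synthetic_spec"), dip >= 0, dip <= 1)
  if (spec$motif_width >= spec$peak_width[1]) {
    stop("motif width must be smaller than the minimum peak width")
  }
  withr::with_seed(spec$seed + 1L, {
    peaks <- place_peaks(spec$layout, max(spec$n_peaks, 1L), spec$peak_width)
    vals <- lapply(stats::setNames(chrom_lengths(spec$layout),
                                   spec$layout$chrom),
                   function(n) rep(background, n))
    height <- background * exp(mean(log(spec$enrichment)))
    for (i in seq_len(nrow(peaks))) {
      ch <- peaks$chrom[i]
      vals[[ch]][(peaks$start[i] + 1L):peaks$end[i]] <- height
    }
    # one motif per selected peak, centered, alternating strand
    n_mot <- min(spec$n_motifs, nrow(peaks))
    idx <- sort(sample.int(nrow(peaks), n_mot))
    w <- spec$motif_width
    ms <- integer(n_mot); mch <- character(n_mot)
    for (k in seq_len(n_mot)) {
      i <- idx[k]
      center <- (peaks$start[i] + peaks$end[i]) %/% 2L
      s <- center - w %/% 2L
      ms[k] <- s; mch[k] <- peaks$chrom[i]
      half <- (w - 1) / 2
      rel <- abs(seq_len(w) - 1 - half) / max(half, 1)  # 0 at center, 1 at edge
      factor <- dip + (1 - dip) * rel
      vals[[mch[k]]][(s + 1L):(s + w)] <- vals[[mch[k]]][(s + 1L):(s + w)] * factor
    }
    strand <- rep_len(c("+", "-"), n_mot)
    fwd <- strand == "+"
    mk <- function(sel) {
      if (!any(sel)) return(empty_intervals())
      interval_set(mch[sel], ms[sel], ms[sel] + w, layout = spec$layout)
    }
    list(clean = dense_track(spec$layout, vals), fwd = mk(fwd), rev = mk(!fwd),
         peaks = peaks)
  })
}

#' Write a read table as TSV
#' @param reads Read data.frame (chrom, start, end, strand, optional barcode).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_reads <- function(reads, path) {
  data.table::fwrite(reads, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read a read table written by [write_reads()]
#' @param path TSV with columns chrom, start, end, strand (optional barcode).
#' @return Read data.frame.
#' @export
read_reads <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}
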