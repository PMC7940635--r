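#' Genome layout
#'
#' An ordered table of chromosome names and lengths. The order is stable and
#' defines iteration order for every track, tiling and output writer in the
#' package. All coordinates in the package are 0-based half-open.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp (all >= 1).
#' @return A `genome_layout` object (a data.frame with columns `chrom`,
#'   `length`).
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1000, 500))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.integer(length)
  if (length(chrom) == 0L) stop("no chromosomes")
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome name: ", chrom[duplicated(chrom)][1])
  }
  if (anyNA(length) || any(length < 1L)) stop("chromosome lengths must be >= 1")
  structure(
    data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
    class = c("genome_layout", "data.frame")
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x), " chromosome(s), ",
      format(sum(as.numeric(x$length)), big.mark = ","), " bp\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Named vector of chromosome lengths
#' @param layout A `genome_layout`.
#' @return Named integer vector.
#' @export
chrom_lengths <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  stats::setNames(layout$length, layout$chrom)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("chromosome not in layout: ", chrom[is.na(i)][1])
  layout$length[i]
}

#' Dense per-base track
#'
#' Holds one numeric value per base for every chromosome of a layout
#' (coverage, peak probabilities, label scores, z-scores, ...).
#'
#' @param layout A `genome_layout`.
#' @param values Optional named list of numeric vectors, one per chromosome,
#'   each of length equal to the chromosome length. Defaults to all zeros.
#' @return A `dense_track` object.
#' @export
dense_track <- function(layout, values = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  if (is.null(values)) {
    values <- lapply(stats::setNames(layout$length, layout$chrom), numeric)
  } else {
    if (!setequal(names(values), layout$chrom)) {
      stop("track values must be named by the layout chromosomes")
    }
    values <- values[layout$chrom]
    for (i in seq_len(nrow(layout))) {
      v <- values[[i]]
      if (length(v) != layout$length[i]) {
        stop("value vector for ", layout$chrom[i], " has length ", length(v),
             ", expected ", layout$length[i])
      }
      if (!all(is.finite(v))) stop("non-finite value in track on ", layout$chrom[i])
    }
  }
  structure(list(layout = layout, values = values), class = "dense_track")
}

#' @export
print.dense_track <- function(x, ...) {
  cat("<dense_track> over ", nrow(x$layout), " chromosome(s); total = ",
      format(track_total(x)), "\n", sep = "")
  invisible(x)
}

#' Genome-wide sum of a track
#' @param track A `dense_track`.
#' @return Numeric scalar.
#' @export
track_total <- function(track) {
  stopifnot(inherits(track, "dense_track"))
  sum(vapply(track$values, sum, numeric(1)))
}

#' Interval set
#'
#' Half-open 0-based genomic intervals with optional name and score columns;
#' the container for peaks, motif sites, TSS flanks and tiling intervals.
#'
#' @param chrom,start,end Vectors defining the intervals (start < end).
#' @param name Optional character labels.
#' @param score Optional numeric scores.
#' @param layout Optional `genome_layout`; when given, intervals are checked
#'   against chromosome bounds.
#' @return An `interval_set` (data.frame with columns `chrom`, `start`,
#'   `end`, and optionally `name`, `score`).
#' @export
interval_set <- function(chrom, start, end, name = NULL, score = NULL,
                         layout = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  validate_intervals(df, layout)
  structure(df, class = c("interval_set", "data.frame"))
}

validate_intervals <- function(df, layout = NULL) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1]
    stop("interval with start >= end: ", df$chrom[bad], ":", df$start[bad],
         "-", df$end[bad])
  }
  if (any(df$start < 0L)) stop("interval with negative start")
  if (!is.null(layout)) {
    len <- chrom_length(layout, df$chrom)
    if (any(df$end > len)) {
      bad <- which(df$end > len)[1]
      stop("interval beyond chromosome end: ", df$chrom[bad], ":",
           df$start[bad], "-", df$end[bad])
    }
  }
  invisible(df)
}

empty_intervals <- function() {
  structure(data.frame(chrom = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE),
            class = c("interval_set", "data.frame"))
}

#' Merge overlapping or touching intervals into their union
#' @param x An `interval_set`.
#' @return An `interval_set` of disjoint, sorted intervals.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(empty_intervals())
  parts <- lapply(split(x, factor(x$chrom, levels = unique(x$chrom))), function(d) {
    o <- order(d$start, d$end)
    s <- d$start[o]; e <- d$end[o]
    ms <- s[1]; me <- e[1]
    out_s <- integer(); out_e <- integer()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= me) me <- max(me, e[i]) else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i]
      }
    }
    data.frame(chrom = d$chrom[1], start = c(out_s, ms), end = c(out_e, me),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  structure(out, class = c("interval_set", "data.frame"))
}

#' Total bases covered by an interval set (after union merge)
#' @param x An `interval_set`.
#' @return Integer bp count.
#' @export
intervals_total_bp <- function(x) {
  m <- merge_intervals(x)
  sum(as.numeric(m$end - m$start))
}

#' Rasterize intervals to a 0/1 dense track
#' @param x An `interval_set`.
#' @param layout A `genome_layout`.
#' @return A binary `dense_track` (1 on covered bases).
#' @export
rasterize_intervals <- function(x, layout) {
  validate_intervals(x, layout)
  vals <- lapply(stats::setNames(layout$length, layout$chrom), numeric)
  for (i in seq_len(nrow(x))) {
    ch <- x$chrom[i]
    vals[[ch]][(x$start[i] + 1L):x$end[i]] <- 1
  }
  dense_track(layout, vals)
}
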