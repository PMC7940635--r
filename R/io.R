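#' Read a UCSC chrom.sizes file
#'
#' @param path Two-column whitespace-delimited text file (name, length).
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  if (file.size(path) == 0L) stop("no chromosomes in ", path)
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = FALSE,
                      colClasses = list(character = 1)),
    error = function(e) stop("malformed chrom.sizes file: ", conditionMessage(e))
  )
  if (nrow(dt) == 0L) stop("no chromosomes in ", path)
  if (ncol(dt) < 2L) stop("chrom.sizes needs two columns (name, length)")
  len <- suppressWarnings(as.numeric(dt[[2]]))
  if (anyNA(len)) stop("non-numeric chromosome length in ", path)
  if (any(len < 1)) stop("non-positive chromosome length in ", path)
  genome_layout(dt[[1]], len)
}

# shortest decimal representation that round-trips through as.numeric
format_num <- function(x) {
  s <- as.character(x)
  bad <- as.numeric(s) != x
  if (any(bad)) s[bad] <- sprintf("%.17g", x[bad])
  s
}

#' Read a 4-column bedGraph into a dense track
#'
#' Intervals may appear in any order but must not overlap; uncovered bases
#' are 0. Coordinates are 0-based half-open.
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @param layout A [genome_layout()] the track is defined over.
#' @return A [dense_track()].
#' @export
read_bedgraph <- function(path, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  vals <- lapply(stats::setNames(layout$length, layout$chrom), numeric)
  dt <- if (file.size(path) == 0L) data.table::data.table() else {
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = list(character = 1))
  }
  if (nrow(dt) > 0L) {
    if (ncol(dt) < 4L) stop("bedGraph needs 4 columns")
    chrom <- dt[[1]]; start <- as.integer(dt[[2]]); end <- as.integer(dt[[3]])
    value <- suppressWarnings(as.numeric(dt[[4]]))
    if (anyNA(value)) stop("non-numeric value in bedGraph ", path)
    if (anyNA(start) || anyNA(end)) stop("non-integer coordinates in ", path)
    len <- chrom_length(layout, chrom)
    if (any(start < 0L) || any(start >= end) || any(end > len)) {
      stop("bedGraph interval outside layout or with start >= end")
    }
    for (d in split(data.frame(start, end, value), chrom)) {
      o <- order(d$start)
      if (any(d$end[o][-nrow(d)] > d$start[o][-1])) {
        stop("overlapping bedGraph intervals")
      }
    }
    for (i in seq_along(chrom)) {
      vals[[chrom[i]]][(start[i] + 1L):end[i]] <- value[i]
    }
  }
  dense_track(layout, vals)
}

#' Write a dense track as bedGraph
#'
#' Maximal runs of equal value are emitted as single lines, sorted by layout
#' order then start. Values are written in the shortest decimal form that
#' round-trips, so `read_bedgraph(write_bedgraph(x))` reproduces `x` exactly.
#'
#' @param track A [dense_track()].
#' @param path Output file path.
#' @param omit_zero Skip zero-valued runs (default TRUE).
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path, omit_zero = TRUE) {
  stopifnot(inherits(track, "dense_track"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in track$layout$chrom) {
    v <- track$values[[ch]]
    r <- rle(v)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- if (omit_zero) r$values != 0 else rep(TRUE, length(end))
    if (!any(keep)) next
    writeLines(paste(ch, start[keep], end[keep],
                     format_num(r$values[keep]), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a BED3+ file
#'
#' @param path BED file with at least chrom, start, end; optional name and
#'   score columns are preserved.
#' @param layout Optional [genome_layout()] for bounds checking.
#' @return An [interval_set()].
#' @export
read_bed <- function(path, layout = NULL) {
  if (file.size(path) == 0L) return(empty_intervals())
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L) return(empty_intervals())
  if (ncol(dt) < 3L) stop("BED needs at least 3 columns")
  interval_set(dt[[1]], dt[[2]], dt[[3]],
               name = if (ncol(dt) >= 4L) dt[[4]] else NULL,
               score = if (ncol(dt) >= 5L) suppressWarnings(as.numeric(dt[[5]])) else NULL,
               layout = layout)
}

#' Write an interval set as BED
#'
#' @param intervals An [interval_set()]; `name` and `score` columns are
#'   written when present (name filled with "." if only score is present).
#' @param path Output file path.
#' @param extra_cols Optional character vector of additional columns of
#'   `intervals` to append after the score column.
#' @return The path, invisibly.
#' @export
write_bed <- function(intervals, path, extra_cols = NULL) {
  df <- as.data.frame(intervals)
  cols <- list(df$chrom, df$start, df$end)
  if (!is.null(df$name) || !is.null(df$score)) {
    cols <- c(cols, list(if (is.null(df$name)) rep(".", nrow(df)) else df$name))
  }
  if (!is.null(df$score)) cols <- c(cols, list(format_num(df$score)))
  for (cc in extra_cols) cols <- c(cols, list(format_num(df[[cc]])))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
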