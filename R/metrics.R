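# helper: logical per-chrom index vectors for a mask
mask_logical <- function(mask, layout) {
  m <- rasterize_intervals(mask, layout)
  lapply(m$values, function(v) v > 0)
}

# gather per-base values of a track, optionally restricted to a mask (or
# its complement)
gather_values <- function(track, mask_log = NULL, complement = FALSE) {
  unlist(lapply(track$layout$chrom, function(ch) {
    v <- track$values[[ch]]
    if (is.null(mask_log)) return(v)
    sel <- if (complement) !mask_log[[ch]] else mask_log[[ch]]
    v[sel]
  }), use.names = FALSE)
}

#' Regression metrics between two tracks
#'
#' Pearson and Spearman correlation (average ranks for ties) and mean
#' squared error between a predicted and a reference track, over all bases
#' or a masked subset. Correlations of a constant vector are returned as
#' `NA` with a `constant_input` flag rather than erroring.
#'
#' @param pred,ref [dense_track()]s on the same layout (or plain numeric
#'   vectors of equal length).
#' @param mask Optional [interval_set()] restricting evaluation.
#' @return List: `pearson`, `spearman`, `mse`, `n`, `constant_input`.
#' @export
track_regression_metrics <- function(pred, ref, mask = NULL) {
  if (inherits(pred, "dense_track")) {
    if (!identical(pred$layout, ref$layout)) stop("layout mismatch")
    ml <- if (!is.null(mask)) mask_logical(mask, pred$layout)
    x <- gather_values(pred, ml)
    y <- gather_values(ref, ml)
  } else {
    x <- as.numeric(pred); y <- as.numeric(ref)
    if (length(x) != length(y)) stop("length mismatch")
  }
  constant <- stats::sd(x) == 0 || stats::sd(y) == 0
  list(
    pearson = if (constant) NA_real_ else stats::cor(x, y),
    spearman = if (constant) NA_real_ else stats::cor(x, y, method = "spearman"),
    mse = mean((x - y)^2),
    n = length(x),
    constant_input = constant
  )
}

#' Classification metrics: AUPRC and AUROC
#'
#' AUROC uses the tie-corrected Mann-Whitney formulation (average ranks);
#' AUPRC integrates the precision-recall step function over the distinct
#' score thresholds, with no interpolation between tied scores.
#'
#' @param scores Numeric vector (or [dense_track()]) of scores.
#' @param labels 0/1 vector (or binary [dense_track()]) of the same length;
#'   must contain both classes.
#' @param mask Optional [interval_set()] restricting evaluation (tracks
#'   only).
#' @return List with `auprc`, `auroc`, `n`, `prevalence`.
#' @export
classification_metrics <- function(scores, labels, mask = NULL) {
  if (inherits(scores, "dense_track")) {
    ml <- if (!is.null(mask)) mask_logical(mask, scores$layout)
    scores <- gather_values(scores, ml)
    labels <- gather_values(labels, ml)
  }
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("labels contain a single class")
  # AUROC: Mann-Whitney with average ranks
  rk <- rank(scores)
  auroc <- (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * as.numeric(n0))
  # AUPRC: step integration over distinct thresholds (descending)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(which(diff(s) != 0), length(s))  # last index of each tied block
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  auprc <- sum((rec - c(0, rec[-length(rec)])) * prec)
  list(auprc = auprc, auroc = auroc, n = n1 + n0, prevalence = n1 / (n1 + n0))
}

# one full evaluation report: regression metrics genome-wide and by mask
# stratum, plus classification metrics when labels are given
eval_report <- function(pred, ref, labels = NULL, mask = NULL) {
  out <- list(genome = track_regression_metrics(pred, ref))
  if (!is.null(mask)) {
    ml <- mask_logical(mask, pred$layout)
    xin <- gather_values(pred, ml); yin <- gather_values(ref, ml)
    xout <- gather_values(pred, ml, complement = TRUE)
    yout <- gather_values(ref, ml, complement = TRUE)
    out$within_mask <- track_regression_metrics(xin, yin)
    out$outside_mask <- track_regression_metrics(xout, yout)
  }
  if (!is.null(labels)) {
    out$classification <- classification_metrics(pred, labels, mask = NULL)
  }
  out
}

#' Compare noisy and denoised tracks against a clean reference
#'
#' Computes identical-strata evaluation reports for the raw noisy track and
#' the denoised track against the same reference (the before/after view of
#' denoising): Pearson, Spearman and MSE genome-wide and within/outside the
#' mask, plus AUPRC/AUROC of each track used as a per-base peak score when
#' labels are supplied.
#'
#' @param noisy,denoised,ref [dense_track()]s on one layout.
#' @param labels Optional binary [dense_track()] of true peak labels.
#' @param mask Optional [interval_set()] (e.g. clean-data peak calls)
#'   defining the within/outside strata.
#' @return List with `noisy` and `denoised` reports.
#' @export
compare_eval <- function(noisy, denoised, ref, labels = NULL, mask = NULL) {
  stopifnot(identical(noisy$layout, ref$layout),
            identical(denoised$layout, ref$layout))
  list(noisy = eval_report(noisy, ref, labels = labels, mask = mask),
       denoised = eval_report(denoised, ref, labels = labels, mask = mask))
}
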