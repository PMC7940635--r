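# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so each file's tests run in seconds.

tiny_layout <- function() genome_layout(c("chrA", "chrB"), c(1000L, 500L))

# a small track with a few value runs on a two-chromosome layout
tiny_track <- function(layout = tiny_layout()) {
  vals <- lapply(stats::setNames(layout$length, layout$chrom), numeric)
  vals[[1]][101:300] <- 2
  vals[[1]][251:400] <- 3  # overwrite tail of the first run
  vals[[2]][51:60] <- 0.5
  dense_track(layout, vals)
}

# small read table spanning both strands
tiny_reads <- function() {
  data.frame(
    chrom = c("chrA", "chrA", "chrA", "chrB"),
    start = c(100L, 100L, 500L, 10L),
    end = c(150L, 150L, 550L, 60L),
    strand = c("+", "-", "+", "-"),
    stringsAsFactors = FALSE
  )
}

# desk-scale simulation spec used across module tests (smaller than the
# acceptance fixture)
small_sim_spec <- function(seed = 7L) {
  synthetic_spec(
    layout = genome_layout(c("chrA", "chrB"), c(200000L, 100000L)),
    n_peaks = 10L, peak_width = c(300L, 800L), enrichment = 8,
    n_reads = 20000L, thinning_p = 0.2, seed = seed
  )
}

# smooth coverage track (uniform reads extended +/- 100 bp), the shape a
# denoised background subsample actually has
smooth_track <- function(layout, n_reads, seed) {
  withr::with_seed(seed, {
    parts <- lapply(seq_len(nrow(layout)), function(i) {
      n <- round(n_reads * layout$length[i] / sum(layout$length))
      data.frame(chrom = layout$chrom[i],
                 pos = sample.int(layout$length[i], n, replace = TRUE) - 1L,
                 strand = "+", stringsAsFactors = FALSE)
    })
    coverage_from_cutsites(do.call(rbind, parts), 100L, layout)
  })
}

# The denoising-recovery fixture: a ~3 Mb three-chromosome genome (train /
# validation / holdout), long-tailed peak enrichments, 500k clean reads
# thinned to 10%, and a small residual model sized for a CPU run. The
# training hyperparameters (6 filters, batch 4, lr 1e-3) are the package's
# desk-scale choices documented in the methods vignette.
acceptance_fixture <- function() {
  layout <- genome_layout(c("chrTrain", "chr20", "chr10"),
                          c(1600000L, 700000L, 700000L))
  spec <- synthetic_spec(layout = layout, n_peaks = 40L,
                         peak_width = c(500L, 2000L), enrichment = c(2, 20),
                         n_reads = 500000L, thinning_p = 0.1, seed = 11L)
  sim <- simulate_reads(spec)
  noisy_reads <- thin_reads(sim$reads, p = spec$thinning_p, seed = 12L)
  clean <- coverage_from_cutsites(cut_sites_from_reads(sim$reads, layout),
                                  100L, layout)
  noisy <- coverage_from_cutsites(
    cut_sites_from_reads(noisy_reads, layout), 100L, layout)
  labels <- label_peaks(poisson_label_scores(clean))
  tiling <- tiling_spec(10000L, 600L)
  ex <- extract_examples(noisy, clean, labels, tiling = tiling)
  split <- split_examples(ex, split_spec(validation_chroms = "chr20",
                                         holdout_chroms = "chr10"))
  list(layout = layout, spec = spec, truth = sim$truth_peaks,
       clean = clean, noisy = noisy, labels = labels, tiling = tiling,
       split = split,
       cfg = model_config(filters = 6L, kernel = 25L, dilation = 4L,
                          reg_blocks = 2L, cls_blocks = 1L, seed = 21L),
       tc = train_config(lr = 1e-3, epochs = 10L, batch_size = 4L,
                         shuffle_seed = 22L))
}

# brute-force reference for the segment caller: per-base scan
brute_segments <- function(values, threshold, min_len, max_gap) {
  above <- which(values > threshold)
  if (length(above) == 0L) return(data.frame(start = integer(), end = integer()))
  # runs of consecutive above-threshold bases
  brk <- which(diff(above) > 1L)
  rs <- above[c(1L, brk + 1L)] - 1L
  re <- above[c(brk, length(above))]
  # merge runs separated by <= max_gap
  ms <- rs[1]; me <- re[1]; out_s <- integer(); out_e <- integer()
  for (i in seq_along(rs)[-1]) {
    if (rs[i] - me <= max_gap) me <- re[i] else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- rs[i]; me <- re[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  keep <- (out_e - out_s) >= min_len
  data.frame(start = out_s[keep], end = out_e[keep])
}

# brute-force AUROC: mean over all positive/negative pairs with 0.5 for ties
brute_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# brute-force AUPRC: explicit threshold enumeration over distinct scores
brute_auprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1)
  prev_rec <- 0; area <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / n1
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# brute-force Benjamini-Hochberg adjusted p-values
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i)  # rank of p[i]
    q[i] <- min(p[o[j:m]] * m / (j:m))
  }
  pmin(q, 1)
}
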