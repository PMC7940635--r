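test_that("cut-site conversion applies the +4/-5 Tn5 offsets", {
  layout <- tiny_layout()
  reads <- data.frame(chrom = "chrA", start = 100L, end = 150L,
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  sites <- cut_sites_from_reads(reads, layout)
  expect_equal(sites$pos, c(104L, 144L))  # 100+4 and (150-1)-5

  # identity offsets: + at start, - at end-1
  sites0 <- cut_sites_from_reads(reads, layout, plus_offset = 0L,
                                 minus_offset = 0L)
  expect_equal(sites0$pos, c(100L, 149L))

  # clipping at chromosome boundaries
  edge <- data.frame(chrom = "chrA", start = c(998L, 0L), end = c(1000L, 3L),
                     strand = c("+", "-"), stringsAsFactors = FALSE)
  se <- cut_sites_from_reads(edge, layout)
  expect_equal(se$pos, c(999L, 0L))

  bad <- data.frame(chrom = "chrA", start = 1L, end = 2L, strand = "*",
                    stringsAsFactors = FALSE)
  expect_error(cut_sites_from_reads(bad, layout), "unknown strand")
})

test_that("cut-site extension adds 2*ext+1 coverage per interior site", {
  layout <- genome_layout("chrA", 1000L)
  one <- data.frame(chrom = "chrA", pos = 500L, strand = "+")
  expect_equal(track_total(coverage_from_cutsites(one, 0L, layout)), 1)
  tr <- coverage_from_cutsites(one, 100L, layout)
  expect_equal(track_total(tr), 201)
  expect_true(all(tr$values$chrA[401:601] == 1))
  expect_equal(tr$values$chrA[400], 0)

  # two sites 50 bp apart: overlap doubles; brute-force accumulation oracle
  two <- data.frame(chrom = "chrA", pos = c(500L, 550L), strand = "+")
  tr2 <- coverage_from_cutsites(two, 100L, layout)
  brute <- numeric(1000)
  for (p in c(500L, 550L)) {
    idx <- max(p - 100L, 0L):min(p + 100L, 999L)
    brute[idx + 1L] <- brute[idx + 1L] + 1
  }
  expect_identical(tr2$values$chrA, brute)
  expect_equal(track_total(tr2), 402)
  expect_equal(max(tr2$values$chrA), 2)

  # boundary site: window truncated, total = clipped width
  edge <- data.frame(chrom = "chrA", pos = 10L, strand = "+")
  expect_equal(track_total(coverage_from_cutsites(edge, 100L, layout)), 111)
})

test_that("coverage totals satisfy the clipped-window-sum invariant", {
  spec <- small_sim_spec()
  sim <- simulate_reads(spec)
  sites <- cut_sites_from_reads(sim$reads, spec$layout)
  ext <- 100L
  tr <- coverage_from_cutsites(sites, ext, spec$layout)
  len <- chrom_length(spec$layout, sites$chrom)
  widths <- pmin(sites$pos + ext + 1L, len) - pmax(sites$pos - ext, 0L)
  expect_equal(track_total(tr), sum(widths))
})

test_that("Poisson label scores match the direct tail-sum oracle", {
  layout <- genome_layout("chrA", 12L)
  tr <- dense_track(layout, list(chrA = c(0, 0, 1, 2, 3, 5, 8, 10, 13, 0, 1, 2)))
  sc <- poisson_label_scores(tr, lambda = 1)
  # brute-force tail sum for lambda = 1
  tail_p <- function(k) sum(exp(-1) / factorial(seq(k, 60)))
  expected <- vapply(round(tr$values$chrA),
                     function(k) if (k == 0) 0 else -log10(tail_p(k)),
                     numeric(1))
  expect_equal(sc$values$chrA, expected, tolerance = 1e-9)

  # obs = 0 -> score 0 exactly
  expect_equal(sc$values$chrA[1], 0)

  # constant track scored against its own mean: all scores equal
  const <- dense_track(layout, list(chrA = rep(4, 12)))
  scc <- poisson_label_scores(const)
  expect_equal(length(unique(scc$values$chrA)), 1L)

  # cap and lambda validation
  big <- dense_track(layout, list(chrA = c(rep(0, 11), 5000)))
  expect_lte(max(poisson_label_scores(big, lambda = 0.1)$values$chrA), 350)
  expect_error(poisson_label_scores(tr, lambda = 0), "lambda")
})

test_that("peak labeling thresholds, merges and is monotone in the cutoff", {
  layout <- genome_layout("chrA", 2000L)
  v <- numeric(2000)
  v[101:400] <- 5            # 300-base run
  v[501:600] <- 4            # run separated by a large gap
  v[621:900] <- 4            # 20-base gap from the previous run
  tr <- dense_track(layout, list(chrA = v))

  expect_equal(nrow(label_peaks(dense_track(layout), cutoff = 3)), 0L)

  pk <- label_peaks(tr, cutoff = 3, min_len = 200L, max_gap = 30L)
  expect_equal(pk$start, c(100L, 500L))
  expect_equal(pk$end, c(400L, 900L))  # 20 bp gap <= 30 merged

  # monotone: raising the cutoff never adds labeled bases
  lab3 <- rasterize_intervals(label_peaks(tr, cutoff = 3, min_len = 50L), layout)
  lab45 <- rasterize_intervals(label_peaks(tr, cutoff = 4.5, min_len = 50L), layout)
  expect_true(all(lab45$values$chrA <= lab3$values$chrA))
})

test_that("genome tiling is an exact partition keeping the final partial interval", {
  layout <- genome_layout(c("chrA", "chrB"), c(120000L, 50000L))
  tl <- tile_genome(layout, tiling_spec(50000L, 5000L))
  a <- tl[tl$chrom == "chrA", ]
  expect_equal(a$end - a$start, c(50000L, 50000L, 20000L))
  b <- tl[tl$chrom == "chrB", ]
  expect_equal(nrow(b), 1L)
  expect_equal(b$end - b$start, 50000L)
  # disjoint and covering
  for (d in split(tl, tl$chrom)) {
    expect_equal(d$start[-1], d$end[-nrow(d)])
    expect_equal(d$start[1], 0L)
    expect_equal(d$end[nrow(d)], chrom_length(layout, d$chrom[1]))
  }
  expect_equal(sum(tl$end - tl$start), sum(layout$length))
})

test_that("extracted examples have the padded window contract", {
  layout <- genome_layout("chrA", 120000L)
  set.seed(11)
  noisy <- dense_track(layout, list(chrA = rpois(120000, 1) * 1.0))
  clean <- dense_track(layout, list(chrA = rpois(120000, 3) * 1.0))
  labels <- interval_set("chrA", 60000L, 61000L, layout = layout)
  tiling <- tiling_spec(50000L, 5000L)
  ex <- extract_examples(noisy, clean, labels, tiling = tiling)
  expect_equal(length(ex), 3L)
  # window length L + 2 pad for every example, even the partial one
  for (e in ex) {
    expect_equal(nrow(e$input), (e$end - e$start) + 10000L)
    expect_equal(ncol(e$input), 1L)
    expect_equal(length(e$target), nrow(e$input))
  }
  # chromosome-start example: first pad bases zero-filled
  expect_true(all(ex[[1]]$input[1:5000, 1] == 0))
  expect_true(all(ex[[1]]$target[1:5000] == 0))
  # labels rasterized in window coordinates: peak at 60000 sits in window 2
  w2 <- ex[[2]]
  off <- 60000L - (w2$start - 5000L)
  expect_true(all(w2$labels[(off + 1L):(off + 1000L)] == 1))
  expect_equal(sum(w2$labels), 1000)
  # discarding pads and concatenating central windows reconstructs the input
  rebuilt <- unlist(lapply(ex, function(e) {
    e$input[(5000L + 1L):(5000L + (e$end - e$start)), 1]
  }))
  expect_identical(rebuilt, noisy$values$chrA, ignore_attr = TRUE)
})

test_that("motif channels are binary per-strand rasters and stack to 3 inputs", {
  layout <- genome_layout("chrA", 10000L)
  fwd <- interval_set("chrA", c(100L, 150L), c(130L, 180L), layout = layout)
  rev <- interval_set("chrA", 160L, 200L, layout = layout)
  mc <- motif_channels(fwd, rev, layout)
  expect_equal(mc$fwd$values$chrA[120], 1)
  expect_equal(mc$rev$values$chrA[120], 0)
  expect_equal(mc$fwd$values$chrA[170], 1)  # base in both fwd and rev sites
  expect_equal(mc$rev$values$chrA[170], 1)
  expect_equal(track_total(mc$fwd), intervals_total_bp(fwd))

  noisy <- dense_track(layout)
  ex <- extract_examples(noisy, extra_channels = mc,
                         tiling = tiling_spec(10000L, 100L))
  expect_equal(ncol(ex[[1]]$input), 3L)
  ex1 <- extract_examples(noisy, tiling = tiling_spec(10000L, 100L))
  expect_equal(ncol(ex1[[1]]$input), 1L)
})
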