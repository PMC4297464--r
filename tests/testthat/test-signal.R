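cs1 <- chrom_sizes("chrS1", 1e4)

test_that("reads extend from their 5' end, strand-aware, clipped to bounds", {
  r <- tibble::tibble(chrom = "chrS1",
                      five_prime = c(100, 400, 1e4 - 10),
                      strand = c("+", "-", "+"))
  ext <- extend_reads(r, cs1, length = 150)
  expect_equal(ext$start, c(100, 251, 1e4 - 10))
  expect_equal(ext$end, c(250, 401, 1e4))
  expect_error(extend_reads(tibble::tibble(chrom = "chrX", five_prime = 1,
                                           strand = "+"), cs1),
               "unknown chromosome")
})

test_that("dyads are floor midpoints and strand-symmetric", {
  expect_equal(dyad_positions(tibble::tibble(start = 100, end = 250)), 175)
  expect_equal(dyad_positions(tibble::tibble(start = 0, end = 150)), 75)
  expect_equal(dyad_positions(tibble::tibble(start = 90, end = 100)), 95)
  # a plus read at p and a minus read at p + 149 share a dyad
  for (p in c(200, 777, 5000)) {
    r <- tibble::tibble(chrom = "chrS1", five_prime = c(p, p + 149),
                        strand = c("+", "-"))
    d <- dyad_positions(extend_reads(r, cs1))
    expect_equal(d[1], d[2])
  }
})

test_that("count_dyads places dyads in windows and conserves reads", {
  g <- window_grid(cs1, width = 250)
  empty <- tibble::tibble(chrom = character(), five_prime = numeric(),
                          strand = character())
  tr <- count_dyads(empty, g)
  expect_true(all(tr$value == 0))
  expect_equal(attr(tr, "library_size"), 0)

  one <- tibble::tibble(chrom = "chrS1", five_prime = 100, strand = "+")
  tr1 <- count_dyads(one, g)  # dyad 175 -> window [0, 250)
  expect_equal(tr1$value[1], 1)
  expect_equal(sum(tr1$value), 1)

  # conservation on a non-overlapping grid, random reads
  withr::with_seed(42, {
    r <- tibble::tibble(chrom = "chrS1",
                        five_prime = sample.int(1e4, 500) - 1,
                        strand = sample(c("+", "-"), 500, TRUE))
  })
  trr <- count_dyads(r, g)
  expect_equal(sum(trr$value), 500)
  expect_error(count_dyads(tibble::tibble(chrom = "chrZ", five_prime = 1,
                                          strand = "+"), g),
               "unknown chromosome")
})

test_that("sliding-grid counts equal brute-force window containment", {
  g <- window_grid(cs1, width = 100, step = 10)
  withr::with_seed(7, {
    r <- tibble::tibble(chrom = "chrS1",
                        five_prime = sample.int(9000, 200) - 1,
                        strand = sample(c("+", "-"), 200, TRUE))
  })
  tr <- count_dyads(r, g)
  dy <- dyad_positions(extend_reads(r, cs1))
  brute <- vapply(seq_len(nrow(g)),
                  function(i) sum(dy >= g$start[i] & dy < g$end[i]),
                  numeric(1))
  expect_equal(tr$value, brute)
})

test_that("the low-pass filter matches its weighted-average definition", {
  expect_equal(lowpass_filter(tiny_track(c(3, 3, 3, 3)))$value[1:4],
               rep(3, 4))
  expect_equal(lowpass_filter(tiny_track(c(0, 4, 0)))$value[2], 2)
  expect_equal(lowpass_filter(tiny_track(c(4, 0, 0)))$value[1], 4 / 1.5)
})

test_that("the low-pass filter equals brute-force convolution on random tracks", {
  withr::with_seed(123, {
    for (i in 1:50) {
      v <- rpois(sample(3:40, 1), 5)
      tr <- tiny_track(v)
      got <- lowpass_filter(tr)$value[seq_along(v)]
      # windows beyond v are zero; restrict the oracle to the full track
      full <- tiny_track(v)$value
      expect_identical(lowpass_filter(tiny_track(v))$value,
                       brute_lowpass(full))
    }
  })
  # interior totals are preserved (normalized weights)
  v <- c(5, 1, 7, 2, 9)
  n <- 40  # pad so edges are far from the signal
  tr <- tiny_track(c(rep(0, 5), v, rep(0, 30)))
  expect_equal(sum(lowpass_filter(tr)$value[2:39]), sum(v))
})

test_that("filter spanning two chromosomes never mixes them", {
  g <- window_grid(test_chroms(), width = 250)
  vals <- rep(0, nrow(g))
  n1 <- sum(g$chrom == "chrS1")
  vals[n1] <- 8       # last window of chrS1
  vals[n1 + 1] <- 0   # first window of chrS2
  tr <- signal_track(g, vals, library_size = 8)
  out <- lowpass_filter(tr)
  expect_equal(out$value[n1], 8 / 1.5)      # chromosome-edge divisor
  expect_equal(out$value[n1 + 1], 0)        # no bleed across chromosomes
})

test_that("enrichment calling applies the Poisson test, BH and fold filter", {
  # window 1: chip 20 vs scaled expectation 2 -> enriched
  # window 2: chip 3 vs 2 -> upper tail ~0.32, not enriched
  # window 3: chip 0 -> never enriched
  chip <- tiny_track(c(20, 3, 0, 2, 2), library_size = 100)
  inp <- tiny_track(c(2, 2, 2, 2, 2), library_size = 100)
  calls <- call_enriched(chip, inp, alpha = 0.05, min_fold = 2)
  expect_equal(calls$p[1], ppois(19, 2, lower.tail = FALSE))
  expect_lt(calls$p[1], 1e-12)
  expect_equal(calls$p[2], ppois(2, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_gt(calls$p[2], 0.3)
  expect_true(calls$enriched[1])
  expect_false(any(calls$enriched[2:5]))
  # grid mismatch and zero library are rejected
  expect_error(call_enriched(chip, tiny_track(c(1, 1))), "grid")
  bad <- tiny_track(c(1, 1, 1, 1, 1), library_size = 0)
  expect_error(call_enriched(chip, bad), "library size")
})

test_that("resampling assigns each fine window its covering coarse value", {
  v <- c(1, 5, 2, 8)
  tr <- tiny_track(v, width = 250)
  fine <- resample_track(tr, width = 10)
  # brute force: fine window value = coarse window containing its midpoint
  mid <- fine$start + (fine$end - fine$start) %/% 2
  expect_equal(fine$value, tr$value[mid %/% 250 + 1])
  expect_equal(sum(fine$value[1:25] == 1), 25)
})

test_that("bedGraph and enriched-BED round-trips preserve the track", {
  tr <- tiny_track(c(1.5, 0, 2.25, 7))
  p <- file.path(tempdir(), "t.bedGraph")
  write_bedgraph(tr, p)
  g <- window_grid(attr(tr, "chrom_sizes"), 250)
  back <- read_bedgraph(p, g)
  expect_equal(back$value, tr$value)
})
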