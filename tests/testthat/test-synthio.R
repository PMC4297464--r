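test_that("archetype rate ordering and counts follow the configuration", {
  ann <- build_annotation(test_chroms(), synth_params(), seed = 5)
  truth <- tibble::as_tibble(ann$truth)
  by_arch <- split(truth$true_lambda, truth$archetype)
  means <- vapply(by_arch, mean, numeric(1))
  expect_lt(means[["heterochromatin"]], means[["gene_body"]])
  expect_lt(means[["gene_body"]], means[["tss_flank"]])
  expect_lt(means[["tss_flank"]], means[["distal_site"]])
  expect_lt(means[["distal_site"]], means[["ndr"]])
  # rate draws respect the configured ranges exactly
  rr <- synth_params()$rate_ranges
  for (a in names(by_arch)) {
    expect_true(all(by_arch[[a]] >= rr[[a]][1] & by_arch[[a]] <= rr[[a]][2]))
  }
  expect_equal(sum(truth$archetype == "ndr"), 30)
  expect_equal(sum(truth$archetype == "satellite_repeat"), 30)
})

test_that("an archetype requested at zero count yields no loci", {
  ann <- build_annotation(test_chroms(), synth_params(n_satellite = 0),
                          seed = 5)
  expect_false("satellite_repeat" %in% ann$truth$archetype)
})

test_that("loci are non-overlapping, in bounds, with NDRs 50-100 bp upstream of TSSs", {
  ann <- build_annotation(test_chroms(), synth_params(), seed = 9)
  truth <- tibble::as_tibble(ann$truth)
  by_chrom <- split(truth, truth$chrom)
  for (d in by_chrom) {
    d <- d[order(d$start), ]
    expect_true(all(d$end[-nrow(d)] <= d$start[-1]))
  }
  tss <- transcript_anchors(ann$transcripts, "tss")
  ndr <- truth[truth$archetype == "ndr", ]
  ndr <- ndr[match(tss$anchor_id, sub("^ndr_", "", ndr$locus_id)), ]
  # signed upstream offsets of NDR edges from the TSS, strand-aware
  p <- tss$start
  near <- ifelse(tss$strand == "+", p - ndr$end, ndr$start - p)
  far <- ifelse(tss$strand == "+", p - ndr$start, ndr$end - 1 - p)
  expect_true(all(near >= 49 & far <= 100))
})

test_that("generation is deterministic for a fixed seed", {
  a1 <- build_annotation(test_chroms(), synth_params(), seed = 11)
  a2 <- build_annotation(test_chroms(), synth_params(), seed = 11)
  expect_identical(a1$truth, a2$truth)
  expect_identical(a1$transcripts, a2$transcripts)
  s1 <- simulate_reads(a1$truth, depth = 0.5, seed = 11)
  s2 <- simulate_reads(a2$truth, depth = 0.5, seed = 11)
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))
  # replicates come from distinct sub-seeds
  s3 <- simulate_reads(a1$truth, depth = 0.5, n_replicates = 2, seed = 11)
  expect_false(identical(get_library(s3, 0, 1), get_library(s3, 0, 2)))
})

test_that("over-filled genomes raise a capacity error", {
  small <- chrom_sizes("chrS1", 2e4)
  expect_error(build_annotation(small, synth_params(n_genes = 50), seed = 1),
               "capacity")
})

test_that("simulated counts follow the exponential decay expectation", {
  # half-life 6 h: N(6)/N(0) converges to 0.5 over many simulations
  truth <- uniform_truth(20, occupancy0 = 100, lambda = log(2) / 6)
  tot0 <- 0; tot6 <- 0
  for (s in 1:200) {
    sim <- simulate_reads(truth, depth = 1, input_reads_per_kb = 1, seed = s)
    tot0 <- tot0 + sum(sim$library == "chip" & sim$timepoint == 0)
    tot6 <- tot6 + sum(sim$library == "chip" & sim$timepoint == 6)
  }
  expect_equal(tot6 / tot0, 0.5, tolerance = 0.02)

  # lambda = 0: no decay
  truth0 <- uniform_truth(50, occupancy0 = 100, lambda = 0)
  sim <- simulate_reads(truth0, depth = 1, input_reads_per_kb = 1, seed = 3)
  n0 <- sum(sim$library == "chip" & sim$timepoint == 0)
  n6 <- sum(sim$library == "chip" & sim$timepoint == 6)
  expect_equal(n6 / n0, 1, tolerance = 0.05)

  # doubling depth doubles counts within Poisson error
  sim2 <- simulate_reads(truth0, depth = 2, input_reads_per_kb = 1, seed = 3)
  n0_2 <- sum(sim2$library == "chip" & sim2$timepoint == 0)
  expect_equal(n0_2 / n0, 2, tolerance = 0.05)
})

test_that("per-locus sample means converge to the truth-table expectation", {
  lam <- c(0, 0.1, 0.3, 0.5)
  truth <- uniform_truth(4, occupancy0 = 80, lambda = lam)
  counts <- matrix(0, 4, 2)
  for (s in 1:200) {
    sim <- simulate_reads(truth, depth = 1, input_reads_per_kb = 1, seed = s)
    for (j in 1:2) {
      t <- c(0, 6)[j]
      reads <- get_library(sim, t, 1)
      cnt <- locus_counts(reads, tibble::as_tibble(truth),
                          attr(truth, "chrom_sizes"))$count
      counts[, j] <- counts[, j] + cnt
    }
  }
  exp_tab <- expected_counts(truth, c(0, 6), depth = 1)
  for (j in 1:2) {
    expected <- exp_tab$expected[exp_tab$timepoint == c(0, 6)[j]]
    expect_true(all(abs(counts[, j] / 200 / expected - 1) < 0.05))
  }
})

test_that("fixtures round-trip losslessly through disk", {
  ann <- build_annotation(test_chroms(), synth_params(n_genes = 5,
                                                      n_heterochromatin = 2,
                                                      n_distal = 5,
                                                      n_satellite = 5,
                                                      n_background = 3),
                          seed = 2)
  sim <- simulate_reads(ann$truth, depth = 0.3, n_replicates = 2, seed = 2)
  dir <- file.path(tempdir(), "h3t_fixture")
  write_fixture(sim, ann, dir)
  back <- read_fixture(dir)

  # identical read multiset per library
  orig <- get_library(sim, 0, 1)
  got <- back$reads[["reads_t0_rep1"]]
  key <- function(d) sort(paste(d$chrom, d$five_prime, d$strand))
  expect_identical(key(got), key(orig))
  expect_identical(key(back$reads[["input_rep2"]]),
                   key(get_library(sim, NA, 2)))

  expect_true("true_lambda" %in% names(back$truth))
  expect_equal(nrow(back$truth), nrow(ann$truth))
  expect_equal(back$truth$true_lambda, ann$truth$true_lambda)
  expect_equal(back$transcripts, ann$transcripts)

  # empty read collection still writes a valid (empty) BED
  empty <- tibble::tibble(chrom = character(), five_prime = numeric(),
                          strand = character())
  p <- file.path(dir, "empty.bed")
  readr::write_lines(character(0), p)
  expect_equal(nrow(read_reads_bed(p)), 0)
})
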