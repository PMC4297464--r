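# Shared fixtures, all generated in code.

test_chroms <- function() chrom_sizes(c("chrS1", "chrS2"), c(2e5, 1.5e5))

# single-chromosome track from a value vector (one window per value);
# the chromosome is sized to the values exactly (test plumbing only, so
# the 10-kb minimum of chrom_sizes() is bypassed)
tiny_track <- function(values, width = 250, library_size = NA_real_) {
  cs <- tibble::tibble(name = "chrT", length = length(values) * width)
  g <- window_grid(cs, width = width)
  signal_track(g, values, library_size = library_size)
}

# truth table of uniformly spaced same-width loci on one chromosome
uniform_truth <- function(n_loci, width = 200, spacing = 500,
                          occupancy0 = 100, lambda) {
  len <- max(10000, n_loci * spacing + 1000)
  cs <- chrom_sizes("chrU", len)
  starts <- (seq_len(n_loci) - 1) * spacing + 100
  truth_table(
    tibble::tibble(chrom = "chrU", start = starts, end = starts + width,
                   archetype = "distal_site", occupancy0 = occupancy0,
                   true_lambda = lambda),
    cs)
}

# brute-force (1, 0.5, 0.5)/sum(w) smoothing of one chromosome's values
brute_lowpass <- function(v) {
  n <- length(v)
  vapply(seq_len(n), function(i) {
    num <- v[i]; den <- 1
    if (i > 1) { num <- num + 0.5 * v[i - 1]; den <- den + 0.5 }
    if (i < n) { num <- num + 0.5 * v[i + 1]; den <- den + 0.5 }
    num / den
  }, numeric(1))
}

# brute-force minimum gap distance between 0-based half-open intervals
brute_gap <- function(s1, e1, s2, e2) {
  if (s1 < e2 && s2 < e1) return(0)
  max(s2 - e1, s1 - e2)
}

# memoised default synthetic pipeline run shared across test files
default_pipeline_run <- local({
  res <- NULL
  function() {
    if (is.null(res)) {
      res <<- suppressMessages(
        run_pipeline(file.path(tempdir(), "h3t_default_run"),
                     config = list(seed = 101), quiet = TRUE))
    }
    res
  }
})

# paired-replicate rate concordance at a given per-locus depth
concordance_at_depth <- function(depth, seed) {
  # sparse layout: most of the genome is background, as in real ChIP
  lam <- withr::with_seed(seed, runif(400, 0, 0.5))
  truth <- uniform_truth(400, width = 200, spacing = 2000,
                         occupancy0 = 1, lambda = lam)
  cs <- attr(truth, "chrom_sizes")
  sim <- simulate_reads(truth, depth = depth, n_replicates = 2,
                        input_reads_per_kb = 30, seed = seed)
  g <- window_grid(cs, 250)
  rate_track <- function(rep) {
    c0 <- lowpass_filter(count_dyads(get_library(sim, 0, rep), g))
    c6 <- lowpass_filter(count_dyads(get_library(sim, 6, rep), g))
    ci <- lowpass_filter(count_dyads(get_library(sim, NA, rep), g))
    est <- turnover_tracks(c0, c6, ci, call_enriched(c0, ci))
    turnover_track(est, "lambda_out")
  }
  replicate_concordance(rate_track(1), rate_track(2), resolution = 10)
}
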