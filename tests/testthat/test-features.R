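test_that("FPKM bins match the published boundaries and partition [0, Inf)", {
  expect_equal(as.character(bin_expression(35)), "top10")
  expect_equal(as.character(bin_expression(0.5)), "silent")
  # upper-inclusive boundaries: 30 belongs to top20, 10 to medium, ...
  expect_equal(as.character(bin_expression(c(30, 10, 3, 1, 0))),
               c("top20", "medium", "low", "silent", "silent"))
  expect_equal(as.character(bin_expression(c(30.0001, 10.5, 3.5, 1.5))),
               c("top10", "top20", "medium", "low"))
  withr::with_seed(4, x <- c(rlnorm(500, 1, 2), 0, 1, 3, 10, 30, 1e6))
  bins <- bin_expression(x)
  expect_false(anyNA(bins))                 # every value maps to one bin
  expect_equal(length(bins), length(x))
  expect_error(bin_expression(-1), "non-negative")
})

tx <- tibble::tibble(transcript_id = "tx1", chrom = "chrS1",
                     start = 50000, end = 60000, strand = "+")

test_that("proximity classification uses inclusive gap distance", {
  sites <- tibble::tibble(chrom = "chrS1",
                          start = c(55000, 66000, 65000, 40000),
                          end = c(55100, 66100, 65100, 40100))
  out <- classify_proximity(sites, tx, cutoff = 5000)
  expect_equal(out$class, c("proximal", "distal", "proximal", "distal"))
  expect_equal(out$dist_to_transcript, c(0, 6000, 5000, 9900))
  # cutoff 0 marks exactly the overlapping sites
  out0 <- classify_proximity(sites, tx, cutoff = 0)
  expect_equal(out0$class == "proximal", c(TRUE, FALSE, FALSE, FALSE))
})

test_that("sites on chromosomes without transcripts become distal, with a message", {
  sites <- tibble::tibble(chrom = c("chrS1", "chrS2"),
                          start = c(55000, 1000), end = c(55100, 1100))
  expect_message(out <- classify_proximity(sites, tx), "distal")
  expect_equal(out$class, c("proximal", "distal"))
  expect_error(classify_proximity(sites, tx[0, ]), "empty")
})

test_that("gap distances agree with a brute-force pairwise oracle", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      s1 <- sample.int(5000, 8); sites <- tibble::tibble(
        chrom = "chrS1", start = s1, end = s1 + sample.int(300, 8))
      s2 <- sample.int(5000, 5); txs <- tibble::tibble(
        chrom = "chrS1", start = s2, end = s2 + sample.int(300, 5))
      got <- classify_proximity(sites, txs, cutoff = 1000)$dist_to_transcript
      brute <- vapply(seq_len(8), function(i) {
        min(vapply(seq_len(5), function(j) {
          brute_gap(sites$start[i], sites$end[i], txs$start[j], txs$end[j])
        }, numeric(1)))
      }, numeric(1))
      expect_equal(got, brute)
    }
  })
})

test_that("repeats classify as genic within 2 kb, inclusive", {
  reps <- tibble::tibble(chrom = "chrS1",
                         start = c(52000, 70000, 62000),
                         end = c(52500, 70500, 62100),
                         name = "satellite")
  out <- classify_repeats(reps, tx)
  expect_equal(out$class, c("genic", "non_genic", "genic"))
  boundary <- tibble::tibble(chrom = "chrS1", start = 62000, end = 62100,
                             name = "x")  # exactly 2,000 bp gap
  expect_equal(classify_repeats(boundary, tx)$dist_to_transcript, 2000)
  expect_equal(classify_repeats(boundary, tx)$class, "genic")
})

test_that("TF binding flags use 1-bp overlap and union semantics", {
  reps <- tibble::tibble(chrom = "chrS1",
                         start = c(1000, 2000, 3000),
                         end = c(1200, 2200, 3200),
                         name = "satellite")
  peaks <- list(
    a = tibble::tibble(chrom = "chrS1", start = 1199, end = 1300),
    b = tibble::tibble(chrom = "chrS1", start = c(1100, 2100),
                       end = c(1150, 2150)))
  ov <- tf_binding_overlap(reps, peaks)
  expect_equal(ov$repeats$bound_a, c(TRUE, FALSE, FALSE))
  expect_equal(ov$repeats$bound_b, c(TRUE, TRUE, FALSE))
  expect_equal(ov$repeats$bound_any, c(TRUE, TRUE, FALSE))  # counted once
  s <- ov$summary
  expect_equal(s$fraction[s$peak_set == "any"], 2 / 3)
  # union dominance: any-set fraction >= every per-set fraction
  expect_true(all(s$fraction[s$peak_set == "any"] >=
                    s$fraction[s$peak_set != "any"]))
  empty <- tf_binding_overlap(reps[0, ], peaks)
  expect_equal(nrow(empty$repeats), 0)
  expect_error(tf_binding_overlap(reps, list()), "at least one")
  expect_error(tf_binding_overlap(reps, list(tibble::tibble())), "named")
})

test_that("bound fractions reproduce published-style counts exactly", {
  # 2,610 elements of which 835 overlap a peak -> 32% bound
  n <- 2610; n_bound <- 835
  starts <- (seq_len(n) - 1) * 1000
  reps <- tibble::tibble(chrom = "chrR", start = starts, end = starts + 200,
                         name = "satellite", class = "non_genic")
  peaks <- list(tf = tibble::tibble(chrom = "chrR",
                                    start = starts[seq_len(n_bound)] + 50,
                                    end = starts[seq_len(n_bound)] + 60))
  s <- tf_binding_overlap(reps, peaks)$summary
  any_frac <- s$fraction[s$peak_set == "any"]
  expect_equal(s$n_bound[s$peak_set == "any"], 835)
  expect_equal(round(100 * any_frac), 32)
})
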