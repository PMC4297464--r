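#' Extend reads to nucleosome size from their 5' end
#'
#' Aligned reads are represented by their 5' position and strand and are
#' extended to `length` bp (150 bp by default, a nucleosome footprint)
#' in the direction of the alignment, then clipped to chromosome bounds.
#'
#' @param reads Data frame with columns `chrom`, `five_prime` (0-based bp)
#'   and `strand` (`+`/`-`).
#' @param chroms Chromosome size tibble.
#' @param length Extension length in bp (> 0), default 150.
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open) and
#'   `strand`; all other read columns are carried through.
#' @examples
#' reads <- tibble::tibble(chrom = "chrS1", five_prime = 100, strand = "+")
#' extend_reads(reads, chrom_sizes("chrS1", 1e4))
#' @export
extend_reads <- function(reads, chroms, length = 150) {
  if (length <= 0) abort("extension length must be > 0")
  check_reads(reads, chroms)
  len <- chroms$length[match(reads$chrom, chroms$name)]
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$five_prime, reads$five_prime - length + 1)
  end <- ifelse(plus, reads$five_prime + length, reads$five_prime + 1)
  out <- as_tibble(reads) |>
    mutate(start = pmax(start, 0), end = pmin(end, len)) |>
    select(-"five_prime") |>
    select("chrom", "start", "end", "strand", dplyr::everything())
  out
}

check_reads <- function(reads, chroms) {
  need <- c("chrom", "five_prime", "strand")
  if (!all(need %in% names(reads))) {
    abort("reads need columns chrom, five_prime, strand")
  }
  m <- match(reads$chrom, chroms$name)
  if (anyNA(m)) {
    abort(paste0("reads on unknown chromosome: ",
                 paste(unique(reads$chrom[is.na(m)]), collapse = ", ")))
  }
  if (any(reads$five_prime < 0 | reads$five_prime >= chroms$length[m])) {
    abort("read 5' positions must lie within chromosome bounds")
  }
  if (!all(reads$strand %in% c("+", "-"))) {
    abort("read strand must be '+' or '-'")
  }
  invisible(TRUE)
}

#' Dyad position of an extended read
#'
#' The dyad -- the counting unit for nucleosome occupancy -- is the floor
#' midpoint of the extended interval: `start + (end - start) %/% 2`. A
#' plus-strand read at p and a minus-strand read at p + length - 1 extend
#' to the same interval and therefore share a dyad.
#'
#' @param intervals Data frame with `start` and `end` columns.
#' @return Integer-valued numeric vector of dyad positions (bp).
#' @examples
#' dyad_positions(tibble::tibble(start = 100, end = 250))  # 175
#' @export
dyad_positions <- function(intervals) {
  intervals$start + (intervals$end - intervals$start) %/% 2
}

#' Count dyads per window
#'
#' Each read is extended, reduced to its dyad, and contributes exactly one
#' count to every window containing the dyad (one window on a
#' non-overlapping grid, several on a sliding grid). The total read count
#' is recorded as the track's library size.
#'
#' @param reads Read data frame (`chrom`, `five_prime`, `strand`).
#' @param grid A [window_grid()] defined over the reads' chromosomes.
#' @param extend Extension length passed to [extend_reads()].
#' @return A count `signal_track` on `grid`.
#' @export
count_dyads <- function(reads, grid, extend = 150) {
  chroms <- grid_chroms(grid)
  w <- grid_width(grid)
  s <- grid_step(grid)
  vals <- numeric(nrow(grid))
  if (nrow(reads) > 0) {
    ext <- extend_reads(reads, chroms, length = extend)
    dy <- tibble(chrom = ext$chrom, pos = dyad_positions(ext))
    grid_meta <- as_tibble(grid) |>
      mutate(.idx = row_number()) |>
      group_by(.data$chrom) |>
      summarise(.first = min(.data$.idx), .n = n())
    for (i in seq_len(nrow(grid_meta))) {
      cm <- grid_meta[i, ]
      p <- dy$pos[dy$chrom == cm$chrom]
      if (!length(p)) next
      # windows k with k*s <= pos < k*s + w, 0 <= k < .n
      k_hi <- pmin(p %/% s, cm$.n - 1)
      k_lo <- pmax(floor((p - w) / s) + 1, 0)
      ks <- unlist(purrr::map2(k_lo, k_hi, function(a, b) if (a <= b) a:b else integer(0)))
      tab <- tabulate(ks + 1L, nbins = cm$.n)
      vals[cm$.first:(cm$.first + cm$.n - 1)] <- tab
    }
  }
  signal_track(grid, vals, library_size = nrow(reads))
}

#' Count dyads within arbitrary loci
#'
#' Convenience counter for locus-level rate estimation (repeat elements,
#' synthetic loci): extends reads, takes dyads, and counts dyads falling
#' in each interval of `loci`.
#'
#' @param reads Read data frame.
#' @param loci Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param chroms Chromosome size tibble.
#' @param extend Extension length in bp.
#' @return `loci` as a tibble with an added `count` column.
#' @export
locus_counts <- function(reads, loci, chroms, extend = 150) {
  loci <- as_tibble(loci)
  if (nrow(reads) == 0) return(mutate(loci, count = 0))
  ext <- extend_reads(reads, chroms, length = extend)
  dy <- GenomicRanges::GRanges(ext$chrom,
                               IRanges::IRanges(dyad_positions(ext) + 1, width = 1))
  lr <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start + 1, loci$end))
  loci$count <- GenomicRanges::countOverlaps(lr, dy)
  loci
}

#' Weighted low-pass filter for windowed counts
#'
#' Smooths a non-overlapping count track with a three-window weighted
#' average: the center window weighted 1 and its two neighbours 0.5 each,
#' divided by the in-bounds weight sum (2 in the interior, 1.5 at
#' chromosome ends, 1 on a single-window chromosome). The normalization
#' makes the filter average-preserving: constant tracks pass unchanged.
#'
#' @param track A count `signal_track` on a non-overlapping grid.
#' @return A filtered `signal_track` on the identical grid.
#' @examples
#' g <- window_grid(chrom_sizes("chrS1", 1e4), 250)
#' lowpass_filter(count_dyads(tibble::tibble(chrom = character(),
#'   five_prime = numeric(), strand = character()), g))
#' @export
lowpass_filter <- function(track) {
  if (grid_step(track) != grid_width(track)) {
    abort("the low-pass filter is defined on non-overlapping grids")
  }
  out <- as_tibble(track) |>
    group_by(.data$chrom) |>
    mutate(
      .prev = lag(.data$value, default = 0),
      .next = lead(.data$value, default = 0),
      .wsum = 1 + 0.5 * (row_number() > 1) + 0.5 * (row_number() < n()),
      value = (.data$value + 0.5 * .data$.prev + 0.5 * .data$.next) / .data$.wsum
    ) |>
    ungroup()
  track_like(track, out$value)
}

#' Call windows enriched over input
#'
#' Defines the analysis universe for all rate computations: a window is
#' enriched iff (i) the one-sided Poisson upper-tail probability of its
#' ChIP count, given the input count scaled to the ChIP library size
#' (floored at `pseudocount`), survives Benjamini-Hochberg control at
#' `alpha`, and (ii) the fold change over that scaled expectation is at
#' least `min_fold`.
#'
#' @param chip0 ChIP count track at 0 h.
#' @param input0 Input count track on the same grid.
#' @param alpha FDR level (default 0.05).
#' @param min_fold Minimum fold enrichment over scaled input (default 2).
#' @param pseudocount Floor for the scaled input expectation (default 0.5).
#' @return A tibble on the same grid with logical column `enriched` plus
#'   diagnostic columns `fold`, `p`, `padj`.
#' @export
call_enriched <- function(chip0, input0, alpha = 0.05, min_fold = 2,
                          pseudocount = 0.5) {
  check_same_grid(chip0, input0)
  lc <- library_size(chip0)
  li <- library_size(input0)
  if (!isTRUE(lc > 0) || !isTRUE(li > 0)) {
    abort("both tracks need a positive library size")
  }
  mu <- pmax(input0$value * lc / li, pseudocount)
  p <- ppois(chip0$value - 1, mu, lower.tail = FALSE)
  out <- tibble(chrom = chip0$chrom, start = chip0$start, end = chip0$end,
                chip = chip0$value, expected = mu,
                fold = chip0$value / mu,
                p = p, padj = p.adjust(p, method = "BH"))
  out$enriched <- out$padj <= alpha & out$fold >= min_fold & out$chip > 0
  structure(out, class = c("enrichment_calls", class(tibble())),
            width = grid_width(chip0), step = grid_step(chip0),
            chrom_sizes = grid_chroms(chip0))
}

#' Write enriched windows as BED
#'
#' @param calls Result of [call_enriched()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enriched_bed <- function(calls, path) {
  e <- calls[calls$enriched, ]
  lines <- sprintf("%s\t%d\t%d\tenriched\t0\t.",
                   e$chrom, as.integer(e$start), as.integer(e$end))
  readr::write_lines(lines, path)
  invisible(path)
}
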