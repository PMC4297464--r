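#' Scale a count track to a target sequencing depth
#'
#' @param track A count `signal_track` with positive library size.
#' @param target_depth Target library size in reads.
#' @return The track with values multiplied by `target_depth /
#'   library_size` and its library size set to `target_depth`.
#' @export
normalize_counts <- function(track, target_depth) {
  ls <- library_size(track)
  if (!isTRUE(ls > 0)) abort("cannot normalize a track with zero library size")
  track_like(track, track$value * target_depth / ls, library_size = target_depth)
}

#' Raw exponential decay rate from two timepoints
#'
#' Under first-order decay N(t) = N(0) e^(-lambda t), the rate recovered
#' from counts at 0 h and `dt` h is `log((n0 + eps) / (n6 + eps)) / dt`.
#' Negative values indicate a count increase. The pseudocount guards empty
#' windows (Haldane-Anscombe convention).
#'
#' @param n0,n6 Dyad counts at 0 h and at `dt` h (vectorized).
#' @param dt Time interval in hours (> 0), default 6.
#' @param eps Pseudocount (> 0), default 0.5.
#' @return Decay rate(s) in h^-1.
#' @examples
#' raw_decay_rate(100, 50)          # ln 2 / 6 ~ 0.1155 h^-1
#' log(2) / raw_decay_rate(100, 50) # implied half-life ~ 6 h
#' @export
raw_decay_rate <- function(n0, n6, dt = 6, eps = 0.5) {
  if (dt <= 0) abort("dt must be > 0")
  if (eps <= 0) abort("eps must be > 0")
  log((n0 + eps) / (n6 + eps)) / dt
}

#' Logistic-scaled dissociation rate in [0, 1]
#'
#' `(n0 + eps) / ((n0 + eps) + (n6 + eps))` -- algebraically the logistic
#' transform `1 / (1 + exp(-lambda_raw * dt))` of the raw rate, so it maps
#' any count pair into [0, 1]: 0.5 means no net change over the interval,
#' values above 0.5 net loss, below 0.5 net gain.
#'
#' @inheritParams raw_decay_rate
#' @return Scaled dissociation rate(s) in [0, 1].
#' @examples
#' scaled_dissociation(100, 100)  # 0.5, no net change
#' scaled_dissociation(100, 50)   # 2/3, half-life = dt
#' @export
scaled_dissociation <- function(n0, n6, dt = 6, eps = 0.5) {
  if (dt <= 0) abort("dt must be > 0")
  if (eps <= 0) abort("eps must be > 0")
  (n0 + eps) / ((n0 + eps) + (n6 + eps))
}

#' Equilibrium enrichment level over input
#'
#' Steady-state tagged-histone enrichment at 0 h, as the log2 ratio of the
#' depth-normalized ChIP count to the input count.
#'
#' @param n0 Normalized ChIP dyad count at 0 h.
#' @param i0 Normalized input dyad count.
#' @param eps Pseudocount (> 0), default 0.5.
#' @return log2((n0 + eps) / (i0 + eps)); always finite.
#' @export
equilibrium_level <- function(n0, i0, eps = 0.5) {
  if (eps <= 0) abort("eps must be > 0")
  log2((n0 + eps) / (i0 + eps))
}

#' Per-window turnover estimates
#'
#' Applies [raw_decay_rate()], [scaled_dissociation()] and
#' [equilibrium_level()] window-wise, restricted to the enriched-window
#' mask; unmasked windows carry NA. The 0 h and `dt` h ChIP tracks are
#' compared as given -- the genome-wide count decline between the two
#' timepoints is the decay signal itself, so no cross-timepoint depth
#' rescaling is applied (use [normalize_counts()] first if libraries were
#' sequenced to deliberately different depths). The input track is scaled
#' to the 0 h ChIP library size before the equilibrium log-ratio.
#'
#' @param lib0,lib6 ChIP count tracks at 0 h and `dt` h (same grid).
#' @param input0 Input count track (same grid).
#' @param mask Logical vector per window, or an [call_enriched()] result.
#' @param dt Time interval in hours, default 6.
#' @param eps Pseudocount, default 0.5.
#' @return A tibble of class `turnover_estimates` with per-window columns
#'   `n0`, `n6`, `i0`, `lambda_raw`, `lambda_out`, `lambda_equ`.
#' @export
turnover_tracks <- function(lib0, lib6, input0, mask, dt = 6, eps = 0.5) {
  check_same_grid(lib0, lib6)
  check_same_grid(lib0, input0)
  if (is.data.frame(mask)) {
    check_same_grid(lib0, mask)
    mask <- mask$enriched
  }
  if (length(mask) != nrow(lib0)) abort("mask length must equal window count")
  i0 <- input0$value
  ls0 <- library_size(lib0)
  lsi <- library_size(input0)
  if (isTRUE(ls0 > 0) && isTRUE(lsi > 0)) i0 <- i0 * ls0 / lsi
  out <- tibble(
    chrom = lib0$chrom, start = lib0$start, end = lib0$end,
    enriched = mask,
    n0 = lib0$value, n6 = lib6$value, i0 = i0,
    lambda_raw = ifelse(mask, raw_decay_rate(lib0$value, lib6$value, dt, eps), NA_real_),
    lambda_out = ifelse(mask, scaled_dissociation(lib0$value, lib6$value, dt, eps), NA_real_),
    lambda_equ = ifelse(mask, equilibrium_level(lib0$value, i0, eps), NA_real_)
  )
  structure(out, class = c("turnover_estimates", class(tibble())),
            width = grid_width(lib0), step = grid_step(lib0),
            chrom_sizes = grid_chroms(lib0), dt = dt, eps = eps)
}

#' Extract one turnover quantity as a signal track
#'
#' @param estimates A [turnover_tracks()] result.
#' @param what One of `"lambda_out"`, `"lambda_raw"`, `"lambda_equ"`.
#' @param resample Optional bp width; if given, the 250-bp estimates are
#'   re-expressed on a finer non-overlapping grid (each fine window takes
#'   the value of the coarse window containing its midpoint).
#' @return A `signal_track`.
#' @export
turnover_track <- function(estimates,
                           what = c("lambda_out", "lambda_raw", "lambda_equ"),
                           resample = NULL) {
  what <- match.arg(what)
  chroms <- grid_chroms(estimates)
  g <- window_grid(chroms, width = grid_width(estimates),
                   step = grid_step(estimates))
  tr <- signal_track(g, estimates[[what]])
  if (!is.null(resample)) tr <- resample_track(tr, width = resample)
  tr
}

#' Per-locus turnover estimates from raw reads
#'
#' Locus-level counterpart of [turnover_tracks()]: counts dyads of the 0 h
#' and `dt` h libraries inside each locus interval and applies the same
#' rate equations. Used for repeat elements and for parameter-recovery
#' checks against the synthetic truth table.
#'
#' @param reads0,reads6 Read data frames for the two timepoints.
#' @param loci Interval data frame (`chrom`, `start`, `end`).
#' @param chroms Chromosome size tibble.
#' @param dt,eps As in [turnover_tracks()].
#' @param extend Read extension length in bp.
#' @return `loci` with added `n0`, `n6`, `lambda_raw`, `lambda_out`.
#' @export
locus_turnover <- function(reads0, reads6, loci, chroms, dt = 6, eps = 0.5,
                           extend = 150) {
  n0 <- locus_counts(reads0, loci, chroms, extend = extend)$count
  n6 <- locus_counts(reads6, loci, chroms, extend = extend)$count
  as_tibble(loci) |>
    mutate(n0 = n0, n6 = n6,
           lambda_raw = raw_decay_rate(n0, n6, dt, eps),
           lambda_out = scaled_dissociation(n0, n6, dt, eps))
}

#' Write the per-window turnover table
#'
#' Tab-delimited export with header columns chrom, start, end, n0, n6, i0,
#' lambda_raw, lambda_out, lambda_equ.
#'
#' @param estimates A [turnover_tracks()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_turnover_table <- function(estimates, path) {
  readr::write_tsv(
    as_tibble(estimates)[, c("chrom", "start", "end", "n0", "n6", "i0",
                             "lambda_raw", "lambda_out", "lambda_equ")],
    path, progress = FALSE)
  invisible(path)
}
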