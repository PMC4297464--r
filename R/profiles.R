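#' Standardize a signal track to mean 0, variance 1
#'
#' Population convention (divide by n, not n-1), computed over finite
#' values; missing values propagate. Used to put heterogeneous ChIP-seq
#' enrichment tracks on a common scale before profile plotting.
#'
#' @param track A `signal_track` with at least two distinct finite values.
#' @return The standardized `signal_track`.
#' @export
standardize_track <- function(track) {
  v <- track$value
  fin <- is.finite(v)
  if (length(unique(v[fin])) < 2) {
    abort("cannot standardize a constant (or empty) track")
  }
  m <- mean(v[fin])
  s <- sqrt(mean((v[fin] - m)^2))
  track_like(track, (v - m) / s, library_size = NA_real_)
}

#' Point anchors at transcription start or end sites
#'
#' @param transcripts Transcript table with `chrom`, `start`, `end`,
#'   `strand`.
#' @param at `"tss"` or `"tes"`.
#' @return Anchor tibble of 1-bp intervals with strand: the TSS of a
#'   minus-strand transcript is its end coordinate, its TES the start.
#' @export
transcript_anchors <- function(transcripts, at = c("tss", "tes")) {
  at <- match.arg(at)
  plus <- transcripts$strand == "+"
  pos <- if (at == "tss") {
    ifelse(plus, transcripts$start, transcripts$end - 1)
  } else {
    ifelse(plus, transcripts$end - 1, transcripts$start)
  }
  tibble(anchor_id = transcripts$transcript_id %||%
           sprintf("anchor%05d", seq_len(nrow(transcripts))),
         chrom = transcripts$chrom, start = pos, end = pos + 1,
         strand = transcripts$strand)
}

# Per-chromosome search index over a track's window midpoints: sorted
# midpoints plus cumulative sums for O(1) finite-mean queries on a range.
track_index <- function(track) {
  idx <- split(seq_len(nrow(track)), track$chrom)
  purrr::map(idx, function(i) {
    mids <- window_mid(track[i, ])
    o <- order(mids)
    v <- track$value[i][o]
    fin <- is.finite(v)
    list(mids = mids[o],
         csum = cumsum(ifelse(fin, v, 0)),
         cnt = cumsum(fin))
  })
}

index_mean <- function(ix, lo, hi) {
  # mean of finite values at midpoints in [lo, hi)
  a <- findInterval(lo - 0.5, ix$mids)
  b <- findInterval(hi - 0.5, ix$mids)
  if (b <= a) return(c(NA_real_, 0))
  s <- ix$csum[b] - if (a > 0) ix$csum[a] else 0
  k <- ix$cnt[b] - if (a > 0) ix$cnt[a] else 0
  if (k == 0) c(NA_real_, 0) else c(s / k, k)
}

#' Anchor-centered profile matrix
#'
#' One row per anchor, one column per offset bin: the mean track value in
#' the `bin`-bp window centered at each offset from the anchor point
#' (interval anchors are reduced to their midpoints). With
#' `oriented = TRUE`, rows of minus-strand anchors are flipped so
#' positive offsets always point downstream of transcription.
#' Out-of-bounds bins and bins with no underlying windows are missing.
#'
#' @param track A `signal_track` (any grid; bin means are taken over the
#'   track windows whose midpoints fall in the bin).
#' @param anchors Data frame with `chrom`, `start`, `end` and optionally
#'   `strand` and `anchor_id`.
#' @param flank Half-width of the profiled region in bp; must be a
#'   multiple of `bin`.
#' @param bin Bin width in bp, default 100.
#' @param step Offset between consecutive bin centers, default `bin`
#'   (set 10 for 100-bp sliding bins).
#' @param oriented Flip minus-strand rows? Default TRUE.
#' @return Long tibble of class `profile_matrix`: `anchor_id`, `offset`
#'   (bin center, bp), `value`, `n` (windows behind the mean).
#' @export
profile_matrix <- function(track, anchors, flank, bin = 100, step = bin,
                           oriented = TRUE) {
  if (flank %% bin != 0) abort("flank must be a multiple of bin")
  anchors <- as_tibble(anchors)
  if (!("strand" %in% names(anchors))) anchors$strand <- "."
  if (!("anchor_id" %in% names(anchors))) {
    anchors$anchor_id <- sprintf("anchor%05d", seq_len(nrow(anchors)))
  }
  offsets <- seq(-flank + bin / 2, flank - bin / 2, by = step)
  ix <- track_index(track)
  chroms <- grid_chroms(track)
  out <- purrr::pmap_dfr(
    anchors[, c("anchor_id", "chrom", "start", "end", "strand")],
    function(anchor_id, chrom, start, end, strand) {
      p <- start + (end - start) %/% 2
      sgn <- if (oriented && strand == "-") -1 else 1
      g <- p + sgn * offsets
      lo <- g - bin / 2
      hi <- g + bin / 2
      len <- chroms$length[match(chrom, chroms$name)]
      res <- vapply(seq_along(offsets), function(i) {
        if (lo[i] < 0 || hi[i] > len) return(c(NA_real_, 0))
        index_mean(ix[[chrom]], lo[i], hi[i])
      }, numeric(2))
      tibble(anchor_id = anchor_id, offset = offsets,
             value = res[1, ], n = as.integer(res[2, ]))
    })
  structure(out, class = c("profile_matrix", class(tibble())),
            bin = bin, step = step, flank = flank, oriented = oriented)
}

#' Group-averaged metaprofile curves
#'
#' Column-wise means of a profile matrix over anchor groups, with the
#' number of finite contributions tracked per offset. Empty groups are
#' dropped with a warning.
#'
#' @param pm A [profile_matrix()].
#' @param groups Named character/factor vector or data frame
#'   (`anchor_id`, `group`) labelling every anchor; NULL pools all
#'   anchors into one group.
#' @return Tibble of class `profile_curves`: `group`, `offset`, `mean`,
#'   `n`.
#' @export
mean_profile <- function(pm, groups = NULL) {
  pm <- as_tibble(pm)
  if (is.null(groups)) {
    lab <- tibble(anchor_id = unique(pm$anchor_id), group = "all")
  } else if (is.data.frame(groups)) {
    lab <- as_tibble(groups)[, c("anchor_id", "group")]
  } else {
    lab <- tibble(anchor_id = names(groups), group = as.character(groups))
  }
  missing_lab <- setdiff(unique(pm$anchor_id), lab$anchor_id)
  if (length(missing_lab)) abort("every anchor must be labelled")
  empty <- setdiff(lab$group, lab$group[lab$anchor_id %in% pm$anchor_id])
  if (length(empty)) {
    warn(paste("dropping empty group(s):", paste(empty, collapse = ", ")))
  }
  out <- pm |>
    left_join(lab, by = "anchor_id") |>
    group_by(.data$group, .data$offset) |>
    summarise(mean = if (any(is.finite(.data$value)))
                mean(.data$value[is.finite(.data$value)]) else NA_real_,
              n = sum(is.finite(.data$value)), .groups = "drop")
  structure(out, class = c("profile_curves", class(tibble())))
}

#' Mean signal per feature set around site midpoints
#'
#' The heatmap summary: for each (feature set, track) pair, the mean of
#' finite track values over all windows whose midpoints fall within
#' `flank` bp of any site midpoint (each site contributes its own
#' windows, so windows shared between nearby sites count once per site).
#'
#' @param tracks Named list of `signal_track`s.
#' @param feature_sets Named list of interval data frames.
#' @param flank Half-width in bp, default 5000 (a 10-kbp region).
#' @return Tibble of class `region_summary`: `feature_set`, `track`,
#'   `mean`, `n_windows`.
#' @export
region_summary <- function(tracks, feature_sets, flank = 5000) {
  if (!length(tracks) || !length(feature_sets)) {
    abort("need at least one track and one feature set")
  }
  out <- purrr::imap_dfr(tracks, function(tr, tr_name) {
    ix <- track_index(tr)
    purrr::imap_dfr(feature_sets, function(fs, fs_name) {
      tot <- 0; cnt <- 0
      for (i in seq_len(nrow(fs))) {
        ch <- fs$chrom[i]
        if (!ch %in% names(ix)) next
        p <- fs$start[i] + (fs$end[i] - fs$start[i]) %/% 2
        r <- index_mean(ix[[ch]], p - flank, p + flank)
        if (r[2] > 0) { tot <- tot + r[1] * r[2]; cnt <- cnt + r[2] }
      }
      tibble(feature_set = fs_name, track = tr_name,
             mean = if (cnt > 0) tot / cnt else NA_real_,
             n_windows = as.integer(cnt))
    })
  })
  structure(out, class = c("region_summary", class(tibble())))
}
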