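#' Chromosome size table
#'
#' Builds the chromosome table that anchors every window grid and every
#' coordinate check in the package. Coordinates throughout are 0-based,
#' half-open (BED convention).
#'
#' @param name Character vector of chromosome labels (unique).
#' @param length Integer vector of chromosome lengths in bp (each >= 10000,
#'   so a chromosome can hold at least a handful of analysis windows).
#' @return A tibble with columns `name` and `length`.
#' @examples
#' chrom_sizes(c("chrS1", "chrS2"), c(2e5, 1e5))
#' @export
chrom_sizes <- function(name, length) {
  if (anyDuplicated(name)) abort("chromosome names must be unique")
  length <- as.numeric(length)
  if (any(!is.finite(length)) || any(length < 10000)) {
    abort("chromosome lengths must be finite and >= 10,000 bp")
  }
  tibble(name = as.character(name), length = length)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a tab-delimited file with columns name, length.
#' @return A chromosome size tibble.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("name", "length"),
                       col_types = "cd", progress = FALSE)
  chrom_sizes(x$name, x$length)
}

#' Tile chromosomes into a window grid
#'
#' Windows start at coordinate 0 on every chromosome and advance by `step`;
#' the last, possibly partial, window is kept. `step < width` yields a
#' sliding grid (used for 100-bp profile bins), `step == width` a
#' non-overlapping tiling (the 250-bp counting grid, the 10-bp export grid).
#'
#' @param chroms Chromosome size tibble from [chrom_sizes()].
#' @param width Window width in bp (> 0).
#' @param step Distance between window starts in bp (0 < step <= width).
#' @return A tibble of class `window_grid` with columns `chrom`, `start`,
#'   `end`, carrying `width`, `step` and the chromosome table as attributes.
#' @examples
#' window_grid(chrom_sizes("chrS1", 1e4), width = 250)
#' @export
window_grid <- function(chroms, width, step = width) {
  stopifnot(is.data.frame(chroms), all(c("name", "length") %in% names(chroms)))
  if (width <= 0 || step <= 0 || step > width) {
    abort("need width > 0 and 0 < step <= width")
  }
  g <- purrr::map2_dfr(chroms$name, chroms$length, function(nm, len) {
    starts <- seq(0, len - 1, by = step)
    tibble(chrom = nm, start = starts, end = pmin(starts + width, len))
  })
  structure(g,
            class = c("window_grid", class(tibble())),
            width = width, step = step, chrom_sizes = chroms)
}

grid_width <- function(x) attr(x, "width", exact = TRUE)
grid_step <- function(x) attr(x, "step", exact = TRUE)
grid_chroms <- function(x) attr(x, "chrom_sizes", exact = TRUE)

#' Attach values to a window grid, forming a signal track
#'
#' A signal track is the package's per-window quantitative container:
#' dyad counts, filtered counts, dissociation rates, equilibrium levels
#' and standardized signal all live on it.
#'
#' @param grid A [window_grid()].
#' @param values Numeric vector, one value per window (NA = missing).
#' @param library_size Total reads behind a count track (NA for derived
#'   tracks such as rates).
#' @return A tibble of class `signal_track` with columns `chrom`, `start`,
#'   `end`, `value`.
#' @export
signal_track <- function(grid, values, library_size = NA_real_) {
  if (length(values) != nrow(grid)) {
    abort("need exactly one value per window")
  }
  if (!is.na(library_size) && isTRUE(any(values[is.finite(values)] < 0))) {
    abort("count tracks cannot hold negative values")
  }
  out <- tibble(chrom = grid$chrom, start = grid$start, end = grid$end,
                value = as.numeric(values))
  structure(out,
            class = c("signal_track", class(tibble())),
            width = grid_width(grid), step = grid_step(grid),
            chrom_sizes = grid_chroms(grid),
            library_size = as.numeric(library_size))
}

library_size <- function(track) attr(track, "library_size", exact = TRUE)

track_like <- function(template, values, library_size = NULL) {
  signal_track(template, values,
               library_size %||% attr(template, "library_size", exact = TRUE))
}

same_grid <- function(a, b) {
  nrow(a) == nrow(b) &&
    identical(a$chrom, b$chrom) &&
    identical(a$start, b$start) &&
    identical(a$end, b$end)
}

check_same_grid <- function(a, b) {
  if (!same_grid(a, b)) abort("tracks are not on the same window grid")
  invisible(TRUE)
}

window_mid <- function(x) x$start + (x$end - x$start) %/% 2

#' Resample a non-overlapping track onto a finer grid
#'
#' Each target window takes the value of the source window containing its
#' midpoint. This is how 250-bp rate tracks are exported at 10-bp
#' resolution for replicate-concordance analysis.
#'
#' @param track A `signal_track` on a non-overlapping grid.
#' @param width Target window width in bp (non-overlapping).
#' @return A `signal_track` on the `width`-bp tiling of the same genome.
#' @export
resample_track <- function(track, width = 10) {
  src_w <- grid_width(track)
  if (grid_step(track) != src_w) {
    abort("resampling requires a non-overlapping source grid")
  }
  chroms <- grid_chroms(track)
  tgt <- window_grid(chroms, width = width)
  # source window index of each target midpoint, per chromosome
  src <- as_tibble(track) |>
    mutate(.idx = row_number()) |>
    group_by(.data$chrom) |>
    mutate(.local = row_number()) |>
    ungroup()
  first_idx <- src |>
    group_by(.data$chrom) |>
    summarise(.first = min(.data$.idx), .n = n())
  tg <- as_tibble(tgt) |>
    left_join(first_idx, by = "chrom") |>
    mutate(mid = window_mid(tgt),
           local = .data$mid %/% src_w,
           ok = .data$local < .data$.n)
  vals <- rep(NA_real_, nrow(tg))
  vals[tg$ok] <- track$value[tg$.first[tg$ok] + tg$local[tg$ok]]
  signal_track(tgt, vals, library_size(track))
}

#' Write a track as bedGraph
#'
#' Windows with missing values are skipped; values are printed with six
#' decimals (fixed notation).
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  keep <- is.finite(track$value)
  lines <- sprintf("%s\t%d\t%d\t%.6f",
                   track$chrom[keep], as.integer(track$start[keep]),
                   as.integer(track$end[keep]), track$value[keep])
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a bedGraph file onto a known grid
#'
#' @param path bedGraph path.
#' @param grid The [window_grid()] the file was written from.
#' @param library_size Optional library size to attach.
#' @return A `signal_track`; windows absent from the file are NA.
#' @export
read_bedgraph <- function(path, grid, library_size = NA_real_) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                       col_types = "ciid", progress = FALSE)
  key_grid <- paste(grid$chrom, grid$start)
  vals <- rep(NA_real_, nrow(grid))
  idx <- match(paste(x$chrom, x$start), key_grid)
  if (anyNA(idx)) abort("bedGraph contains windows absent from the grid")
  vals[idx] <- x$value
  signal_track(grid, vals, library_size)
}
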