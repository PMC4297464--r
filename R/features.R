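#' Bin transcripts by expression level
#'
#' FPKM stratification into five classes: top10 (> 30 FPKM), top20
#' (10-30], medium (3-10], low (1-3], silent [0-1]. Boundaries are
#' upper-inclusive so the verbal ranges tile [0, Inf) without gaps.
#'
#' @param fpkm Non-negative numeric vector of FPKM values.
#' @return Ordered factor with levels silent < low < medium < top20 <
#'   top10.
#' @examples
#' bin_expression(c(0.5, 2, 35))
#' @export
bin_expression <- function(fpkm) {
  if (any(!is.finite(fpkm)) || any(fpkm < 0)) {
    abort("fpkm must be finite and non-negative")
  }
  cut(fpkm, breaks = c(0, 1, 3, 10, 30, Inf),
      labels = c("silent", "low", "medium", "top20", "top10"),
      include.lowest = TRUE, right = TRUE, ordered_result = TRUE)
}

features_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}

# Minimum gap distance (bp) from each query interval to the subject set;
# overlap or adjacency = 0, no subject on the chromosome = NA. Strand is
# ignored.
nearest_gap <- function(query, subject) {
  q <- features_gr(query)
  s <- features_gr(subject)
  hits <- GenomicRanges::distanceToNearest(q, s, ignore.strand = TRUE)
  d <- rep(NA_real_, nrow(query))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  d
}

#' Classify sites as gene-proximal or distal
#'
#' A site is proximal iff its minimum gap distance to any transcript span
#' (TSS to TES) is at most `cutoff` bp; overlapping sites have distance 0
#' and the cutoff is inclusive. Sites on chromosomes with no annotated
#' transcript are classified distal (with a message), not rejected.
#'
#' @param sites Interval data frame (`chrom`, `start`, `end`).
#' @param transcripts Transcript table (`chrom`, `start`, `end`;
#'   `transcript_id`, `strand` ignored here).
#' @param cutoff Distance cutoff in bp, default 5000.
#' @param exons Optional exon table; when supplied, distances are
#'   measured to exons rather than to full transcript spans.
#' @return `sites` with added columns `dist_to_transcript` and `class`
#'   (`"proximal"`/`"distal"`).
#' @export
classify_proximity <- function(sites, transcripts, cutoff = 5000,
                               exons = NULL) {
  if (nrow(transcripts) == 0) abort("transcript set is empty")
  target <- exons %||% transcripts
  d <- nearest_gap(sites, target)
  if (anyNA(d)) {
    inform(sprintf(
      "%d site(s) on chromosomes without transcripts: classified distal",
      sum(is.na(d))))
  }
  as_tibble(sites) |>
    mutate(dist_to_transcript = d,
           class = ifelse(!is.na(d) & d <= cutoff, "proximal", "distal"))
}

#' Classify repeat elements as genic or non-genic
#'
#' Same distance rule as [classify_proximity()] with a 2-kb cutoff:
#' repeats within 2 kb of a known transcript are genic, others non-genic.
#'
#' @inheritParams classify_proximity
#' @param repeats Repeat interval data frame (family label in `name`).
#' @param cutoff Distance cutoff in bp, default 2000.
#' @return `repeats` with added `dist_to_transcript` and `class`
#'   (`"genic"`/`"non_genic"`).
#' @export
classify_repeats <- function(repeats, transcripts, cutoff = 2000,
                             exons = NULL) {
  out <- classify_proximity(repeats, transcripts, cutoff = cutoff,
                            exons = exons)
  out$class <- ifelse(out$class == "proximal", "genic", "non_genic")
  out
}

#' Flag repeats bound by transcription-factor peaks
#'
#' A repeat is bound for a peak set iff it overlaps at least one peak by
#' at least `min_overlap` bp; the `any` flag is the union over sets, so a
#' repeat hit by several factors counts once. Bound fractions are
#' reported per repeat group (by `group_by` columns when present).
#'
#' @param repeats Repeat data frame (`chrom`, `start`, `end`; optional
#'   grouping columns such as `name` (family) and `class`).
#' @param peak_sets Named list of peak interval data frames.
#' @param min_overlap Minimum overlap in bp, default 1.
#' @param group_by Character vector of repeat columns to summarise over;
#'   defaults to whichever of `name`, `class` are present.
#' @return List with `repeats` (input plus logical `bound_<set>` columns
#'   and `bound_any`) and `summary` (tibble: group columns, `peak_set`,
#'   `n`, `n_bound`, `fraction`), including a `peak_set = "any"` row per
#'   group.
#' @export
tf_binding_overlap <- function(repeats, peak_sets, min_overlap = 1,
                               group_by = NULL) {
  if (!length(peak_sets)) abort("need at least one peak set")
  if (is.null(names(peak_sets)) || any(names(peak_sets) == "")) {
    abort("peak_sets must be a named list")
  }
  repeats <- as_tibble(repeats)
  group_by <- group_by %||% intersect(c("name", "class"), names(repeats))
  if (nrow(repeats) == 0) {
    return(list(repeats = repeats,
                summary = tibble(peak_set = character(), n = integer(),
                                 n_bound = integer(), fraction = numeric())))
  }
  rgr <- features_gr(repeats)
  flags <- purrr::map(peak_sets, function(p) {
    if (nrow(p) == 0) return(rep(FALSE, nrow(repeats)))
    GenomicRanges::countOverlaps(rgr, features_gr(p),
                                 minoverlap = min_overlap) > 0
  })
  for (nm in names(flags)) repeats[[paste0("bound_", nm)]] <- flags[[nm]]
  repeats$bound_any <- Reduce(`|`, flags)

  summarise_set <- function(flag, set_name) {
    repeats |>
      mutate(.bound = flag) |>
      group_by(across(all_of(group_by))) |>
      summarise(peak_set = set_name, n = n(),
                n_bound = sum(.data$.bound),
                fraction = mean(.data$.bound), .groups = "drop")
  }
  summary <- bind_rows(c(purrr::imap(flags, summarise_set),
                         list(summarise_set(repeats$bound_any, "any"))))
  list(repeats = repeats, summary = summary)
}
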