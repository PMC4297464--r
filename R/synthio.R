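#' Settings for the synthetic TET-OFF genome generator
#'
#' Defaults encode the qualitative rate regimes seen genome-wide:
#' promoter-proximal nucleosome-depleted regions (NDRs) and distal
#' regulatory sites exchange H3.3 fast, gene bodies more slowly, and
#' heterochromatin barely at all; non-genic satellite repeats are fast.
#' Rates are in h^-1; occupancy is the expected dyad count per locus at
#' 0 h at unit depth.
#'
#' @param n_genes Number of synthetic transcripts (each contributes one
#'   NDR, one TSS-flank locus and one gene-body locus).
#' @param n_heterochromatin,n_distal,n_satellite,n_background Counts of
#'   stand-alone loci per archetype.
#' @param rate_ranges Named list of `c(min, max)` decay-rate ranges per
#'   archetype; the default ordering ndr > satellite_repeat > distal_site
#'   > tss_flank > gene_body > heterochromatin is preserved by
#'   construction.
#' @param occupancy Named list of mean 0 h dyad densities per archetype,
#'   in expected dyads per 100 bp of locus at unit depth (a locus's total
#'   expected count scales with its width).
#' @param equ_coupling Strength of the positive coupling between a locus's
#'   decay rate and its 0 h occupancy (0 decouples them); with positive
#'   coupling, fast-exchanging loci are also the most enriched at
#'   equilibrium.
#' @param occupancy_cv Lognormal sdlog of per-locus occupancy noise.
#' @param gene_width,gap Ranges (bp) for transcript spans and inter-locus
#'   spacing.
#' @param read_length Simulated read length in bp (metadata only; rate
#'   estimation extends reads to 150 bp downstream).
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_genes = 30,
                         n_heterochromatin = 10,
                         n_distal = 30,
                         n_satellite = 30,
                         n_background = 20,
                         rate_ranges = list(
                           ndr = c(0.2, 0.5),
                           satellite_repeat = c(0.15, 0.4),
                           distal_site = c(0.12, 0.3),
                           tss_flank = c(0.06, 0.15),
                           gene_body = c(0.02, 0.08),
                           heterochromatin = c(0, 0.02),
                           background = c(0.01, 0.1)
                         ),
                         occupancy = list(
                           ndr = 40, tss_flank = 25, gene_body = 15,
                           distal_site = 30, satellite_repeat = 30,
                           heterochromatin = 10, background = 1
                         ),
                         equ_coupling = 2,
                         occupancy_cv = 0.25,
                         gene_width = c(2000, 5000),
                         gap = c(200, 800),
                         read_length = 36) {
  p <- list(n_genes = n_genes, n_heterochromatin = n_heterochromatin,
            n_distal = n_distal, n_satellite = n_satellite,
            n_background = n_background, rate_ranges = rate_ranges,
            occupancy = occupancy, equ_coupling = equ_coupling,
            occupancy_cv = occupancy_cv, gene_width = gene_width,
            gap = gap, read_length = read_length)
  structure(p, class = "synth_params")
}

ARCHETYPES <- c("ndr", "tss_flank", "gene_body", "heterochromatin",
                "distal_site", "satellite_repeat", "background")

#' Validate and label a truth table
#'
#' The truth table is the parameter-recovery oracle: one row per synthetic
#' locus with its archetype, expected 0 h occupancy and true decay rate.
#'
#' @param loci Data frame with columns `chrom`, `start`, `end`,
#'   `archetype`, `occupancy0`, `true_lambda` (optionally `locus_id`,
#'   `strand`).
#' @param chroms Chromosome size tibble.
#' @return A tibble of class `truth_table` with the chromosome table
#'   attached as an attribute.
#' @export
truth_table <- function(loci, chroms) {
  loci <- as_tibble(loci)
  need <- c("chrom", "start", "end", "archetype", "occupancy0", "true_lambda")
  if (!all(need %in% names(loci))) {
    abort(paste("truth table needs columns:", paste(need, collapse = ", ")))
  }
  if (!("locus_id" %in% names(loci))) {
    loci$locus_id <- sprintf("locus%05d", seq_len(nrow(loci)))
  }
  if (any(loci$occupancy0 < 0)) abort("occupancy0 must be >= 0")
  if (any(loci$true_lambda < 0)) abort("true_lambda must be >= 0")
  if (!all(loci$archetype %in% ARCHETYPES)) {
    abort("unknown archetype in truth table")
  }
  len <- chroms$length[match(loci$chrom, chroms$name)]
  if (anyNA(len) || any(loci$start < 0) || any(loci$end > len) ||
      any(loci$start >= loci$end)) {
    abort("locus intervals must lie within chromosome bounds")
  }
  structure(loci, class = c("truth_table", class(tibble())),
            chrom_sizes = chroms)
}

#' Expected dyad counts under the decay model
#'
#' For each locus and timepoint, the noiseless expectation
#' `occupancy0 * depth * exp(-true_lambda * t)`.
#'
#' @param truth A [truth_table()].
#' @param timepoints Hours after shut-off.
#' @param depth Reads per unit occupancy.
#' @return Long tibble with `locus_id`, `archetype`, `true_lambda`,
#'   `timepoint`, `expected`.
#' @export
expected_counts <- function(truth, timepoints = c(0, 6), depth = 1) {
  tidyr::crossing(as_tibble(truth)[, c("locus_id", "archetype", "occupancy0",
                                       "true_lambda")],
                  timepoint = timepoints) |>
    mutate(expected = .data$occupancy0 * depth *
             exp(-.data$true_lambda * .data$timepoint)) |>
    select(-"occupancy0")
}

sub_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647) * 31 + i * 1000003) %% 2147483647L
}

runif_int <- function(n, lo, hi) floor(runif(n, lo, hi + 1))

#' Generate a synthetic annotated genome with known decay rates
#'
#' Lays out non-overlapping loci of seven archetypes across the given
#' chromosomes and assigns each a true decay rate drawn from its
#' archetype's range and a 0 h occupancy (optionally coupled to the rate).
#' Each synthetic gene carries a strand, TSS, TES and exons, a gene-body
#' locus, an NDR locus placed 50-100 bp upstream of its TSS, and two
#' TSS-flank loci (the first 300 bp of the transcript and the -1
#' nucleosome territory 100-450 bp upstream), so the fast-exchanging NDR
#' sits in a moderate-turnover promoter context on both sides.
#' Deterministic for a fixed seed.
#'
#' @param chroms Chromosome size tibble.
#' @param params A [synth_params()] list.
#' @param seed Integer master seed.
#' @return A list of class `h3_annotation`: `truth` (a [truth_table()]),
#'   `transcripts`, `exons`, `expression`, `chrom_sizes`, `params`,
#'   `seed`.
#' @export
build_annotation <- function(chroms, params = synth_params(), seed = 1) {
  withr::with_seed(sub_seed(seed, 1), {
    # entity widths; gene blocks reserve 600 bp of upstream/promoter space
    # so profile flanks up to ~500 bp see no neighbouring locus
    gw <- runif_int(params$n_genes, params$gene_width[1], params$gene_width[2])
    ent <- bind_rows(
      tibble(kind = "gene", width = gw + 600,
             id = sprintf("tx%04d", seq_len(params$n_genes))),
      tibble(kind = "heterochromatin",
             width = runif_int(params$n_heterochromatin, 2000, 4000),
             id = sprintf("het%04d", seq_len(params$n_heterochromatin))),
      tibble(kind = "distal_site",
             width = runif_int(params$n_distal, 200, 400),
             id = sprintf("dist%04d", seq_len(params$n_distal))),
      tibble(kind = "satellite_repeat",
             width = runif_int(params$n_satellite, 200, 500),
             id = sprintf("sat%04d", seq_len(params$n_satellite))),
      tibble(kind = "background",
             width = runif_int(params$n_background, 200, 500),
             id = sprintf("bg%04d", seq_len(params$n_background)))
    )
    ent <- ent[sample.int(nrow(ent)), ]
    ent$strand <- sample(c("+", "-"), nrow(ent), replace = TRUE)
    ent$gap <- runif_int(nrow(ent), params$gap[1], params$gap[2])

    cursor <- setNames(rep(300, nrow(chroms)), chroms$name)
    placed <- vector("list", nrow(ent))
    for (i in seq_len(nrow(ent))) {
      need <- ent$width[i] + ent$gap[i]
      room <- chroms$length - 300 - cursor[chroms$name]
      ok <- which(room >= need)
      if (!length(ok)) {
        abort("requested loci exceed genome capacity: enlarge chromosomes or reduce counts")
      }
      ch <- chroms$name[ok[which.max(room[ok])]]
      start <- unname(cursor[ch] + ent$gap[i])
      cursor[ch] <- start + ent$width[i]
      placed[[i]] <- tibble(kind = ent$kind[i], id = ent$id[i],
                            chrom = ch, start = start,
                            end = start + ent$width[i],
                            strand = ent$strand[i])
    }
    placed <- bind_rows(placed)

    draw_rate <- function(kind, n) {
      r <- params$rate_ranges[[kind]]
      runif(n, r[1], r[2])
    }
    draw_occ <- function(kind, lambda, width) {
      params$occupancy[[kind]] * width / 100 *
        (1 + params$equ_coupling * lambda) *
        rlnorm(length(lambda), 0, params$occupancy_cv)
    }
    mk_loci <- function(df, kind) {
      lam <- draw_rate(kind, nrow(df))
      tibble(chrom = df$chrom, start = df$start, end = df$end,
             strand = df$strand %||% ".", archetype = kind,
             occupancy0 = draw_occ(kind, lam, df$end - df$start),
             true_lambda = lam,
             locus_id = paste0(kind, "_", df$id))
    }

    genes <- placed[placed$kind == "gene", ]
    gsp <- genes |> mutate(
      tss = ifelse(.data$strand == "+", .data$start + 600, .data$end - 600),
      gstart = ifelse(.data$strand == "+", .data$tss, .data$start),
      gend = ifelse(.data$strand == "+", .data$end, .data$tss))
    transcripts <- tibble(transcript_id = gsp$id, chrom = gsp$chrom,
                          start = gsp$gstart, end = gsp$gend,
                          strand = gsp$strand)
    # NDR occupies offsets [-100, -50) upstream of the TSS, strand-aware
    ndr <- tibble(chrom = gsp$chrom,
                  start = ifelse(gsp$strand == "+", gsp$tss - 100, gsp$gend + 50),
                  end = ifelse(gsp$strand == "+", gsp$tss - 50, gsp$gend + 100),
                  strand = gsp$strand, id = gsp$id)
    flank <- tibble(chrom = gsp$chrom,
                    start = ifelse(gsp$strand == "+", gsp$gstart, gsp$gend - 300),
                    end = ifelse(gsp$strand == "+", gsp$gstart + 300, gsp$gend),
                    strand = gsp$strand, id = gsp$id)
    # upstream promoter flank (-1 nucleosome territory beyond the NDR)
    upflank <- tibble(chrom = gsp$chrom,
                      start = ifelse(gsp$strand == "+", gsp$tss - 450,
                                     gsp$gend + 100),
                      end = ifelse(gsp$strand == "+", gsp$tss - 100,
                                   gsp$gend + 450),
                      strand = gsp$strand, id = paste0(gsp$id, "u"))
    gl <- gsp$gend - gsp$gstart
    body_w <- pmin(800, gl %/% 3)
    body <- tibble(chrom = gsp$chrom,
                   start = gsp$gstart + gl %/% 2 - body_w %/% 2,
                   end = gsp$gstart + gl %/% 2 + body_w %/% 2,
                   strand = gsp$strand, id = gsp$id)

    loci <- bind_rows(
      mk_loci(ndr, "ndr"),
      mk_loci(flank, "tss_flank"),
      mk_loci(upflank, "tss_flank"),
      mk_loci(body, "gene_body"),
      mk_loci(placed[placed$kind == "heterochromatin", ], "heterochromatin"),
      mk_loci(placed[placed$kind == "distal_site", ], "distal_site"),
      mk_loci(placed[placed$kind == "satellite_repeat", ], "satellite_repeat"),
      mk_loci(placed[placed$kind == "background", ], "background")
    ) |> arrange(.data$chrom, .data$start)

    # exons: split each transcript into 2-4 exons with internal introns
    exons <- purrr::pmap_dfr(
      list(transcripts$transcript_id, transcripts$start, transcripts$end),
      function(id, s, e) {
        n_ex <- sample(2:4, 1)
        cuts <- sort(runif_int(2 * (n_ex - 1), s + 100, e - 100))
        bounds <- c(s, cuts, e)
        starts <- bounds[seq(1, length(bounds), by = 2)]
        ends <- bounds[seq(2, length(bounds), by = 2)]
        keep <- starts < ends
        tibble(transcript_id = id, start = starts[keep], end = ends[keep])
      })
    exons <- left_join(exons,
                       transcripts[, c("transcript_id", "chrom")],
                       by = "transcript_id") |>
      select("transcript_id", "chrom", "start", "end")

    expression <- tibble(transcript_id = transcripts$transcript_id,
                         fpkm = rlnorm(nrow(transcripts), meanlog = 1.2,
                                       sdlog = 1.6))

    structure(list(truth = truth_table(loci, chroms),
                   transcripts = transcripts, exons = exons,
                   expression = expression, chrom_sizes = chroms,
                   params = params, seed = seed),
              class = "h3_annotation")
  })
}

#' Simulate TET-OFF time-course read libraries
#'
#' For every locus, replicate and timepoint, the read count is drawn
#' Poisson with mean `occupancy0 * depth * exp(-true_lambda * t)` and
#' strands are random. Read placement emulates sequencing the ends of
#' nucleosome-sized fragments: each read's dyad (the midpoint of its
#' 150-bp extension) is uniform within the locus, so downstream read
#' extension recovers occupancy at the locus itself
#' (`position_mode = "fragment"`, the default). With
#' `position_mode = "uniform5p"` the raw 5' positions are uniform within
#' the locus instead, which smears extended dyads up to 75 bp beyond the
#' locus edges. An input library per replicate covers the genome
#' uniformly. Each library uses a distinct sub-seed derived from the
#' master seed, so the whole simulation is reproducible and replicates
#' are independent.
#'
#' @param truth A [truth_table()].
#' @param timepoints Hours after shut-off; must contain 0 and 6 (the rate
#'   interval), further points (12, 24, 48, ...) optional.
#' @param depth Mean reads per unit occupancy (> 0).
#' @param n_replicates Number of replicate ChIP/input library pairs.
#' @param input_reads_per_kb Mean input coverage, reads per kb of genome.
#' @param position_mode `"fragment"` (dyad uniform in the locus) or
#'   `"uniform5p"` (5' end uniform in the locus).
#' @param extend Extension length (bp) the analysis will apply; fixes the
#'   5'-to-dyad offset used by fragment placement.
#' @param seed Integer master seed.
#' @return A tibble of class `synth_reads` with columns `chrom`,
#'   `five_prime`, `strand`, `library` ("chip"/"input"), `timepoint`
#'   (NA for input) and `replicate`.
#' @export
simulate_reads <- function(truth, timepoints = c(0, 6), depth = 1,
                           n_replicates = 1, input_reads_per_kb = 50,
                           position_mode = c("fragment", "uniform5p"),
                           extend = 150, seed = 1) {
  position_mode <- match.arg(position_mode)
  if (any(timepoints < 0)) abort("timepoints must be non-negative")
  if (!all(c(0, 6) %in% timepoints)) {
    abort("timepoints must include 0 and 6 (the rate interval)")
  }
  if (depth <= 0) abort("depth must be > 0")
  chroms <- attr(truth, "chrom_sizes", exact = TRUE)
  if (is.null(chroms)) abort("truth table lacks its chromosome table")
  timepoints <- sort(unique(timepoints))

  libs <- tidyr::crossing(replicate = seq_len(n_replicates),
                          timepoint = c(timepoints, NA_real_))
  out <- purrr::pmap_dfr(libs, function(replicate, timepoint) {
    s <- sub_seed(seed, replicate * 101 +
                    ifelse(is.na(timepoint), 97, timepoint + 2))
    withr::with_seed(s, {
      if (is.na(timepoint)) {
        n_per <- rpois(nrow(chroms), input_reads_per_kb * chroms$length / 1000)
        tibble(chrom = rep(chroms$name, n_per),
               five_prime = floor(runif(sum(n_per), 0,
                                        rep(chroms$length, n_per))),
               strand = sample(c("+", "-"), sum(n_per), replace = TRUE),
               library = "input", timepoint = NA_real_,
               replicate = replicate)
      } else {
        mu <- truth$occupancy0 * depth * exp(-truth$true_lambda * timepoint)
        n <- rpois(length(mu), mu)
        pos <- floor(runif(sum(n), rep(truth$start, n), rep(truth$end, n)))
        strand <- sample(c("+", "-"), sum(n), replace = TRUE)
        if (position_mode == "fragment") {
          # place the 5' end so the extended read's dyad equals pos
          pos <- ifelse(strand == "+", pos - extend %/% 2,
                        pos + (extend - 1) %/% 2)
          len <- chroms$length[match(rep(truth$chrom, n), chroms$name)]
          pos <- pmin(pmax(pos, 0), len - 1)
        }
        tibble(chrom = rep(truth$chrom, n),
               five_prime = pos,
               strand = strand,
               library = "chip", timepoint = timepoint,
               replicate = replicate)
      }
    })
  })
  structure(out, class = c("synth_reads", class(tibble())),
            chrom_sizes = chroms, depth = depth, timepoints = timepoints,
            seed = seed)
}

#' Select one library from a simulated read set
#'
#' @param sim A [simulate_reads()] result.
#' @param timepoint Hours, or NA for the input library.
#' @param replicate Replicate index.
#' @return A read tibble (`chrom`, `five_prime`, `strand`).
#' @export
get_library <- function(sim, timepoint, replicate = 1) {
  sel <- if (is.na(timepoint)) {
    sim$library == "input" & sim$replicate == replicate
  } else {
    sim$library == "chip" & sim$replicate == replicate &
      sim$timepoint == timepoint
  }
  as_tibble(sim)[sel, c("chrom", "five_prime", "strand")]
}

#' Simulate transcription-factor peak sets over synthetic loci
#'
#' Emulates pluripotency-factor binding concentrated in non-genic
#' satellite repeats: each satellite locus is bound with probability
#' `frac_satellite`, every other (non-background) locus with probability
#' `frac_other`; a bound locus receives a peak of `peak_width` bp placed
#' inside it. Defaults reflect the binding disparity the genome-wide
#' analysis is designed to detect (roughly a third of satellites versus a
#' fifth of other elements bound by at least one factor).
#'
#' @param annotation A [build_annotation()] result.
#' @param frac_satellite,frac_other Binding probabilities per locus.
#' @param peak_width Peak width in bp.
#' @param seed Integer seed.
#' @return Peak tibble (`chrom`, `start`, `end`, `name`).
#' @export
simulate_tf_peaks <- function(annotation, frac_satellite = 0.32,
                              frac_other = 0.19, peak_width = 100,
                              seed = 1) {
  loci <- as_tibble(annotation$truth)
  loci <- loci[loci$archetype != "background", ]
  withr::with_seed(sub_seed(seed, 7), {
    pr <- ifelse(loci$archetype == "satellite_repeat",
                 frac_satellite, frac_other)
    bound <- runif(nrow(loci)) < pr
    b <- loci[bound, ]
    w <- pmin(peak_width, b$end - b$start)
    off <- floor(runif(nrow(b), 0, b$end - b$start - w + 1))
    tibble(chrom = b$chrom, start = b$start + off, end = b$start + off + w,
           name = "tf_peak")
  })
}
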