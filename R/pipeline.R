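#' Default pipeline configuration
#'
#' @param seed Integer master seed for every stochastic stage.
#' @return Named list of pipeline settings: analysis parameters (window
#'   and resampling widths, read extension, rate interval `dt`,
#'   pseudocount `eps`, enrichment `alpha`/`min_fold`, proximity
#'   cutoffs), synthetic-genome settings, and simulation depth/replicate
#'   counts. Any element can be overridden via the `config` argument of
#'   [run_pipeline()].
#' @export
default_config <- function(seed = 1) {
  list(
    synthetic = TRUE,
    seed = seed,
    window = 250,
    resample = 10,
    extend = 150,
    dt = 6,
    eps = 0.5,
    alpha = 0.05,
    min_fold = 2,
    pseudocount = 0.5,
    proximal_cutoff = 5000,
    repeat_cutoff = 2000,
    profile_flank = 500,
    profile_bin = 50,
    profile_window = 50,
    region_flank = 1000,
    depth = 2,
    replicates = 2,
    input_reads_per_kb = 30,
    chroms = list(name = c("chrS1", "chrS2"), length = c(2e5, 15e4))
  )
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- default_config()
  cfg[names(config)] <- config
  cfg
}

validate_config <- function(cfg) {
  if (!isTRUE(cfg$dt > 0)) abort("config error: dt must be > 0")
  if (!isTRUE(cfg$eps > 0)) abort("config error: eps must be > 0")
  if (!isTRUE(cfg$window > 0)) abort("config error: window must be > 0")
  if (!isTRUE(cfg$depth > 0)) abort("config error: depth must be > 0")
  if (!isTRUE(cfg$synthetic)) {
    need <- c("reads_t0", "reads_t6", "input", "chrom_sizes", "transcripts")
    missing <- setdiff(need, names(cfg))
    missing <- c(missing, need[vapply(cfg[intersect(need, names(cfg))],
                                      function(p) !file.exists(p),
                                      logical(1))])
    if (length(missing)) {
      abort(paste("config error: missing input(s):",
                  paste(unique(missing), collapse = ", ")))
    }
  }
  invisible(cfg)
}

#' Run the full turnover analysis pipeline
#'
#' Executes simulate (synthetic mode) or load (file mode), then count,
#' low-pass filter, enrichment calling, per-window rate estimation,
#' feature classification, metaprofiles, region summaries and headline
#' statistics, writing every result table plus a JSON manifest to
#' `out_dir`. The run is deterministic for a fixed configuration and
#' seed.
#'
#' @param out_dir Output directory.
#' @param config Named list or YAML path; elements override
#'   [default_config()]. Set `synthetic: false` and supply `reads_t0`,
#'   `reads_t6`, `input`, `chrom_sizes`, `transcripts` paths to analyse
#'   real alignments.
#' @param quiet Suppress per-stage messages?
#' @return Invisibly, a list with the main in-memory results: `truth`
#'   (synthetic mode), `estimates`, `concordance`, `rate_vs_equilibrium`,
#'   `region_summary`, `tss_curves`, `repeat_binding`, `satellite_chisq`.
#' @export
run_pipeline <- function(out_dir, config = list(), quiet = FALSE) {
  cfg <- validate_config(read_config(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  t_start <- Sys.time()

  # ---- inputs -------------------------------------------------------
  if (isTRUE(cfg$synthetic)) {
    say("stage simulate: synthetic genome + TET-OFF libraries")
    chroms <- chrom_sizes(cfg$chroms$name, cfg$chroms$length)
    ann <- build_annotation(chroms, synth_params(), seed = cfg$seed)
    sim <- simulate_reads(ann$truth, timepoints = c(0, 6),
                          depth = cfg$depth,
                          n_replicates = max(2, cfg$replicates),
                          input_reads_per_kb = cfg$input_reads_per_kb,
                          seed = cfg$seed)
    reads0 <- get_library(sim, 0, 1); reads6 <- get_library(sim, 6, 1)
    input <- get_library(sim, NA, 1)
    transcripts <- ann$transcripts
    truth <- ann$truth
    repeats <- as_tibble(truth) |>
      filter(.data$archetype == "satellite_repeat") |>
      mutate(name = "satellite")
    peaks <- list(tf = simulate_tf_peaks(ann, seed = cfg$seed))
    readr::write_tsv(as_tibble(truth), file.path(out_dir, "truth.tsv"),
                     progress = FALSE)
  } else {
    say("stage load: reading alignment and annotation files")
    chroms <- read_chrom_sizes(cfg$chrom_sizes)
    reads0 <- read_reads_bed(cfg$reads_t0)
    reads6 <- read_reads_bed(cfg$reads_t6)
    input <- read_reads_bed(cfg$input)
    transcripts <- readr::read_tsv(cfg$transcripts, col_types = readr::cols(),
                                   progress = FALSE)
    truth <- NULL
    repeats <- if (!is.null(cfg$repeats)) read_features_bed(cfg$repeats)
    peaks <- if (!is.null(cfg$peaks)) {
      setNames(purrr::map(cfg$peaks, read_features_bed),
               names(cfg$peaks) %||% paste0("set", seq_along(cfg$peaks)))
    }
  }

  # ---- signal -------------------------------------------------------
  say("stage signal: dyad counting and low-pass filtering")
  grid <- window_grid(chroms, width = cfg$window)
  c0 <- lowpass_filter(count_dyads(reads0, grid, extend = cfg$extend))
  c6 <- lowpass_filter(count_dyads(reads6, grid, extend = cfg$extend))
  ci <- lowpass_filter(count_dyads(input, grid, extend = cfg$extend))
  calls <- call_enriched(c0, ci, alpha = cfg$alpha, min_fold = cfg$min_fold,
                         pseudocount = cfg$pseudocount)
  write_enriched_bed(calls, file.path(out_dir, "enriched.bed"))

  # ---- rates --------------------------------------------------------
  say("stage rates: per-window dissociation and equilibrium")
  est <- turnover_tracks(c0, c6, ci, calls, dt = cfg$dt, eps = cfg$eps)
  write_turnover_table(est, file.path(out_dir, "turnover.tsv"))
  for (w in c("lambda_out", "lambda_raw", "lambda_equ")) {
    write_bedgraph(turnover_track(est, w),
                   file.path(out_dir, paste0(w, ".bedGraph")))
    write_bedgraph(turnover_track(est, w, resample = cfg$resample),
                   file.path(out_dir, sprintf("%s_%dbp.bedGraph", w,
                                              cfg$resample)))
  }
  rate_tr <- turnover_track(est, "lambda_out")
  equ_tr <- turnover_track(est, "lambda_equ")

  # ---- classification ----------------------------------------------
  repeat_binding <- NULL; satellite_chisq <- NULL
  if (!is.null(repeats) && nrow(repeats) && !is.null(peaks)) {
    say("stage classify: repeats and TF binding")
    rep_cls <- classify_repeats(repeats, transcripts,
                                cutoff = cfg$repeat_cutoff)
    ov <- tf_binding_overlap(rep_cls, peaks, group_by = "class")
    repeat_binding <- ov$summary
    readr::write_tsv(repeat_binding,
                     file.path(out_dir, "repeat_binding.tsv"),
                     progress = FALSE)
    if (isTRUE(cfg$synthetic)) {
      # satellites vs all other non-background loci, bound vs unbound
      others <- as_tibble(truth) |>
        filter(!.data$archetype %in% c("satellite_repeat", "background"))
      ov_o <- tf_binding_overlap(others, peaks, group_by = character(0))
      sat <- ov$repeats
      tab <- matrix(c(sum(sat$bound_any), sum(!sat$bound_any),
                      sum(ov_o$repeats$bound_any),
                      sum(!ov_o$repeats$bound_any)),
                    nrow = 2,
                    dimnames = list(c("bound", "unbound"),
                                    c("satellite", "other")))
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        satellite_chisq <- chisq_2x2(tab)
      }
    }
  }

  # ---- profiles -----------------------------------------------------
  say("stage profiles: TSS metaprofile and region summary")
  tss <- transcript_anchors(transcripts, at = "tss")
  # promoter-scale rates: a 50-bp counting grid resolves the NDR, which
  # the genome-wide 250-bp grid cannot
  pgrid <- window_grid(chroms, width = cfg$profile_window)
  p0 <- lowpass_filter(count_dyads(reads0, pgrid, extend = cfg$extend))
  p6 <- lowpass_filter(count_dyads(reads6, pgrid, extend = cfg$extend))
  pi0 <- lowpass_filter(count_dyads(input, pgrid, extend = cfg$extend))
  pcalls <- call_enriched(p0, pi0, alpha = cfg$alpha,
                          min_fold = cfg$min_fold,
                          pseudocount = cfg$pseudocount)
  pest <- turnover_tracks(p0, p6, pi0, pcalls, dt = cfg$dt, eps = cfg$eps)
  rate_fine <- turnover_track(pest, "lambda_out", resample = cfg$resample)
  pm <- profile_matrix(rate_fine, tss, flank = cfg$profile_flank,
                       bin = cfg$profile_bin, oriented = TRUE)
  tss_curves <- mean_profile(pm)
  readr::write_tsv(as_tibble(tss_curves),
                   file.path(out_dir, "tss_profile.tsv"), progress = FALSE)
  expr <- if (isTRUE(cfg$synthetic)) ann$expression
          else if (!is.null(cfg$expression)) {
            readr::read_tsv(cfg$expression, col_types = "cd",
                            progress = FALSE)
          }
  expr_curves <- NULL
  if (!is.null(expr)) {
    groups <- tibble(anchor_id = expr$transcript_id,
                     group = as.character(bin_expression(expr$fpkm)))
    expr_curves <- suppressWarnings(mean_profile(pm, groups))
    readr::write_tsv(as_tibble(expr_curves),
                     file.path(out_dir, "tss_profile_by_expression.tsv"),
                     progress = FALSE)
  }
  region <- NULL
  if (!is.null(truth)) {
    sets <- split(as_tibble(truth), as_tibble(truth)$archetype)
    region <- region_summary(list(lambda_out = rate_tr,
                                  lambda_equ = equ_tr),
                             sets, flank = cfg$region_flank)
    readr::write_tsv(as_tibble(region),
                     file.path(out_dir, "region_summary.tsv"),
                     progress = FALSE)
  }

  # ---- statistics ---------------------------------------------------
  say("stage stats: concordance and correlations")
  concordance <- NULL
  if (isTRUE(cfg$synthetic)) {
    c0b <- lowpass_filter(count_dyads(get_library(sim, 0, 2), grid,
                                      extend = cfg$extend))
    c6b <- lowpass_filter(count_dyads(get_library(sim, 6, 2), grid,
                                      extend = cfg$extend))
    cib <- lowpass_filter(count_dyads(get_library(sim, NA, 2), grid,
                                      extend = cfg$extend))
    calls_b <- call_enriched(c0b, cib, alpha = cfg$alpha,
                             min_fold = cfg$min_fold,
                             pseudocount = cfg$pseudocount)
    est_b <- turnover_tracks(c0b, c6b, cib, calls_b, dt = cfg$dt,
                             eps = cfg$eps)
    concordance <- replicate_concordance(rate_tr,
                                         turnover_track(est_b, "lambda_out"),
                                         resolution = cfg$resample)
    readr::write_tsv(concordance$density,
                     file.path(out_dir, "concordance_density.tsv"),
                     progress = FALSE)
  }
  rate_vs_equ <- track_pearson(rate_tr, equ_tr)
  correlations <- bind_rows(
    mutate(tidy(rate_vs_equ), comparison = "lambda_out_vs_lambda_equ"),
    if (!is.null(concordance)) {
      mutate(tidy(concordance)[, c("estimate", "n", "df", "p.value",
                                   "method")],
             comparison = "replicate_concordance_10bp")
    })
  readr::write_tsv(correlations, file.path(out_dir, "correlations.tsv"),
                   progress = FALSE)

  # ---- manifest -----------------------------------------------------
  manifest <- list(
    package = "h3turnover",
    version = as.character(utils::packageVersion("h3turnover")),
    seed = cfg$seed,
    synthetic = isTRUE(cfg$synthetic),
    parameters = cfg[c("window", "resample", "extend", "dt", "eps",
                       "alpha", "min_fold", "pseudocount",
                       "proximal_cutoff", "repeat_cutoff", "depth")],
    elapsed_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("pipeline complete: %s", out_dir)
  invisible(list(truth = truth, estimates = est,
                 concordance = concordance,
                 rate_vs_equilibrium = rate_vs_equ,
                 region_summary = region, tss_curves = tss_curves,
                 expression_curves = expr_curves,
                 repeat_binding = repeat_binding,
                 satellite_chisq = satellite_chisq))
}
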