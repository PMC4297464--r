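#' Write a synthetic dataset to disk as plain-text fixtures
#'
#' Emits every simulated library as BED6 (one record per read: a 1-bp
#' interval anchored at the 5' position, strand in column 6), the locus
#' annotation as BED6 (archetype in the name column), the truth table,
#' transcript/exon/expression tables as tab-delimited text, the
#' chromosome table as chrom.sizes, and a YAML snapshot of the generator
#' settings. Everything round-trips through [read_fixture()].
#'
#' @param sim A [simulate_reads()] result.
#' @param annotation The matching [build_annotation()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, annotation, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) {
    abort(paste0("cannot write fixture directory: ", dir))
  }
  chroms <- annotation$chrom_sizes

  write_reads_bed <- function(reads, path) {
    lines <- sprintf("%s\t%d\t%d\tread\t0\t%s",
                     reads$chrom, as.integer(reads$five_prime),
                     as.integer(reads$five_prime) + 1L, reads$strand)
    readr::write_lines(lines, path)
  }
  reps <- sort(unique(sim$replicate))
  tps <- attr(sim, "timepoints", exact = TRUE)
  for (r in reps) {
    for (t in tps) {
      write_reads_bed(get_library(sim, t, r),
                      file.path(dir, sprintf("reads_t%g_rep%d.bed", t, r)))
    }
    write_reads_bed(get_library(sim, NA, r),
                    file.path(dir, sprintf("input_rep%d.bed", r)))
  }

  truth <- as_tibble(annotation$truth)
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%s\t0\t%s", truth$chrom, as.integer(truth$start),
            as.integer(truth$end), truth$archetype, truth$strand),
    file.path(dir, "loci.bed"))
  readr::write_tsv(truth[, c("chrom", "start", "end", "archetype",
                             "occupancy0", "true_lambda", "locus_id",
                             "strand")],
                   file.path(dir, "truth.tsv"), progress = FALSE)
  readr::write_tsv(annotation$transcripts, file.path(dir, "transcripts.tsv"),
                   progress = FALSE)
  readr::write_tsv(annotation$exons, file.path(dir, "exons.tsv"),
                   progress = FALSE)
  readr::write_tsv(annotation$expression, file.path(dir, "expression.tsv"),
                   progress = FALSE)
  readr::write_lines(sprintf("%s\t%d", chroms$name, as.integer(chroms$length)),
                     file.path(dir, "chrom.sizes"))
  cfg <- list(seed = annotation$seed,
              timepoints = as.numeric(tps),
              depth = attr(sim, "depth", exact = TRUE),
              replicates = length(reps),
              params = unclass(annotation$params))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a fixture directory back
#'
#' @param dir Directory written by [write_fixture()].
#' @return A list with `chrom_sizes`, `truth`, `transcripts`, `exons`,
#'   `expression`, `config`, and `reads` (named list of read tibbles,
#'   keyed as in the BED file names).
#' @export
read_fixture <- function(dir) {
  chroms <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           col_types = "cddcddcc", progress = FALSE)
  bed_files <- list.files(dir, pattern = "\\.bed$", full.names = TRUE)
  bed_files <- bed_files[basename(bed_files) != "loci.bed"]
  reads <- purrr::map(bed_files, read_reads_bed)
  names(reads) <- sub("\\.bed$", "", basename(bed_files))
  list(chrom_sizes = chroms,
       truth = truth_table(truth, chroms),
       transcripts = readr::read_tsv(file.path(dir, "transcripts.tsv"),
                                     col_types = "ccddc", progress = FALSE),
       exons = readr::read_tsv(file.path(dir, "exons.tsv"),
                               col_types = "ccii", progress = FALSE),
       expression = readr::read_tsv(file.path(dir, "expression.tsv"),
                                    col_types = "cd", progress = FALSE),
       config = yaml::read_yaml(file.path(dir, "config.yaml")),
       reads = reads)
}

#' Read a BED file of 5'-anchored reads
#'
#' @param path BED6 path (1-bp records anchored at the read 5' end).
#' @return Read tibble (`chrom`, `five_prime`, `strand`).
#' @export
read_reads_bed <- function(path) {
  x <- readr::read_tsv(path,
                       col_names = c("chrom", "start", "end", "name",
                                     "score", "strand"),
                       col_types = "ciicic", progress = FALSE)
  tibble(chrom = x$chrom, five_prime = x$start, strand = x$strand)
}

#' Read a BED file of features
#'
#' @param path BED path (>= 3 columns; name/score/strand optional).
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`
#'   and `strand`.
#' @export
read_features_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                       progress = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  if (ncol(x) >= 6) names(x)[6] <- "strand"
  as_tibble(x[, intersect(c("chrom", "start", "end", "name", "strand"),
                          names(x))])
}
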