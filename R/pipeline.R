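#' Build a pipeline configuration
#'
#' Collects every tunable of the simulate-link-count-quantify-analyze
#' workflow in one validated list. All stochastic stages draw from the
#' single `seed`, so a config run twice produces byte-identical outputs.
#'
#' @param output_dir Directory for all stage outputs.
#' @param seed Integer RNG seed (mandatory: every stage downstream of the
#'   simulator is stochastic).
#' @param n_inserts Number of codon-pair inserts to use (default all 4096;
#'   smaller values take the first rows of the library for demo runs).
#' @param barcodes_per_insert,bottleneck Clone structure passed to
#'   [simulate_truth()].
#' @param effects An [effect_config()] (or list of its arguments).
#' @param depth_linkage,depth_gdna,depth_mrna Total read depths.
#' @param dispersion,error_rate,noise_free Read-simulation noise controls.
#' @param max_dist Collision filter edit-distance threshold.
#' @param min_reads,min_reads_mrna,min_barcodes,cv_max Count filters.
#' @param bootstrap Bootstrap resamples per insert.
#' @param pseudocount Optional pseudocount for zero-mRNA resamples.
#' @param normalization Level normalization mode.
#' @param gzip Write gzip-compressed FASTQ files.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, seed,
                            n_inserts = 4096L,
                            barcodes_per_insert = 100L,
                            bottleneck = 0.2,
                            effects = effect_config(),
                            depth_linkage = 1e6,
                            depth_gdna = 4e6,
                            depth_mrna = 4e6,
                            dispersion = 0.3,
                            error_rate = 1e-3,
                            noise_free = FALSE,
                            max_dist = 2L,
                            min_reads = 10L,
                            min_reads_mrna = 0L,
                            min_barcodes = 2L,
                            cv_max = Inf,
                            bootstrap = 100L,
                            pseudocount = NULL,
                            normalization = "median",
                            gzip = FALSE) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  required <- c("output_dir", "seed")
  for (f in required) {
    if (is.null(cfg[[f]]) || length(cfg[[f]]) != 1L || is.na(cfg[[f]])) {
      stop("config field '", f, "' is missing or invalid")
    }
  }
  if (!is.numeric(cfg$seed)) stop("config field 'seed' must be an integer")
  for (f in c("depth_linkage", "depth_gdna", "depth_mrna")) {
    if (cfg[[f]] <= 0) stop("config field '", f, "' must be positive")
  }
  if (cfg$min_barcodes < 1) stop("config field 'min_barcodes' must be >= 1")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1) {
    stop("config field 'error_rate' must be in [0, 1)")
  }
  if (!cfg$normalization %in% c("median", "spikein", "rpm", "none")) {
    stop("config field 'normalization' must be one of median/spikein/rpm/none")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$effects)) raw$effects <- do.call(effect_config, raw$effects)
  do.call(pipeline_config, raw)
}

stage_msg <- function(stage, t0, ...) {
  message(sprintf("[%s] %5.1fs %s", stage,
                  as.numeric(Sys.time()) - t0, paste0(...)))
}

#' Run the full reporter-assay workflow on simulated data
#'
#' Executes design -> simulate -> link -> count -> quantify -> analyze,
#' writing every stage's table under `config$output_dir` together with a
#' JSON run manifest (seed, package version, per-stage provenance counters,
#' file checksums). Deterministic: the same config yields byte-identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the key tables (`truth`, `linkage`,
#'   `levels`, `positional`, `dipeptides`, `csc`) and the manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  validate_config(config)
  t0 <- as.numeric(Sys.time())
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  ext <- if (config$gzip) ".fastq.gz" else ".fastq"
  prov <- list()

  # design
  library <- utils::head(codon_pair_library(), config$n_inserts)
  write_library(library, file.path(out, "design.csv"))
  stage_msg("design", t0, nrow(library), " inserts")

  # simulate
  truth <- simulate_truth(
    library,
    barcodes_per_insert = config$barcodes_per_insert,
    bottleneck = config$bottleneck,
    effects = config$effects
  )
  write_truth(truth, file.path(out, "truth"))
  fq <- file.path(out, paste0(c("linkage", "gdna", "mrna"), ext))
  names(fq) <- c("linkage", "gdna", "mrna")
  depths <- c(linkage = config$depth_linkage, gdna = config$depth_gdna,
              mrna = config$depth_mrna)
  for (s in names(fq)) {
    simulate_reads(truth, fq[[s]], type = s, depth = depths[[s]],
                   dispersion = config$dispersion,
                   error_rate = config$error_rate,
                   noise_free = config$noise_free)
  }
  stage_msg("simulate", t0, nrow(truth$clones), " clones")

  # link
  reference <- dplyr::bind_rows(
    library[, c("insert_id", "insert_seq")],
    truth$inserts[truth$inserts$class == "spikein",
                  c("insert_id", "insert_seq")]
  )
  raw_pairs <- extract_linkage_pairs(fq[["linkage"]], reference)
  linkage <- filter_barcode_collisions(raw_pairs, max_dist = config$max_dist)
  write_linkage(linkage, file.path(out, "linkage.csv"))
  prov$linkage <- attr(linkage, "provenance")
  stage_msg("link", t0, nrow(linkage), " barcodes retained")

  # count
  gdna <- count_barcodes(fq[["gdna"]], linkage)
  mrna <- count_barcodes(fq[["mrna"]], linkage)
  readr::write_csv(gdna, file.path(out, "counts_gdna.csv"))
  readr::write_csv(mrna, file.path(out, "counts_mrna.csv"))
  prov$count_gdna <- attr(gdna, "provenance")
  prov$count_mrna <- attr(mrna, "provenance")
  stage_msg("count", t0, nrow(gdna), " gDNA / ", nrow(mrna),
            " mRNA barcodes")

  # quantify
  paired <- filter_counts(
    mrna, gdna,
    min_reads = config$min_reads, min_reads_mrna = config$min_reads_mrna,
    min_barcodes = config$min_barcodes, cv_max = config$cv_max
  )
  levels <- quantify_inserts(paired, B = config$bootstrap,
                             pseudocount = config$pseudocount)
  spike_ids <- truth$inserts$insert_id[truth$inserts$class == "spikein"]
  levels <- normalize_levels(levels, mode = config$normalization,
                             spikeins = spike_ids)
  readr::write_csv(levels, file.path(out, "levels.csv"))
  stage_msg("quantify", t0, nrow(levels), " inserts quantified")

  # analyze
  lvl_lib <- levels[levels$insert_id %in% library$insert_id, ]
  positional <- positional_means(lvl_lib, library, unit = "codon")
  dipeptides <- dipeptide_levels(lvl_lib, library)
  csc <- compute_csc(lvl_lib, library)
  readr::write_csv(positional, file.path(out, "positional_means.csv"))
  readr::write_csv(dipeptides, file.path(out, "dipeptide_levels.csv"))
  readr::write_csv(csc, file.path(out, "csc.csv"))
  stage_msg("analyze", t0, "tables written")

  tables <- list.files(out, pattern = "\\.csv$", recursive = TRUE,
                       full.names = TRUE)
  manifest <- list(
    package = "dicodon",
    version = as.character(utils::packageVersion("dicodon")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    n_inserts = config$n_inserts,
    provenance = prov,
    md5 = as.list(tools::md5sum(tables))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(truth = truth, linkage = linkage, levels = levels,
                 positional = positional, dipeptides = dipeptides,
                 csc = csc, manifest = manifest))
}
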