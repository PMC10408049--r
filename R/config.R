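#' Read a declarative run configuration
#'
#' Parses a YAML run file describing a full pipeline run: exposure and
#' outcome summary-statistics paths with optional column maps, the LD
#' matrix path, gene regions, selection thresholds, the palindromic
#' band, lead variants and a seed. See
#' `system.file("extdata", "full_run_config.yaml", package = "cismr")`
#' for a commented template matching the caffeine analysis.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: cannot read ", path)
  cfg <- yaml::read_yaml(path)
  for (field in c("exposure", "outcomes", "ld")) {
    if (is.null(cfg[[field]])) {
      stop("read_run_config: missing required field '", field, "'")
    }
  }
  structure(cfg, class = "run_config")
}

resolve_column_map <- function(x) {
  if (is.null(x)) character() else unlist(x)
}

#' Run the pipeline from a configuration file
#'
#' Loads every input named in a run configuration (see
#' [read_run_config()]) and hands them to [run_pipeline()]; optionally
#' serializes the result bundle with [write_results()].
#'
#' @param config a `run_config` or path to one.
#' @param out_dir optional output directory for [write_results()].
#' @param base_dir directory against which relative paths in the config
#'   are resolved; defaults to the config file's directory when `config`
#'   is a path, else the working directory.
#' @return The `result_bundle`.
#' @export
run_pipeline_file <- function(config, out_dir = NULL, base_dir = NULL) {
  if (is.character(config)) {
    if (is.null(base_dir)) base_dir <- dirname(config)
    config <- read_run_config(config)
  }
  if (is.null(base_dir)) base_dir <- "."
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }

  exposure <- read_summary_stats(
    resolve(config$exposure$path),
    column_map = resolve_column_map(config$exposure$column_map),
    trait = config$exposure$trait %||% "exposure",
    trait_type = "continuous",
    units = config$exposure$units %||% "SD")
  outcomes <- lapply(config$outcomes, function(oc) {
    lapply(oc$sources, function(src) {
      read_summary_stats(resolve(src$path),
                         column_map = resolve_column_map(src$column_map),
                         trait = oc$trait %||% "outcome",
                         trait_type = "binary",
                         units = "log-odds",
                         source = src$name %||% basename(src$path))
    })
  })
  ld <- read_ld_matrix(resolve(config$ld))
  regions <- if (is.null(config$regions)) {
    caffeine_regions()
  } else {
    lapply(config$regions, function(r) {
      gene_region(r$name, r$chrom, r$start, r$end, r$flank %||% 1e5)
    })
  }
  sel <- selection_config(
    p_threshold = config$selection$p_threshold %||% 5e-5,
    clump_r2 = config$selection$clump_r2 %||% 0.3,
    clump_window_kb = config$selection$clump_window_kb %||% 10000,
    m_total = config$selection$m_total %||% NA)

  bundle <- run_pipeline(exposure, outcomes, ld,
                         regions = regions, config = sel,
                         eaf_band = config$eaf_band %||% 0.08,
                         leads = unlist(config$leads),
                         fiqt = config$fiqt %||% TRUE,
                         seed = config$seed %||% NA)
  if (!is.null(out_dir)) write_results(bundle, out_dir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a
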