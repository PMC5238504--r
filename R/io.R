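#' Read a binding data CSV with schema validation
#'
#' Recognises the two tabular schemas used throughout the package:
#' dissociation time courses (columns `experiment_id`, `time_min`,
#' `conc_tracer_M`, `conc_competitor_M` and `bound_pct` or `bound`) and
#' saturation curves (columns `experiment_id`, `conc_tracer_M`, `total`,
#' `nonspecific`).  Cells are type-checked; malformed rows are reported
#' with their line numbers.
#'
#' @param path CSV file path.
#' @return a `dissociation_series` or `saturation_curve` data frame, with
#'   attribute `schema` set accordingly.
#' @export
read_binding_csv <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_validation("cannot parse ", path,
                                                     ": ", conditionMessage(e)))
  if (!nrow(df)) stop_validation("empty input file: ", path)
  time_cols <- c("experiment_id", "time_min", "conc_tracer_M",
                 "conc_competitor_M")
  sat_cols <- c("experiment_id", "conc_tracer_M", "total", "nonspecific")
  is_tc <- all(time_cols %in% names(df)) &&
    any(c("bound_pct", "bound") %in% names(df))
  is_sat <- !is_tc && all(sat_cols %in% names(df))
  if (!is_tc && !is_sat)
    stop_validation("unrecognised schema in ", path,
                    ": need dissociation columns (",
                    paste(time_cols, collapse = ", "), ", bound_pct) or ",
                    "saturation columns (", paste(sat_cols, collapse = ", "),
                    ")")
  numeric_cols <- setdiff(names(df), c("condition", "model"))
  for (cn in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad))
      stop_validation("non-numeric value in column ", cn, " at data row ",
                      bad[1], " of ", path)
    df[[cn]] <- v
  }
  conc_cols <- grep("^conc_", names(df), value = TRUE)
  for (cn in conc_cols) {
    bad <- which(df[[cn]] < 0)
    if (length(bad))
      stop_validation("negative concentration in column ", cn,
                      " at data row ", bad[1], " of ", path)
  }
  class(df) <- c(if (is_tc) "dissociation_series" else "saturation_curve",
                 class(df))
  attr(df, "schema") <- if (is_tc) "dissociation" else "saturation"
  df
}

#' Write a binding data frame to CSV
#' @param x data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_binding_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a structured run configuration
#'
#' Configurations are YAML files.  A `seed` field is required so that
#' every randomized run is reproducible from (config, seed).
#'
#' @param path YAML file path.
#' @return named list with at least a `seed` element.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_validation("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_validation("config must be a YAML mapping")
  if (is.null(cfg$seed)) stop_validation("config must contain a seed")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# stable hash of an arbitrary config (md5 of its canonical YAML rendering)
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

#' Report pipeline results to CSV or JSON
#'
#' Emits the group summary in the layout of the binding-parameter tables
#' (condition, n, mean +/- SEM of pK_D, k_off, pK_A, significance flags
#' from the Dunnett comparisons) together with the run seed and a hash of
#' the configuration, so that every artifact records its provenance.
#' The JSON and CSV renderings contain the same numbers.
#'
#' @param results a `group_summary` from [run_pipeline()].
#' @param path output file path (extension is added if absent).
#' @param format `"csv"` or `"json"`.
#' @param seed seed used for the run (recorded in the output).
#' @param config optional configuration list (hashed into the output).
#' @return invisibly, the written file path.
#' @export
report_results <- function(results, path, format = c("csv", "json"),
                           seed = NA_integer_, config = NULL) {
  format <- match.arg(format)
  if (!inherits(results, "group_summary"))
    stop_validation("results must be a group_summary")
  tab <- results$summary
  for (p in names(results$comparisons)) {
    cmp <- results$comparisons[[p]]
    col <- paste0(p, "_significant")
    tab[[col]] <- NA
    for (i in seq_len(nrow(cmp))) {
      hit <- tab$condition == cmp$condition[i]
      tab[[col]][hit] <- cmp$significant[i]
    }
    tab[[col]][tab$condition == results$reference] <- FALSE
  }
  meta <- list(seed = seed,
               config_hash = if (is.null(config)) NA_character_
                             else config_hash(config),
               reference = results$reference)
  if (format == "csv") {
    if (!grepl("\\.csv$", path)) path <- paste0(path, ".csv")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# seed: %s", meta$seed), con)
    writeLines(sprintf("# config_hash: %s", meta$config_hash), con)
    writeLines(sprintf("# reference: %s", meta$reference), con)
    utils::write.csv(tab, con, row.names = FALSE)
  } else {
    if (!grepl("\\.json$", path)) path <- paste0(path, ".json")
    jsonlite::write_json(list(meta = meta, summary = tab,
                              comparisons = results$comparisons),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
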