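#' Read and write trace tables
#'
#' Traces are exchanged as long-format CSV with columns `cell_id`,
#' `time` (min), `channel` (`ctd`, `ser5ph`, `mrna`), `intensity`, and
#' optionally `x_nm`, `y_nm`.
#'
#' @param path CSV file path.
#' @return `read_traces()` returns a tibble; `write_traces()` returns
#'   `path` invisibly.
#' @export
read_traces <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("cell_id", "time", "channel", "intensity")
  if (!all(need %in% names(tr)))
    stop("trace CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tr
}

#' @rdname read_traces
#' @param traces Trace tibble.
#' @export
write_traces <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}

#' Read a model configuration file
#'
#' YAML or JSON with keys `variant`, `omega`, `k_off`, `beta`, `k_ab`,
#' `k_esc`, `k_c` and optionally `extras` (a map of variant rates). Missing
#' rates take the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [build_model()] specification.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  variant <- cfg$variant %||% "base"
  extras <- cfg$extras %||% list()
  rate_names <- c("omega", "k_off", "beta", "k_ab", "k_esc", "k_c")
  args <- cfg[intersect(rate_names, names(cfg))]
  params <- do.call(rate_params, c(args, extras))
  build_model(variant, params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a correlation set
#'
#' Writes the curves plus metadata (cell count, sampling interval,
#' shot-noise table) to JSON; `read_correlations()` restores the object.
#'
#' @param corr_set A [correlate_traces()] result.
#' @param path JSON file path.
#' @export
write_correlations <- function(corr_set, path) {
  obj <- list(n_cells = attr(corr_set, "n_cells"),
              dt = attr(corr_set, "dt"),
              shot_noise = attr(corr_set, "shot_noise"),
              curves = as.data.frame(corr_set))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_correlations
#' @export
read_correlations <- function(path) {
  obj <- jsonlite::fromJSON(path)
  out <- as_tibble(obj$curves)
  structure(out, class = c("correlation_set", class(out)),
            n_cells = obj$n_cells, dt = obj$dt,
            shot_noise = as_tibble(obj$shot_noise))
}
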