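#' Construct a validated rate grid
#'
#' The central data container: replicated initial reaction rates indexed by
#' substrate concentration `substrate_uM` (µM), inhibitor concentration
#' `inhibitor_uM` (µM) and `replicate`. A valid grid has strictly positive
#' substrate levels, non-negative inhibitor levels, and at least one
#' zero-inhibitor row (the uninhibited reference needed for the
#' Michaelis-Menten stage). Measured rates may be slightly negative only
#' when the grid is flagged as noisy; model-predicted rates are always
#' non-negative.
#'
#' @param data data frame with columns `substrate_uM`, `inhibitor_uM`,
#'   `rate`, and optionally `replicate` (defaults to 1).
#' @param metadata named list of grid-level metadata, e.g.
#'   `enzyme_nominal_uM`, `substrate_name`, `inhibitor_name`.
#' @param noisy logical; `TRUE` marks the rates as noisy measurements,
#'   permitting small negative values.
#' @return A data frame of class `"rate_grid"` with attributes `metadata`
#'   and `noisy`. Row order is preserved.
#' @export
rate_grid <- function(data, metadata = list(), noisy = FALSE) {
  df <- as.data.frame(data)
  if (nrow(df) == 0L) stop("rate table is empty")
  required <- c("substrate_uM", "inhibitor_uM", "rate")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(sQuote(missing), collapse = ", "))
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  bad <- which(!is.finite(df$substrate_uM) | df$substrate_uM <= 0)
  if (length(bad)) {
    stop("invalid substrate_uM (must be > 0) in row(s) ",
         paste(bad, collapse = ", "))
  }
  bad <- which(!is.finite(df$inhibitor_uM) | df$inhibitor_uM < 0)
  if (length(bad)) {
    stop("invalid inhibitor_uM (must be >= 0) in row(s) ",
         paste(bad, collapse = ", "))
  }
  if (!any(df$inhibitor_uM == 0)) {
    stop("grid must contain at least one zero-inhibitor row")
  }
  if (any(!is.finite(df$rate))) stop("non-finite rate values")
  if (any(df$rate < 0) && !noisy) {
    warning("negative rates present in a grid not flagged as noisy")
  }
  structure(df, metadata = metadata, noisy = isTRUE(noisy),
            class = c("rate_grid", "data.frame"))
}

#' Read a long-format rate table from CSV
#'
#' Expects a UTF-8 CSV with "." decimal separator and one row per measured
#' rate. Header names are configurable through `col_names` so tables from
#' other pipelines can be ingested without editing the file. Units are
#' assumed µM for concentrations and nmol/min for rates.
#'
#' @param path path to the CSV file.
#' @param col_names named character vector mapping the canonical names
#'   (`substrate`, `inhibitor`, `replicate`, `rate`) to the file's headers.
#' @param noisy logical, passed to [rate_grid()].
#' @param metadata optional metadata list attached to the grid.
#' @return A [rate_grid].
#' @export
read_rate_table <- function(path,
                            col_names = c(substrate = "substrate_uM",
                                          inhibitor = "inhibitor_uM",
                                          replicate = "replicate",
                                          rate = "rate"),
                            noisy = FALSE, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("rate table is empty: ", path)
  defaults <- c(substrate = "substrate_uM", inhibitor = "inhibitor_uM",
                replicate = "replicate", rate = "rate")
  defaults[names(col_names)] <- col_names
  col_names <- defaults
  for (key in c("substrate", "inhibitor", "rate")) {
    if (!col_names[[key]] %in% names(raw)) {
      stop("schema error: missing column ", sQuote(col_names[[key]]),
           " in ", path)
    }
  }
  df <- data.frame(
    substrate_uM = as.numeric(raw[[col_names[["substrate"]]]]),
    inhibitor_uM = as.numeric(raw[[col_names[["inhibitor"]]]]),
    rate = as.numeric(raw[[col_names[["rate"]]]])
  )
  df$replicate <- if (col_names[["replicate"]] %in% names(raw)) {
    raw[[col_names[["replicate"]]]]
  } else 1L
  rate_grid(df, metadata = metadata, noisy = noisy)
}

#' Write a rate grid to CSV
#'
#' Inverse of [read_rate_table()]; writing then re-reading is the identity
#' on the table values (metadata is not serialized).
#'
#' @param grid a [rate_grid].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(grid, path) {
  df <- as.data.frame(grid)[, c("substrate_uM", "inhibitor_uM",
                                "replicate", "rate")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the analysis report
#'
#' Serializes a three-mode comparison, the Michaelis-Menten stage, and an
#' optional per-substrate IC50 table to a machine-readable JSON report plus
#' flat CSV companions (`<stem>_modes.csv`, and `<stem>_ic50.csv` when an
#' IC50 table is given). Numbers are written at full precision so AIC
#' values survive a round trip bit-exactly.
#'
#' @param comparison a [compare_inhibition_modes()] result.
#' @param path output path for the JSON report.
#' @param mm optional `mm_fit` object from the uninhibited stage.
#' @param ic50 optional data frame with per-substrate IC50 values.
#' @param config optional configuration echo (named list).
#' @param seed optional seed recorded for provenance.
#' @return `path`, invisibly.
#' @export
write_report <- function(comparison, path, mm = NULL, ic50 = NULL,
                         config = NULL, seed = NULL) {
  if (!inherits(comparison, "tb_comparison") ||
      length(comparison$fits) == 0L) {
    stop("'comparison' must be a non-empty inhibition-mode comparison")
  }
  modes <- lapply(comparison$fits, function(f) {
    if (is.null(f)) return(list(converged = FALSE))
    list(
      params = f$params[!vapply(f$params, is.null, logical(1))],
      se = as.list(f$se),
      fixed = f$fixed,
      rss = f$rss, n = f$n, k = f$k, aic = f$aic,
      converged = f$converged
    )
  })
  report <- list(
    package = list(name = "tightbind",
                   version = as.character(utils::packageVersion("tightbind"))),
    seed = seed,
    config = config,
    mm = if (!is.null(mm)) list(Km = mm$Km, Vmax = mm$Vmax,
                                se_Km = mm$se_Km, se_Vmax = mm$se_Vmax,
                                rss = mm$rss, n = mm$n_points),
    modes = modes,
    best_mode = comparison$best_mode,
    delta_aic = as.list(comparison$table$delta_aic |>
                          stats::setNames(comparison$table$mode)),
    ic50 = ic50
  )
  ok <- tryCatch({
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null")
    TRUE
  }, error = function(e) stop("cannot write report to ", path, ": ",
                              conditionMessage(e)))
  stem <- sub("\\.json$", "", path)
  utils::write.csv(comparison$table, paste0(stem, "_modes.csv"),
                   row.names = FALSE)
  if (!is.null(ic50)) {
    utils::write.csv(ic50, paste0(stem, "_ic50.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON analysis report
#'
#' @param path path written by [write_report()].
#' @return The parsed report as a nested list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
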