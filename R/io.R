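# Localization-table and trace I/O (TSV/CSV via data.table) and JSON
# configuration files.

.LOC_MANDATORY <- c("id", "x_nm", "y_nm", "sigma_nm", "L", "n_c", "t_s")

#' Read a localization table
#'
#' TSV/CSV with a header; the mandatory columns are
#' `id, x_nm, y_nm, sigma_nm, L, n_c, t_s`. Unknown columns (e.g.
#' ground-truth positions) are preserved.
#'
#' @param path File path.
#' @return data.frame of localizations.
#' @export
read_locs <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  missing <- setdiff(.LOC_MANDATORY, names(df))
  if (length(missing) > 0)
    stop(sprintf("read_locs: missing mandatory column(s): %s",
                 paste(missing, collapse = ", ")))
  df
}

#' Write a localization table
#'
#' @param locs data.frame with at least the mandatory columns (see
#'   [read_locs()]).
#' @param path Output path; the extension selects the separator
#'   (`.csv` = comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_locs <- function(locs, path) {
  missing <- setdiff(.LOC_MANDATORY, names(locs))
  if (length(missing) > 0)
    stop(sprintf("write_locs: missing mandatory column(s): %s",
                 paste(missing, collapse = ", ")))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fwrite(locs, path, sep = sep)
  invisible(path)
}

#' Write traces as a long-format TSV
#'
#' One row per detected photon with the trace id, timing, circle
#' center, ramp state, background flag and ground truth.
#'
#' @param traces List of `minsted_trace` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  tabs <- lapply(seq_along(traces), function(k) {
    tr <- traces[[k]]
    d <- tr$data
    data.frame(trace_id = k, i = d$i, t_ms = d$t_ms, x_nm = d$x_nm,
               y_nm = d$y_nm, E_nJ = d$E_nJ, R_nm = d$R_nm,
               fwhm_nm = d$fwhm_nm, is_bg = d$is_bg,
               truth_x_nm = tr$truth[1], truth_y_nm = tr$truth[2])
  })
  data.table::fwrite(data.table::rbindlist(tabs), path, sep = "\t")
  invisible(path)
}

#' Read traces written by [write_traces()]
#'
#' Rebuilds `minsted_trace` objects (with `n_c` taken from the
#' supplied configuration).
#'
#' @param path File path.
#' @param n_c Ramp completion index of the recording configuration.
#' @return List of `minsted_trace` objects.
#' @export
read_traces <- function(path, n_c = 80) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("trace_id", "i", "t_ms", "x_nm", "y_nm", "E_nJ", "R_nm",
            "fwhm_nm", "is_bg")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop(sprintf("read_traces: missing column(s): %s",
                 paste(missing, collapse = ", ")))
  lapply(split(df, df$trace_id), function(d) {
    truth <- if (all(c("truth_x_nm", "truth_y_nm") %in% names(d))) {
      c(d$truth_x_nm[1], d$truth_y_nm[1])
    } else c(NA_real_, NA_real_)
    structure(
      list(data = d[order(d$i),
                    c("i", "t_ms", "x_nm", "y_nm", "E_nJ", "R_nm",
                      "fwhm_nm", "is_bg")],
           n_c = n_c, L = nrow(d), initiated = TRUE,
           converged_ramp = nrow(d) >= n_c, truth = truth,
           termination = "imported"),
      class = "minsted_trace")
  })
}

#' Read a JSON configuration file
#'
#' A single JSON object with optional sections `optics`, `localizer`,
#' `precision`, `sample` and `render`, whose entries are passed to the
#' respective constructors; missing sections fall back to defaults.
#'
#' @param path JSON file path.
#' @return List with elements `optics`, `localizer`, `precision`,
#'   `kinetics`, `render`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(fun, section) {
    args <- raw[[section]]
    if (is.null(args)) fun() else do.call(fun, as.list(args))
  }
  list(optics = build(optics_model, "optics"),
       localizer = build(localizer_config, "localizer"),
       precision = build(precision_config, "precision"),
       kinetics = build(kinetics_model, "sample"),
       render = build(render_config, "render"))
}
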