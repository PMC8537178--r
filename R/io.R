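## Plain-text interchange: two-column spectrum files with '#' metadata
## header lines, JSON fit reports with a reproducibility block.

#' Read a two-column spectrum file
#'
#' Accepts comma-, tab- or whitespace-separated numeric columns
#' (frequency, value).  Leading `#` comment lines of the form
#' `# key: value` are parsed as metadata (`unit`, `temperature`,
#' `system`, `technique`, `seed`).  Descending frequencies are sorted
#' with a warning.
#'
#' @param path file path.
#' @param unit frequency unit, overriding any header value (default
#'   `"GHz"` when neither is given).
#' @return a [spectrum()].
#' @export
read_spectrum <- function(path, unit = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  parse_row <- function(i) {
    parts <- strsplit(trimws(body[i]), "[,\t ]+")[[1]]
    v <- suppressWarnings(as.numeric(parts[1:2]))
    if (length(parts) < 2 || any(is.na(v)))
      stop(sprintf("non-numeric data at line %d of %s",
                   which(lines == body[i])[1], path), call. = FALSE)
    v
  }
  mat <- t(vapply(seq_along(body), parse_row, numeric(2)))
  fr <- mat[, 1]; val <- mat[, 2]
  if (is.unsorted(fr, strictly = TRUE)) {
    if (is.unsorted(rev(fr), strictly = TRUE))
      stop("frequencies are neither increasing nor decreasing", call. = FALSE)
    warning("descending frequency axis; sorting", call. = FALSE)
    o <- order(fr); fr <- fr[o]; val <- val[o]
  }
  unit <- unit %||% meta$unit %||% "GHz"
  spectrum(fr, val, unit = unit,
           temperature = as.numeric(meta$temperature %||% NA),
           system = meta$system %||% NA_character_,
           technique = meta$technique %||% NA_character_,
           meta = list(seed = as.numeric(meta$seed %||% NA)))
}

#' Write a spectrum to a two-column text file
#'
#' @param s a [spectrum()].
#' @param path output file.
#' @param digits significant digits.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, digits = 15) {
  stopifnot(inherits(s, "spectrum"))
  hdr <- c(sprintf("# unit: %s", s$unit))
  for (k in c("temperature", "system", "technique", "seed")) {
    v <- s$meta[[k]]
    if (!is.null(v) && !is.na(v)) hdr <- c(hdr, sprintf("# %s: %s", k, v))
  }
  rows <- sprintf("%.*g\t%.*g", digits, s$frequency, digits, s$value)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

## stable content hash of an R object via canonical JSON + md5
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Write a fit or summary report to disk
#'
#' Emits a JSON report with parameters, uncertainties and derived
#' quantities, per-component curves as CSV (for fits), and a
#' reproducibility block (seed when known, configuration hash, package
#' version).
#'
#' @param x an `"edls_fit"`, `"hydration_summary"` or `"scir"` object.
#' @param dir output directory (created if needed).
#' @param name base file name (default from the object).
#' @param seed seed to record.
#' @return named list of files written, invisibly.
#' @export
write_report <- function(x, dir, name = NULL, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  repro <- function(cfg) list(
    seed = seed %||% NA,
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("hydrospec")))
  if (inherits(x, "edls_fit")) {
    name <- name %||% paste0("fit_", x$stage)
    rep <- list(stage = x$stage, parameters = as.list(x$par),
                se = as.list(x$se), fixed = as.list(x$fixed %||% list()),
                deviance = x$deviance, niter = x$niter,
                reproducibility = repro(list(par = x$par, fixed = x$fixed,
                                             stage = x$stage)))
    files$json <- file.path(dir, paste0(name, ".json"))
    jsonlite::write_json(rep, files$json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    ev <- evaluate_model(x$model, x$nu_THz, unit = "THz")
    curves <- data.frame(frequency_THz = x$nu_THz, observed = x$obs,
                         total = ev$value, attr(ev, "partials"),
                         check.names = FALSE)
    files$curves <- file.path(dir, paste0(name, "_curves.csv"))
    utils::write.csv(curves, files$curves, row.names = FALSE)
  } else if (inherits(x, "hydration_summary")) {
    name <- name %||% "hydration"
    rep <- list(r = x$r, N_ultraslow_mean = x$N_mean, N_ultraslow_sd = x$N_sd,
                trend = x$trend, Ea = x$Ea,
                reproducibility = repro(x$table))
    files$json <- file.path(dir, paste0(name, ".json"))
    jsonlite::write_json(rep, files$json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files$table <- file.path(dir, paste0(name, "_table.csv"))
    utils::write.csv(x$table, files$table, row.names = FALSE)
  } else if (inherits(x, "scir")) {
    name <- name %||% "scir"
    rep <- list(factor = x$factor, tolerance = x$tolerance, area = x$area,
                negativity = x$negativity,
                band_metrics = x$band_metrics,
                reproducibility = repro(list(factor = x$factor,
                                             tolerance = x$tolerance)))
    files$json <- file.path(dir, paste0(name, ".json"))
    jsonlite::write_json(rep, files$json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files$spectrum <- file.path(dir, paste0(name, "_spectrum.csv"))
    utils::write.csv(data.frame(wavenumber = x$sc_spectrum$frequency,
                                value = x$sc_spectrum$value),
                     files$spectrum, row.names = FALSE)
  } else stop("unsupported report object", call. = FALSE)
  invisible(files)
}
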