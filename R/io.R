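#' Read a kinetic trace from CSV
#'
#' Expects header columns `time_s` and `signal` (optionally `sigma`).
#' Columns named `time_ms` or `concentration_uM` in sidecar metadata are
#' converted to seconds/molar on load, keeping units explicit. Times must
#' be strictly increasing; violations are reported with the offending file
#' line (header = line 1). When a sidecar JSON manifest `<path minus
#' .csv>.json` exists, its scalar fields are attached as attributes.
#'
#' @param path CSV file path.
#' @return data frame with columns `time_s`, `signal` (and `sigma` when
#'   present), plus any sidecar metadata as attributes.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path))
    stop_teckin("teckin_missing_file", paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("time_ms" %in% names(df) && !"time_s" %in% names(df)) {
    df$time_s <- df$time_ms / 1000
    df$time_ms <- NULL
  }
  missing <- setdiff(c("time_s", "signal"), names(df))
  if (length(missing))
    stop_teckin("teckin_missing_column",
                paste0(path, ": missing column(s): ",
                       paste(missing, collapse = ", ")))
  for (col in intersect(c("time_s", "signal", "sigma"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop_teckin("teckin_nonnumeric_cell",
                  paste0(path, ": non-numeric value in column '", col,
                         "' at line ", bad[1] + 1))
    df[[col]] <- v
  }
  d <- diff(df$time_s)
  if (any(d == 0)) {
    i <- which(d == 0)[1]
    stop_teckin("teckin_duplicate_time",
                paste0(path, ": duplicate time at line ", i + 2))
  }
  if (any(d < 0)) {
    i <- which(d < 0)[1]
    stop_teckin("teckin_nonincreasing_time",
                paste0(path, ": times not increasing at line ", i + 2))
  }
  sidecar <- sub("\\.csv$", ".json", path)
  if (sidecar != path && file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    for (nm in names(meta))
      if (length(meta[[nm]]) == 1 || is.numeric(meta[[nm]]))
        attr(df, nm) <- meta[[nm]]
  }
  df
}

#' Write a kinetic trace to CSV (with a JSON metadata sidecar)
#'
#' Numeric columns are written at full double precision so a
#' written-then-read trace is value-identical. Provenance attributes
#' (`seed`, `scheme`, `assay`, `noise`, concentrations, dead time) go to a
#' sidecar `<path minus .csv>.json` that [read_trace_csv()] reattaches.
#'
#' @param trace trace data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  for (col in names(df))
    if (is.numeric(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  keep <- setdiff(names(attributes(trace)),
                  c("names", "row.names", "class", "dim", "dimnames"))
  meta <- attributes(trace)[keep]
  meta <- Filter(function(x) is.atomic(x) && length(x) >= 1, meta)
  if (length(meta)) {
    sidecar <- sub("\\.csv$", ".json", path)
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a fit report to JSON
#'
#' Serializes a [fit_global()], [fit_stretched_exponential()] or
#' [fit_titration()] result to a JSON document carrying all parameters,
#' bounds (mirroring the lower / best fit / upper layout), chi-square,
#' flags, the chi-square-increase fraction used for bounds, and the package
#' version. Numbers are written at full precision so reading the report
#' back reproduces the numeric fields exactly.
#'
#' @param result the fit object.
#' @param path output path.
#' @param seed optional seed to record for provenance.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(result, path, seed = NULL) {
  ver <- as.character(utils::packageVersion("teckinetics"))
  rep <- if (inherits(result, "global_fit")) {
    r <- list(type = "global_fit", scheme = result$scheme_name,
              parameters = as.list(result$params),
              free = result$free, chi2 = result$chi2,
              converged = result$converged, iterations = result$niter,
              unidentifiable = result$unidentifiable,
              nuisances = result$nuisances)
    if (!is.null(result$Kd)) r$Kd_M <- result$Kd
    if (!is.null(result$bounds)) {
      b <- result$bounds
      r$bounds <- lapply(seq_len(nrow(b)), function(i)
        list(parameter = b$parameter[i], lower = b$lower[i],
             best = b$best[i], upper = b$upper[i],
             lower_unbounded = b$lower_unbounded[i],
             upper_unbounded = b$upper_unbounded[i]))
      r$chi2_increase <- attr(b, "chi2_increase")
    } else {
      r$chi2_increase <- 0.10
    }
    r
  } else if (inherits(result, "stretched_exp_fit")) {
    list(type = "stretched_exponential",
         baseline = result$baseline, amplitude = result$amplitude,
         tau_s = result$tau, beta = result$beta, rss = result$rss,
         median_time_s = result$median_time,
         at_beta_bound = result$at_beta_bound,
         short_span = result$short_span, n = result$n)
  } else if (inherits(result, "titration_fit")) {
    list(type = "titration",
         Kd_M = result$Kd_M, conf_level = result$conf_level,
         ci_profile_M = result$ci_profile_M, ci_wald_M = result$ci_wald_M,
         endpoints = result$endpoints, ssr = result$ssr, df = result$df,
         wide_ci_flag = result$wide_ci_flag)
  } else {
    stop_teckin("teckin_bad_report", "unsupported result type")
  }
  rep$seed <- seed
  rep$package_version <- ver
  ok <- try(jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                                 null = "null"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop_teckin("teckin_unwritable_path", paste0("cannot write report to ", path))
  invisible(path)
}

#' Read a fit report written by [write_fit_report()]
#'
#' @param path JSON report path.
#' @return the report as a list.
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path))
    stop_teckin("teckin_missing_file", paste0("file not found: ", path))
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Load an experiment manifest and build a dataset
#'
#' The manifest is a JSON document with fields: `scheme` (name), and
#' `observations`, an array of records each naming a trace `csv` path
#' (relative paths resolve against the manifest's directory), the
#' observable `kind` (`state_sum` with `states`, or `fluorescence` with
#' `coefficients`), and optional `conditions` (with explicit units:
#' `receptor_total_uM`, `species_totals_uM`, `dead_time_s`). Syringe
#' concentrations may be given instead as `receptor_syringe_uM` /
#' `species_syringe_uM`; post-mix values are half the syringe values
#' (equal-volume mixing), and the division is performed here, once.
#'
#' @param path manifest JSON path.
#' @return list with `scheme` (a `kinetic_scheme`), `dataset` (a
#'   [kinetic_dataset()]) and `init_params` when the manifest provides them.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path))
    stop_teckin("teckin_missing_file", paste0("manifest not found: ", path))
  m <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  scheme <- .scheme_registry(m$scheme %||% "three_step")
  obs <- lapply(m$observations, function(o) {
    csv <- o$csv
    if (!grepl("^(/|[A-Za-z]:)", csv)) csv <- file.path(dirname(path), csv)
    if (!file.exists(csv))
      stop_teckin("teckin_missing_file", paste0("trace file not found: ", csv))
    tr <- read_trace_csv(csv)
    omap <- if (identical(o$kind, "state_sum")) {
      observable_map("state_sum", states = unlist(o$states))
    } else {
      observable_map("fluorescence", coefficients = unlist(o$coefficients))
    }
    cond <- list()
    co <- o$conditions %||% list()
    rt <- co$receptor_total_uM %||%
      (if (!is.null(co$receptor_syringe_uM)) co$receptor_syringe_uM / 2)
    if (!is.null(rt)) cond$receptor_total <- rt * 1e-6
    st <- co$species_totals_uM %||%
      (if (!is.null(co$species_syringe_uM))
         lapply(co$species_syringe_uM, function(x) x / 2))
    if (!is.null(st)) cond$species_totals <- unlist(st) * 1e-6
    cond$dead_time <- co$dead_time_s %||% 0
    kin_observation(tr, omap, conditions = cond, label = o$label %||% csv)
  })
  init <- if (!is.null(m$init_params)) unlist(m$init_params) else NULL
  list(scheme = scheme, dataset = kinetic_dataset(obs), init_params = init)
}
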