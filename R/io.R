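#' Read a cohort measurement table from CSV
#'
#' Reads the canonical comma-separated cohort schema (UTF-8, header
#' row; `#`-prefixed lines are configuration-echo comments and are
#' skipped).  Required columns are `iop_mmHg`, `map_mmHg`, `flow_pct`
#' and `erg_pct`; `group`, `animal_id`, `step`, `po2_pct`,
#' `erg_sem_pct` and other `*_sem_pct`/`n` columns are carried through
#' when present.
#'
#' @param path CSV file path.
#' @param required Columns that must be present; a schema error naming
#'   the missing column is raised otherwise.
#' @return A tibble of measurement records.
#' @export
read_cohort_csv <- function(path,
                            required = c("iop_mmHg", "map_mmHg",
                                         "flow_pct", "erg_pct")) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("schema error in '", path, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Write a cohort measurement table to CSV
#'
#' Writes records in the canonical schema.  When the table carries a
#' generating [cohort_config()] (attribute `"config"`, as set by
#' [generate_cohort()]) or one is supplied, its JSON echo is written as
#' `#`-prefixed header comments so any output file is sufficient to
#' reproduce the run.
#'
#' @param x Data frame of records.
#' @param path Output CSV path.
#' @param config Optional [cohort_config()] to echo (defaults to
#'   `attr(x, "config")`).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path, config = attr(x, "config")) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(config)) {
    echo <- jsonlite::toJSON(config_echo(config), auto_unbox = TRUE)
    writeLines(paste("# config:", echo), con)
  }
  writeLines(paste("# written by opperg", as.character(utils::packageVersion("opperg"))), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_echo <- function(config) {
  list(map_level = config$map_level,
       iop_grid = c(config$iop_start, config$iop_stop, config$iop_step),
       flow_curve = unclass(config$flow_curve),
       gen_params = as.list(unclass(config$gen_params)),
       noise_sd = as.list(config$noise_sd),
       n_animals = config$n_animals,
       group = config$group,
       seed = config$seed)
}

#' Serialize a fit (with optional bootstrap intervals) as JSON
#'
#' Writes the fit report: parameter estimates, SSE, chi-square summary
#' (when available), flags, bootstrap 95\% intervals (when supplied)
#' and the seeds/settings needed to reproduce the run.
#'
#' @param fit An [fit_erg_model()] result.
#' @param path Output JSON path; `NULL` returns the report list
#'   without writing.
#' @param ci Optional [bootstrap_ci()] table to embed.
#' @return The report list, invisibly (visibly when `path` is `NULL`).
#' @export
write_fit_report <- function(fit, path = NULL, ci = NULL) {
  report <- list(
    params = as.list(unclass(fit$params)),
    sse = fit$sse,
    chi2 = if (!is.null(fit$gof)) fit$gof$chi2,
    df = if (!is.null(fit$gof)) fit$gof$df,
    q = if (!is.null(fit$gof)) fit$gof$q,
    grade = if (!is.null(fit$gof)) fit$gof$grade,
    flags = fit$flags,
    n_records = nrow(fit$data),
    n_starts = fit$n_starts,
    seed = fit$seed,
    bounds = lapply(fit$bounds, as.list)
  )
  if (!is.null(ci)) {
    report$ci <- lapply(seq_len(nrow(ci)), function(i) {
      list(parameter = ci$parameter[i], estimate = ci$estimate[i],
           lower = ci$lower[i], upper = ci$upper[i])
    })
    report$n_boot <- attr(ci, "n_boot")
    report$boot_type <- attr(ci, "type")
    report$boot_failed <- attr(ci, "n_failed")
  }
  if (is.null(path)) return(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(report)
}
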