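# Readers and writers for the plain-CSV interchange tables. Missing values
# are written as empty fields and round-trip as NA. Malformed numeric
# fields are reported with their (1-based, header-inclusive) line number.

read_checked_csv <- function(file, required, numeric_cols) {
  if (!file.exists(file)) stop(sprintf("file not found: %s", file))
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required columns: %s", file,
                 paste(miss, collapse = ", ")))
  }
  for (cn in intersect(numeric_cols, names(df))) {
    raw <- df[[cn]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value '%s' in column '%s' at line %d",
                   file, raw[bad[1]], cn, bad[1] + 1))
    }
    val[raw == ""] <- NA_real_
    df[[cn]] <- val
  }
  df
}

write_plain_csv <- function(df, file) {
  utils::write.csv(df, file, row.names = FALSE, na = "")
  invisible(file)
}

#' Write / read a climate ensemble as one long CSV
#'
#' Columns: `year`, `value`, `model_id` (empty for observed rows), and
#' `scenario` in `observed`, `preindustrial`, `projection`.
#'
#' @param ensemble A `climate_ensemble`.
#' @param file Path to the CSV file.
#' @return `write_climate_ensemble()` the path; `read_climate_ensemble()` a
#'   `climate_ensemble`.
#' @export
write_climate_ensemble <- function(ensemble, file) {
  rows <- rbind(
    data.frame(year = ensemble$observed$year, value = ensemble$observed$value,
               model_id = "", scenario = "observed"),
    do.call(rbind, lapply(ensemble$models, function(m) {
      rbind(data.frame(year = m$preindustrial$year, value = m$preindustrial$value,
                       model_id = m$model_id, scenario = "preindustrial"),
            data.frame(year = m$projection$year, value = m$projection$value,
                       model_id = m$model_id, scenario = "projection"))
    }))
  )
  write_plain_csv(rows, file)
}

#' @rdname write_climate_ensemble
#' @export
read_climate_ensemble <- function(file) {
  df <- read_checked_csv(file, c("year", "value", "model_id", "scenario"),
                         c("year", "value"))
  bad <- setdiff(unique(df$scenario),
                 c("observed", "preindustrial", "projection"))
  if (length(bad)) stop("unknown scenario labels: ", paste(bad, collapse = ", "))
  obs <- df[df$scenario == "observed", c("year", "value")]
  ids <- unique(df$model_id[df$scenario != "observed"])
  models <- lapply(ids, function(id) {
    list(model_id = id,
         preindustrial = df[df$scenario == "preindustrial" & df$model_id == id,
                            c("year", "value")],
         projection = df[df$scenario == "projection" & df$model_id == id,
                         c("year", "value")])
  })
  structure(list(observed = `rownames<-`(obs, NULL), models = models),
            class = "climate_ensemble")
}

#' Write / read a survey panel (long format)
#'
#' Columns `year`, `series_id`, `value`; missing survey years round-trip as
#' empty fields.
#'
#' @param panel Long data.frame.
#' @param file Path.
#' @export
write_survey_panel <- function(panel, file) write_plain_csv(panel, file)

#' @rdname write_survey_panel
#' @export
read_survey_panel <- function(file) {
  read_checked_csv(file, c("year", "series_id", "value"), c("year", "value"))
}

#' Write / read seine catch records
#'
#' @param data A `seine_catch` data.frame.
#' @param file Path.
#' @export
write_seine_catch <- function(data, file) write_plain_csv(data, file)

#' @rdname write_seine_catch
#' @export
read_seine_catch <- function(file) {
  df <- read_checked_csv(file, c("year", "day_of_year", "bay", "site", "count"),
                         c("year", "day_of_year", "count", "temperature", "ssb"))
  if (nrow(df) && any(df$count != round(df$count) | df$count < 0, na.rm = TRUE)) {
    bad <- which(df$count != round(df$count) | df$count < 0)[1]
    stop(sprintf("%s: count must be a non-negative integer at line %d",
                 file, bad + 1))
  }
  df$count <- as.integer(df$count)
  class(df) <- c("seine_catch", "data.frame")
  df
}

#' Write / read a recruitment series
#'
#' Columns `year`, `log_anomaly`, optional `source`; the standardization
#' constants travel in companion columns `center`/`scale` on the first row
#' if supplied via attributes.
#'
#' @param series data.frame (`year`, `log_anomaly`, ...).
#' @param file Path.
#' @export
write_recruitment_series <- function(series, file) write_plain_csv(series, file)

#' @rdname write_recruitment_series
#' @export
read_recruitment_series <- function(file) {
  read_checked_csv(file, c("year", "log_anomaly"), c("year", "log_anomaly"))
}

#' Write / read a FAR table or FAR estimate
#'
#' @param x A `far_table` or `far_estimate` data.frame.
#' @param file Path.
#' @export
write_far_table <- function(x, file) write_plain_csv(x, file)

#' @rdname write_far_table
#' @export
read_far_table <- function(file) {
  df <- read_checked_csv(file, c("year", "model_id", "far"),
                         c("year", "far", "p_pre", "p_cur"))
  class(df) <- c("far_table", "data.frame")
  df
}

#' @rdname write_far_table
#' @export
read_far_estimate <- function(file) {
  df <- read_checked_csv(file, c("year", "mean", "se"),
                         c("year", "mean", "se", "lo80", "hi80", "lo90",
                           "hi90", "lo95", "hi95"))
  class(df) <- c("far_estimate", "data.frame")
  df
}

#' Generate and write a complete synthetic data set
#'
#' Produces every pipeline input (climate ensemble, seine catch, survey
#' panel, recruitment series) under one master seed, writes them as plain
#' CSV files plus a JSON sidecar recording all generator parameters, and
#' returns the objects invisibly.
#'
#' @param dir Output directory (created if needed).
#' @param climate,recruit,seine Parameter objects (defaults used if NULL).
#' @param seed Master seed applied to all generators.
#' @return Invisibly, a list of generated objects and file paths.
#' @export
write_synthetic_dataset <- function(dir, climate = NULL, recruit = NULL,
                                    seine = NULL, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  climate <- climate %||% climate_sim_params(seed = seed)
  recruit <- recruit %||% recruit_sim_params(seed = seed)
  seine <- seine %||% seine_sim_params(seed = seed)
  climate$seed <- recruit$seed <- seine$seed <- seed

  ens <- simulate_climate(climate)
  ft <- suppressMessages(build_far_table(ens, "hindcast"))
  far_yr <- stats::aggregate(far ~ year, data = ft, FUN = mean)
  rec <- simulate_recruitment(far_yr$far, recruit, years = far_yr$year)
  rec$source <- "assessment"
  seine_years <- seine$first_year + seq_len(seine$n_years) - 1
  far_seine <- far_yr$far[match(seine_years, far_yr$year)]
  far_seine[is.na(far_seine)] <- 0
  catch <- simulate_seine(seine, far_by_year = far_seine)
  trend <- simulate_latent_trend(length(far_yr$year), seed = seed)
  panel <- simulate_survey_panel(trend, loadings = c(0.8, 0.6, 0.4, 0.0),
                                 obs_sd = rep(0.4, 4),
                                 missing_frac = rep(0.15, 4),
                                 seed = seed, years = far_yr$year)
  paths <- list(
    climate = file.path(dir, "climate_ensemble.csv"),
    seine = file.path(dir, "seine_catch.csv"),
    survey_panel = file.path(dir, "survey_panel.csv"),
    assessment = file.path(dir, "recruitment.csv")
  )
  write_climate_ensemble(ens, paths$climate)
  write_seine_catch(catch, paths$seine)
  write_survey_panel(panel, paths$survey_panel)
  write_recruitment_series(rec, paths$assessment)
  sidecar <- list(seed = seed,
                  climate = unclass(climate), recruit = unclass(recruit),
                  seine = unclass(seine))
  jsonlite::write_json(sidecar, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(ensemble = ens, seine = catch, panel = panel,
                 recruitment = rec, paths = paths))
}
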