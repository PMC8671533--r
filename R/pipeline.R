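# End-to-end orchestration: attribution -> latent trend / annual index /
# bridge -> recruitment-FAR spline with measurement error -> decadal
# projection, with every stage's outputs written and a machine-readable
# manifest linking them.

#' Assemble a pipeline configuration
#'
#' @param paths Named list of input file paths: `climate` (long ensemble
#'   CSV), `seine`, `survey_panel`, `assessment`; optional `far_hist`,
#'   `far_proj` (precomputed FAR estimate CSVs, otherwise computed from the
#'   climate file).
#' @param out_dir Directory for stage outputs and the manifest.
#' @param center_window,scale_window Year ranges for anomaly
#'   standardization (NULL = full series).
#' @param far_threshold Categorical-FAR threshold (default 0.98).
#' @param clamp_lo,clamp_hi FAR clamping bounds.
#' @param k_far Spline basis size for FAR smooths (3 or 5).
#' @param chains,iter,burn,adapt MCMC settings shared by all fits.
#' @param seed Master seed; recorded in every output sidecar.
#' @param periods Named list of year vectors (first = historical reference).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(paths, out_dir,
                            center_window = NULL, scale_window = NULL,
                            far_threshold = 0.98,
                            clamp_lo = 1e-4, clamp_hi = 0.9999,
                            k_far = 3, chains = 2, iter = 1000, burn = 500,
                            adapt = 500, seed = 1, periods = NULL) {
  required <- c("climate", "seine", "survey_panel", "assessment")
  miss <- setdiff(required, names(paths))
  if (length(miss)) stop("paths missing for inputs: ", paste(miss, collapse = ", "))
  structure(list(paths = paths, out_dir = out_dir,
                 center_window = center_window, scale_window = scale_window,
                 far_threshold = far_threshold, clamp_lo = clamp_lo,
                 clamp_hi = clamp_hi, k_far = k_far, chains = chains,
                 iter = iter, burn = burn, adapt = adapt, seed = seed,
                 periods = periods),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param file YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  y <- yaml::read_yaml(file)
  do.call(pipeline_config, y)
}

stage_run <- function(name, input_hint, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed (input: %s): %s",
                 name, input_hint, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full attribution-to-recruitment pipeline
#'
#' Stages: (1) attribution — FAR tables and Bayesian ensemble FAR
#' posteriors for hindcast and projection periods; (2) latent trend — DFA
#' on the survey panel; (3) annual index — year-effect ZINB on the seine
#' data; (4) bridge — regression of assessment recruitment on the annual
#' index to fill recent years; (5) recruitment model — measurement-error
#' FAR spline on the bridged series; (6) projection — per-period predicted
#' recruitment with percent declines. Every stage writes CSV outputs under
#' `out_dir` and the manifest (`manifest.json`) records stages, files and
#' the seed.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (nm in names(config$paths)) {
    if (!file.exists(config$paths[[nm]])) {
      stop(sprintf("input file for '%s' not found: %s", nm, config$paths[[nm]]))
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  outputs <- list()
  note <- function(stage, files) {
    manifest$stages[[length(manifest$stages) + 1]] <<-
      list(stage = stage, outputs = as.character(files))
  }
  opath <- function(f) file.path(config$out_dir, f)

  # 1. attribution
  res_attr <- stage_run("attribution", config$paths$climate, {
    ens <- read_climate_ensemble(config$paths$climate)
    ft_h <- suppressMessages(build_far_table(ens, "hindcast",
                                             config$clamp_lo, config$clamp_hi))
    ft_p <- suppressMessages(build_far_table(ens, "projection",
                                             config$clamp_lo, config$clamp_hi))
    if (!is.null(config$paths$far_hist)) {
      fe_h <- read_far_estimate(config$paths$far_hist)
      fe_p <- read_far_estimate(config$paths$far_proj)
    } else {
      fe_h <- fit_far_model(ft_h, chains = config$chains, iter = config$iter,
                            burn = config$burn, adapt = config$adapt,
                            seed = substream_seed(config$seed, "far-hind"))
      fe_p <- fit_far_model(ft_p, chains = config$chains, iter = config$iter,
                            burn = config$burn, adapt = config$adapt,
                            seed = substream_seed(config$seed, "far-proj"))
    }
    write_far_table(ft_h, opath("far_table_hindcast.csv"))
    write_far_table(ft_p, opath("far_table_projection.csv"))
    write_plain_csv(as.data.frame(fe_h), opath("far_estimate_hindcast.csv"))
    write_plain_csv(as.data.frame(fe_p), opath("far_estimate_projection.csv"))
    list(ensemble = ens, table_hind = ft_h, table_proj = ft_p,
         est_hind = fe_h, est_proj = fe_p)
  })
  note("attribution", c("far_table_hindcast.csv", "far_table_projection.csv",
                        "far_estimate_hindcast.csv", "far_estimate_projection.csv"))

  # 2. latent trend (DFA)
  res_dfa <- stage_run("latent_trend", config$paths$survey_panel, {
    panel <- read_survey_panel(config$paths$survey_panel)
    fit <- fit_dfa(panel)
    write_plain_csv(fit$trend, opath("dfa_trend.csv"))
    write_plain_csv(fit$loadings, opath("dfa_loadings.csv"))
    fit
  })
  note("latent_trend", c("dfa_trend.csv", "dfa_loadings.csv"))

  # 3. annual abundance index (ZINB with year effects)
  res_index <- stage_run("annual_index", config$paths$seine, {
    catch <- read_seine_catch(config$paths$seine)
    fit <- fit_zinb(catch, covariates = "day_of_year", year_effect = TRUE,
                    chains = config$chains, iter = config$iter,
                    burn = config$burn, adapt = config$adapt,
                    seed = substream_seed(config$seed, "zinb-index"))
    idx <- annual_index(fit)
    write_plain_csv(idx, opath("annual_index.csv"))
    list(fit = fit, index = idx)
  })
  note("annual_index", "annual_index.csv")

  # 4. bridge recent recruitment from the seine index
  res_bridge <- stage_run("bridge", config$paths$assessment, {
    assess <- read_recruitment_series(config$paths$assessment)
    idx <- res_index$index
    idx_log <- data.frame(year = idx$year, estimate = log(idx$median))
    n_pred <- min(3, nrow(idx) - 3)
    pred_years <- utils::tail(sort(idx$year), n_pred)
    overlap_years <- setdiff(intersect(assess$year, idx$year), pred_years)
    if (length(overlap_years) >= 3 && n_pred >= 1) {
      bridged <- bridge_recent_recruitment(
        idx_log, assess, overlap = range(overlap_years),
        predict_years = intersect(pred_years, idx$year))
    } else {
      bridged <- data.frame(year = assess$year,
                            log_anomaly = assess$log_anomaly,
                            source = "assessment", pred_se = 0)
    }
    # re-standardize the merged series over its reference years
    z <- standardize(bridged$log_anomaly)
    series <- data.frame(year = bridged$year, log_anomaly = as.numeric(z),
                         source = bridged$source)
    attr(series, "center") <- attr(z, "center")
    attr(series, "scale") <- attr(z, "scale")
    write_plain_csv(series, opath("recruitment_bridged.csv"))
    series
  })
  note("bridge", "recruitment_bridged.csv")

  # 5. recruitment-FAR spline with FAR measurement error
  res_gam <- stage_run("recruitment_model", "recruitment_bridged.csv", {
    fit <- fit_far_gam_me(res_bridge, res_attr$est_hind, k = config$k_far,
                          chains = config$chains, iter = config$iter,
                          burn = config$burn, adapt = config$adapt,
                          seed = substream_seed(config$seed, "gam-me"))
    r2 <- bayes_r2(fit)
    write_plain_csv(data.frame(looic = fit$looic, r2_median = r2$median,
                               r2_lo95 = r2$ci95[1], r2_hi95 = r2$ci95[2]),
                    opath("recruit_fit_summary.csv"))
    fit
  })
  note("recruitment_model", "recruit_fit_summary.csv")

  # 6. projection by period
  res_proj <- stage_run("projection", "far_estimate_projection.csv", {
    periods <- config$periods
    if (is.null(periods)) {
      hist_years <- intersect(res_gam$years, res_attr$est_hind$year)
      proj_years <- res_attr$est_proj$year
      dec <- split(proj_years, (proj_years %/% 10) * 10)
      dec <- dec[vapply(dec, length, integer(1)) >= 5]
      periods <- c(list(historical = hist_years),
                   stats::setNames(dec, paste0(names(dec), "s")))
    }
    summ <- summarize_projection(
      res_gam, res_attr$est_hind, res_attr$est_proj, periods,
      center = attr(res_bridge, "center") %||% 0,
      scale = attr(res_bridge, "scale") %||% 1,
      seed = substream_seed(config$seed, "projection"))
    write_plain_csv(summ, opath("projection_summary.csv"))
    summ
  })
  note("projection", "projection_summary.csv")

  manifest$config <- list(
    paths = config$paths, far_threshold = config$far_threshold,
    clamp = c(config$clamp_lo, config$clamp_hi), k_far = config$k_far,
    chains = config$chains, iter = config$iter)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(attribution = res_attr, dfa = res_dfa, index = res_index,
                 recruitment = res_bridge, fit = res_gam,
                 projection = res_proj, manifest = manifest))
}
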