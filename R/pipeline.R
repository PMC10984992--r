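#' Pipeline configuration
#'
#' Bundles the synthetic-survey configuration, stage toggles, seeds and
#' conventions for [run_pipeline()].
#'
#' @param synthetic a [synthetic_config()] (the simulate stage's
#'   scenario).
#' @param out_dir output directory (created if absent).
#' @param stages which stages to run, in order.
#' @param widths height-class widths by vegetation type.
#' @param responses metric(s) modelled in the drivers stage.
#' @param bootstrap_reps bootstrap replicates for the size-matched
#'   attribution (0 skips it).
#' @param bootstrap_n plots drawn per type and replicate.
#' @param krige_vars soil/atmospheric layers rebuilt by kriging from the
#'   plots before mapping (NULL skips kriging).
#' @param registry driver registry.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            out_dir = tempfile("vsc_run_"),
                            stages = c("simulate", "metrics", "drivers",
                                       "upscale", "report"),
                            widths = class_widths(),
                            responses = "height_max",
                            bootstrap_reps = 0L,
                            bootstrap_n = 237L,
                            krige_vars = c("pH", "SOC", "TN", "PO2", "PCO2"),
                            registry = vsc_variables()) {
  stopifnot(all(widths > 0))
  if (anyDuplicated(registry$name) || nrow(registry) != 13L) {
    stop("registry must classify the 13 drivers exactly once", call. = FALSE)
  }
  structure(
    list(
      synthetic = synthetic, out_dir = out_dir, stages = stages,
      widths = widths, responses = responses,
      bootstrap_reps = bootstrap_reps, bootstrap_n = bootstrap_n,
      krige_vars = krige_vars, registry = registry
    ),
    class = "pipeline_config"
  )
}

stage_log <- function(cfg, ...) {
  message("[vsc] ", paste0(...))
}

#' Run the full analysis pipeline
#'
#' Executes, in order, the enabled stages: `simulate` (synthetic survey +
#' raster), `metrics` (per-plot VSC, written to `vsc.csv`), `drivers`
#' (screening, per-type stepwise attribution written to `models.json`,
#' optional bootstrap size-matching), `upscale` (kriged predictor
#' layers, random-forest fit, gridded maps written as ASCII grids) and
#' `report` (Table-1-style summary and resource/non-resource shares).
#' All randomness derives from the seed in the synthetic config, echoed
#' to the log, so a fixed config reproduces every output bit for bit.
#'
#' @param config a [pipeline_config()].
#' @return the report bundle (named list of stage outputs), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list()
  run <- function(stage) stage %in% config$stages
  seed <- config$synthetic$seed

  if (run("simulate")) {
    stage_log(config, "simulate: seed ", seed)
    bundle$plots <- generate_plots(config$synthetic)
    bundle$raster <- generate_raster(config$synthetic)
    write_plot_table(bundle$plots$plants, file.path(config$out_dir, "plots.csv"))
    write_env_table(bundle$plots$env, file.path(config$out_dir, "env.csv"))
  }

  if (run("metrics")) {
    if (is.null(bundle$plots)) stop("metrics: no plot data", call. = FALSE)
    stage_log(config, "metrics: ", nrow(bundle$plots$env), " plots")
    bundle$vsc <- compute_vsc(bundle$plots$plants, config$widths)
    utils::write.csv(bundle$vsc, file.path(config$out_dir, "vsc.csv"),
      row.names = FALSE, quote = FALSE, na = ""
    )
  }

  if (run("drivers")) {
    if (is.null(bundle$vsc)) stop("drivers: no VSC table", call. = FALSE)
    stage_log(config, "drivers: screening 13 variables")
    bundle$screen <- screen_variables(bundle$plots$env)
    merged <- merge(bundle$vsc, bundle$plots$env[, c("plot_id", bundle$screen$kept)],
      by = "plot_id"
    )
    models <- list()
    for (ty in intersect(veg_types(), unique(merged$veg_type))) {
      sub <- merged[merged$veg_type == ty, ]
      for (resp in config$responses) {
        fml <- stats::reformulate(bundle$screen$kept, resp)
        fit <- fit_drivers(fml, sub,
          registry = config$registry,
          coords = sub[, c("lon", "lat")]
        )
        models[[ty]][[resp]] <- driver_model_record(fit)
      }
    }
    bundle$models <- models
    jsonlite::write_json(models, file.path(config$out_dir, "models.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    if (config$bootstrap_reps > 0L) {
      btypes <- names(which(table(merged$veg_type) >= config$bootstrap_n))
      btypes <- intersect(veg_types(), btypes)
      stage_log(config, "drivers: bootstrap x", config$bootstrap_reps,
                " (seed ", seed, ")")
      bundle$bootstrap <- bootstrap_match(
        merged, config$responses[1L], bundle$screen$kept,
        n_target = config$bootstrap_n, n_reps = config$bootstrap_reps,
        seed = seed, types = btypes
      )
    }
  }

  if (run("upscale")) {
    if (is.null(bundle$vsc)) stop("upscale: no VSC table", call. = FALSE)
    stage_log(config, "upscale: RF split seed ", seed)
    raster <- bundle$raster
    if (!is.null(config$krige_vars) && !is.null(raster)) {
      stage_log(config, "upscale: kriging ",
                paste(config$krige_vars, collapse = ", "))
      raster <- krige_to_raster(raster, bundle$plots$env,
        vars = config$krige_vars
      )
      bundle$raster <- raster
    }
    bundle$upscale <- fit_rf(bundle$vsc, bundle$plots$env, split_seed = seed)
    if (!is.null(raster)) {
      bundle$maps <- predict_map(bundle$upscale, raster)
      for (resp in names(bundle$maps$layers)) {
        write_grid(
          bundle$maps$layers[[resp]],
          file.path(config$out_dir, paste0("map_", resp, ".asc")),
          xll = min(bundle$maps$lon), yll = min(bundle$maps$lat),
          cellsize = bundle$maps$cell_size[2L]
        )
      }
    }
  }

  if (run("report")) {
    if (!is.null(bundle$vsc)) {
      bundle$summary <- vsc_summary(bundle$vsc)
      utils::write.csv(bundle$summary,
        file.path(config$out_dir, "summary.csv"),
        row.names = FALSE, quote = FALSE
      )
    }
    if (!is.null(bundle$models)) {
      shares <- do.call(rbind, lapply(names(bundle$models), function(ty) {
        m <- bundle$models[[ty]][[config$responses[1L]]]
        data.frame(
          veg_type = ty, response = config$responses[1L],
          resource_share = m$resource_share,
          nonresource_share = m$nonresource_share,
          r2_total = m$r2_total, stringsAsFactors = FALSE
        )
      }))
      bundle$shares <- shares
      utils::write.csv(shares, file.path(config$out_dir, "shares.csv"),
        row.names = FALSE, quote = FALSE
      )
    }
    stage_log(config, "report: written to ", config$out_dir)
  }
  invisible(bundle)
}

# serializable snapshot of a driver_model (for models.json)
driver_model_record <- function(fit) {
  list(
    response = fit$response,
    n = fit$n,
    selected = as.list(fit$selected),
    coefficients = if (length(fit$selected) > 0L) {
      as.list(stats::setNames(
        fit$coefficients[fit$selected, "Estimate"], fit$selected
      ))
    } else {
      list()
    },
    p_values = if (length(fit$selected) > 0L) {
      as.list(stats::setNames(
        fit$coefficients[fit$selected, "Pr(>|t|)"], fit$selected
      ))
    } else {
      list()
    },
    vif = as.list(fit$vif[!is.na(fit$vif)]),
    r2_total = fit$r2_total,
    r2_by_var = as.list(fit$r2_by_var),
    resource_share = fit$resource_share,
    nonresource_share = fit$nonresource_share,
    residual_moran_i = if (!is.null(fit$residual_moran)) {
      fit$residual_moran$observed
    } else {
      NULL
    }
  )
}
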