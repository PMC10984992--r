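#' Train/validation split indices
#'
#' @param n number of rows.
#' @param train_frac training fraction (default 0.75).
#' @param seed RNG seed.
#' @return list with integer `train` and `test` index vectors
#'   (`floor(train_frac * n)` training rows).
#' @export
train_test_split <- function(n, train_frac = 0.75, seed = 1L) {
  set.seed(seed)
  tr <- sort(sample.int(n, floor(train_frac * n)))
  list(train = tr, test = setdiff(seq_len(n), tr))
}

#' Random-forest upscaling of plot-level VSC
#'
#' Trains one regression forest per VSC metric on the 13 drivers using
#' 75% of the plots, and reports the hold-out accuracy on the remaining
#' 25% together with the node-purity (variance-reduction) importance
#' ranking. Height-max is log10-transformed before training (its plot
#' values span more than two orders of magnitude); predictions are
#' back-transformed by [predict_map()].
#'
#' @param vsc per-plot VSC table from [compute_vsc()].
#' @param env per-plot environment table carrying the 13 driver columns
#'   and `plot_id`.
#' @param responses metric columns to model.
#' @param split_seed seed for the 75/25 split and forest growth.
#' @param ntree,mtry forest size and candidate variables per split
#'   (defaults 500 and `ceiling(p/3)`).
#' @param train_frac training fraction.
#' @param min_train minimum admissible training-set size.
#' @param log_height_max log10-transform Height-max (default TRUE).
#' @param r2_mode hold-out accuracy convention: `"cor"` (squared Pearson
#'   correlation of observed and predicted, default) or `"ss"`
#'   (1 - SSE/SST).
#' @return An object of class `upscale_report`: fitted `models`,
#'   `validation_r2`, `importance` (named, decreasing), `observed` and
#'   `predicted` hold-out values per response, `train`/`test` indices
#'   and the seed.
#' @export
fit_rf <- function(vsc, env,
                   responses = c("height_max", "height_var", "height_even"),
                   split_seed = 1L, ntree = 500L, mtry = NULL,
                   train_frac = 0.75, min_train = 30L,
                   log_height_max = TRUE, r2_mode = c("cor", "ss")) {
  r2_mode <- match.arg(r2_mode)
  vars <- vsc_variables()$name
  missing_cols <- setdiff(vars, names(env))
  if (length(missing_cols) > 0L) {
    stop("missing driver columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  d <- merge(vsc, env[, c("plot_id", vars)], by = "plot_id")
  d <- d[order(d$plot_id), ] # canonical row order: fixed-seed reproducibility
  d <- d[stats::complete.cases(d[, c(responses, vars)]), ]
  n <- nrow(d)
  split <- train_test_split(n, train_frac, split_seed)
  if (length(split$train) < min_train) {
    stop("training set smaller than ", min_train, " plots", call. = FALSE)
  }
  x <- d[, vars]
  if (is.null(mtry)) mtry <- ceiling(length(vars) / 3)

  models <- list()
  r2 <- numeric(0)
  importance <- list()
  observed <- list()
  predicted <- list()
  for (resp in responses) {
    y <- d[[resp]]
    if (resp == "height_max" && log_height_max) y <- log10(y)
    set.seed(split_seed)
    rf <- randomForest::randomForest(
      x = x[split$train, ], y = y[split$train],
      ntree = ntree, mtry = mtry
    )
    pred <- stats::predict(rf, x[split$test, ])
    obs <- y[split$test]
    r2[resp] <- switch(r2_mode,
      cor = stats::cor(obs, pred)^2,
      ss = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    )
    imp <- rf$importance[, "IncNodePurity"]
    importance[[resp]] <- sort(imp, decreasing = TRUE)
    models[[resp]] <- rf
    observed[[resp]] <- obs
    predicted[[resp]] <- unname(pred)
  }
  structure(
    list(
      models = models, validation_r2 = r2, importance = importance,
      observed = observed, predicted = predicted,
      train = split$train, test = split$test, seed = split_seed,
      responses = responses, log_height_max = log_height_max,
      r2_mode = r2_mode, predictors = vars
    ),
    class = "upscale_report"
  )
}

#' @export
print.upscale_report <- function(x, ...) {
  cat("Random-forest upscaling:", length(x$train), "training /",
      length(x$test), "validation plots\n")
  for (resp in x$responses) {
    top <- names(x$importance[[resp]])[1:3]
    cat(sprintf(
      "  %-12s validation R2 = %.3f; top drivers: %s\n",
      resp, x$validation_r2[[resp]], paste(top, collapse = ", ")
    ))
  }
  invisible(x)
}

#' Predict gridded VSC maps
#'
#' Applies the fitted forests to every unmasked cell of a predictor
#' raster stack; Height-max is back-transformed from log10. Masked cells
#' propagate as NA.
#'
#' @param report an [fit_rf()] report.
#' @param raster a `raster_stack` whose layers cover every model
#'   predictor.
#' @return A `raster_stack` with one predicted layer per response.
#' @export
predict_map <- function(report, raster) {
  stopifnot(inherits(raster, "raster_stack"))
  missing_layers <- setdiff(report$predictors, names(raster$layers))
  if (length(missing_layers) > 0L) {
    stop("missing raster layer(s): ", paste(missing_layers, collapse = ", "),
      call. = FALSE
    )
  }
  nr <- length(raster$lat)
  nc <- length(raster$lon)
  cells <- data.frame(lapply(
    raster$layers[report$predictors],
    function(m) as.vector(m)
  ))
  ok <- stats::complete.cases(cells)
  out <- list()
  for (resp in report$responses) {
    v <- rep(NA_real_, nr * nc)
    if (any(ok)) {
      p <- stats::predict(report$models[[resp]], cells[ok, , drop = FALSE])
      if (resp == "height_max" && report$log_height_max) p <- 10^p
      v[ok] <- p
    }
    out[[resp]] <- matrix(v, nr, nc)
  }
  structure(
    list(layers = out, lat = raster$lat, lon = raster$lon,
         elevation = raster$elevation, mask = raster$mask,
         cell_size = raster$cell_size),
    class = "raster_stack"
  )
}

#' Observed vs predicted hold-out table
#'
#' @param report an [fit_rf()] report.
#' @param response which response to extract.
#' @return data frame `observed`, `predicted` with attribute `r2`
#'   (squared Pearson correlation; the 1:1-line diagnostic).
#' @export
observed_vs_predicted <- function(report, response = report$responses[1L]) {
  obs <- report$observed[[response]]
  pred <- report$predicted[[response]]
  out <- data.frame(observed = obs, predicted = pred)
  attr(out, "r2") <- stats::cor(obs, pred)^2
  out
}

#' Kriged predictor layers from plot samples
#'
#' Fills the soil/atmospheric predictor layers of a raster stack by
#' ordinary kriging of their plot-level samples (the survey measures
#' them only at plots).
#'
#' @param raster template `raster_stack` (provides the grid and mask).
#' @param env plot environment table with `lon`, `lat` and the sampled
#'   columns.
#' @param vars variables to krige.
#' @param ... passed to [krige_layer()].
#' @return the raster stack with the kriged layers replaced.
#' @export
krige_to_raster <- function(raster, env,
                            vars = c("pH", "SOC", "TN", "PO2", "PCO2"),
                            ...) {
  stopifnot(inherits(raster, "raster_stack"))
  grid <- cbind(
    lon = rep(raster$lon, each = length(raster$lat)),
    lat = rep(raster$lat, length(raster$lon))
  )
  for (v in vars) {
    kr <- krige_layer(cbind(env$lon, env$lat), env[[v]], grid, ...)
    m <- matrix(kr$pred, length(raster$lat), length(raster$lon))
    m[raster$mask] <- NA_real_
    raster$layers[[v]] <- m
  }
  raster
}
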