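#' Fit a stepwise driver-attribution model
#'
#' The central fitting function: starting from the full OLS model of a
#' VSC metric on the screened drivers, a bidirectional AIC search
#' ([MASS::stepAIC]) finds the minimal adequate model; the surviving
#' predictors are then decomposed into per-variable R-squared shares
#' (LMG by default, averaging the incremental R-squared over all orders
#' of entry), checked for collinearity with VIFs, aggregated into
#' resource vs non-resource shares, and — when coordinates are supplied —
#' the residuals are screened for spatial autocorrelation with Moran's I.
#'
#' @param formula model formula, e.g. `height_max ~ MAT + AI + ...` or
#'   `log(height_max) ~ .` with `data` restricted to the drivers.
#' @param data data frame holding the response and drivers.
#' @param registry driver registry (default [vsc_variables()]) used for
#'   the resource split.
#' @param coords optional two-column (lon, lat) matrix/data frame of plot
#'   coordinates for the residual Moran's I.
#' @param importance `"lmg"` (default) or `"sequential"`.
#' @param direction stepwise direction, passed to [MASS::stepAIC].
#' @param alpha significance level used when printing (reporting only;
#'   selection is AIC-driven).
#' @return An object of class `driver_model`.
#' @seealso [lmg_importance()], [resource_split()], [morans_i()]
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(AI = rnorm(80), Wind = rnorm(80))
#' d$y <- 1.5 * d$AI - 0.5 * d$Wind + rnorm(80, 0, 0.5)
#' fit <- fit_drivers(y ~ AI + Wind, d)
#' coef(fit)
fit_drivers <- function(formula, data, registry = vsc_variables(),
                        coords = NULL, importance = c("lmg", "sequential"),
                        direction = "both", alpha = 0.05) {
  importance <- match.arg(importance)
  # stepAIC re-evaluates the model call in the formula environment, so
  # the data must be reachable there under a stable name
  fit_env <- new.env(parent = environment(formula) %||% parent.frame())
  assign("..vsc_fit_data..", data, envir = fit_env)
  fml <- formula
  environment(fml) <- fit_env
  full <- eval(
    call("lm", formula = fml, data = as.name("..vsc_fit_data..")),
    fit_env
  )
  aliased <- names(stats::coef(full))[is.na(stats::coef(full))]
  if (length(aliased) > 0L) {
    stop("rank-deficient design; aliased columns: ",
      paste(aliased, collapse = ", "),
      call. = FALSE
    )
  }
  n <- stats::nobs(full)
  p_full <- length(stats::coef(full)) - 1L
  if (n <= p_full + 2L) {
    stop("need n > p + 2 observations", call. = FALSE)
  }
  # stepAIC refits candidate models with eval.parent(), so it must be
  # called from fit_env as well
  fit <- eval(
    as.call(list(MASS::stepAIC, full, direction = direction, trace = 0)),
    fit_env
  )
  selected <- attr(stats::terms(fit), "term.labels")

  mf <- stats::model.frame(fit)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(fit)[, selected, drop = FALSE]
  r2_total <- summary(fit)$r.squared
  r2_by_var <- if (length(selected) > 0L) {
    switch(importance,
      lmg = lmg_importance(y, x),
      sequential = seq_importance(y, x)
    )
  } else {
    stats::setNames(numeric(0), character(0))
  }
  # generic predictors outside the registry leave the split undefined
  shares <- if (length(selected) > 0L &&
                all(names(r2_by_var) %in% registry$name)) {
    resource_split(r2_by_var, registry)
  } else {
    c(resource = NA_real_, nonresource = NA_real_)
  }
  vif <- vif_values(x)
  moran <- if (!is.null(coords) && length(selected) > 0L) {
    morans_i(stats::residuals(fit), coords = coords)
  } else {
    NULL
  }

  ct <- summary(fit)$coefficients
  structure(
    list(
      call = match.call(), formula = formula, response = all.vars(formula)[1L],
      fit = fit, selected = selected, coefficients = ct,
      r2_total = r2_total, r2_by_var = r2_by_var, vif = vif,
      resource_share = unname(shares["resource"]),
      nonresource_share = unname(shares["nonresource"]),
      residual_moran = moran, importance = importance,
      aic = stats::AIC(fit), n = n, alpha = alpha
    ),
    class = "driver_model"
  )
}

#' @export
print.driver_model <- function(x, digits = 3, ...) {
  cat("Driver-attribution model:", x$response, "~",
      if (length(x$selected) > 0L) paste(x$selected, collapse = " + ")
      else "1", "\n")
  cat(sprintf("n = %d, model R2 = %.3f (AIC %.1f)\n", x$n, x$r2_total, x$aic))
  if (length(x$selected) > 0L) {
    tab <- data.frame(
      estimate = x$coefficients[x$selected, "Estimate"],
      p = x$coefficients[x$selected, "Pr(>|t|)"],
      VIF = x$vif[x$selected],
      R2 = x$r2_by_var[x$selected]
    )
    tab <- tab[order(-tab$R2), ]
    print(round(tab, digits))
    cat(sprintf(
      "relative importance: resource %.1f%%, non-resource %.1f%% (%s)\n",
      x$resource_share, x$nonresource_share, x$importance
    ))
  }
  if (!is.null(x$residual_moran)) {
    cat(sprintf(
      "residual Moran's I = %.4f (null expectation %.4f)\n",
      x$residual_moran$observed, x$residual_moran$expected
    ))
  }
  invisible(x)
}

#' @export
summary.driver_model <- function(object, ...) {
  out <- list(
    model = object,
    lm_summary = summary(object$fit),
    significant = if (length(object$selected) > 0L) {
      object$selected[
        object$coefficients[object$selected, "Pr(>|t|)"] < object$alpha
      ]
    } else {
      character(0)
    }
  )
  class(out) <- "summary.driver_model"
  out
}

#' @export
print.summary.driver_model <- function(x, ...) {
  print(x$model)
  cat("significant at alpha =", x$model$alpha, ":",
      if (length(x$significant)) paste(x$significant, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' @export
coef.driver_model <- function(object, ...) stats::coef(object$fit)

#' @export
predict.driver_model <- function(object, newdata = NULL, ...) {
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.driver_model <- function(object, ...) stats::residuals(object$fit)

#' Bootstrap size-matched driver attribution
#'
#' Equalises sample sizes across vegetation types by drawing `n_target`
#' plots without replacement per type and replicate, re-running the full
#' stepwise + relative-importance + resource-split chain each time.
#' Types with fewer than `n_target` plots cannot be resampled and must be
#' excluded by the caller (the survey's shrublands, with 30 plots, are
#' the canonical exclusion).
#'
#' @param data merged per-plot table holding `veg_type`, the response and
#'   the predictors.
#' @param response response column name.
#' @param predictors character vector of predictor columns (typically the
#'   `kept` set of [screen_variables()]).
#' @param n_target plots drawn per type and replicate.
#' @param n_reps number of replicates.
#' @param seed RNG seed.
#' @param types vegetation types to resample (default: all in `data`).
#' @return An object of class `bootstrap_match`: data frame with one row
#'   per replicate x type (`rep`, `veg_type`, `resource_share`,
#'   `nonresource_share`, `r2_total`, `n_selected`).
#' @export
bootstrap_match <- function(data, response, predictors, n_target = 237L,
                            n_reps = 100L, seed = 1L,
                            types = unique(data$veg_type)) {
  counts <- table(data$veg_type)[types]
  if (any(is.na(counts)) || any(counts < n_target)) {
    stop("n_target exceeds the plot count of: ",
      paste(types[is.na(counts) | counts < n_target], collapse = ", "),
      call. = FALSE
    )
  }
  set.seed(seed)
  fml <- stats::reformulate(predictors, response)
  rows <- vector("list", n_reps * length(types))
  k <- 0L
  for (r in seq_len(n_reps)) {
    for (ty in types) {
      sub <- data[data$veg_type == ty, , drop = FALSE]
      sub <- sub[sample.int(nrow(sub), n_target), , drop = FALSE]
      fit <- fit_drivers(fml, sub)
      k <- k + 1L
      rows[[k]] <- data.frame(
        rep = r, veg_type = ty,
        resource_share = fit$resource_share,
        nonresource_share = fit$nonresource_share,
        r2_total = fit$r2_total,
        n_selected = length(fit$selected),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_target") <- n_target
  attr(out, "seed") <- seed
  class(out) <- c("bootstrap_match", "data.frame")
  out
}

#' @export
summary.bootstrap_match <- function(object, ...) {
  agg <- stats::aggregate(
    cbind(resource_share, nonresource_share, r2_total) ~ veg_type,
    data = object, FUN = mean, na.action = stats::na.omit
  )
  agg
}

#' @export
print.bootstrap_match <- function(x, ...) {
  cat("Bootstrap size-matched attribution: n_target =",
      attr(x, "n_target"), ",", max(x$rep), "replicates\n")
  print(summary(x))
  invisible(x)
}
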