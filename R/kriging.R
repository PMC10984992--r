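#' Empirical semivariogram
#'
#' Bins half squared differences of all sample pairs by separation
#' distance.
#'
#' @param coords two-column coordinate matrix (x, y; planar).
#' @param values numeric sample values.
#' @param n_bins number of distance bins.
#' @param cutoff maximum separation considered (default: half the
#'   largest pairwise distance).
#' @return data frame with `dist` (bin centre), `gamma`, `n` (pair
#'   count); empty bins are dropped.
#' @export
empirical_variogram <- function(coords, values, n_bins = 15L,
                                cutoff = NULL) {
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  dz2 <- 0.5 * outer(values, values, "-")^2
  up <- upper.tri(d)
  h <- d[up]
  g <- dz2[up]
  if (is.null(cutoff)) cutoff <- max(h) / 2
  keep <- h <= cutoff & h > 0
  h <- h[keep]
  g <- g[keep]
  br <- seq(0, cutoff, length.out = n_bins + 1L)
  bin <- cut(h, br, include.lowest = TRUE)
  out <- data.frame(
    dist = as.numeric(tapply(h, bin, mean)),
    gamma = as.numeric(tapply(g, bin, mean)),
    n = as.integer(table(bin))
  )
  out[out$n > 0L & is.finite(out$dist), ]
}

#' Fit a variogram model
#'
#' Weighted least squares (weights = pair counts) fit of a spherical or
#' linear model with nugget to an empirical semivariogram.
#'
#' @param vg empirical variogram from [empirical_variogram()].
#' @param model `"spherical"` or `"linear"`.
#' @param nugget allow a nugget (TRUE) or pin it at zero.
#' @return list of class `variogram_model` with the model type and its
#'   parameters (`nugget`, and `psill`/`range` or `slope`).
#' @export
fit_variogram <- function(vg, model = c("spherical", "linear"),
                          nugget = TRUE) {
  model <- match.arg(model)
  w <- vg$n
  if (model == "linear") {
    # weighted least squares has a closed form here
    fit <- if (nugget) {
      stats::lm(gamma ~ dist, data = vg, weights = w)
    } else {
      stats::lm(gamma ~ 0 + dist, data = vg, weights = w)
    }
    cf <- stats::coef(fit)
    n0 <- if (nugget) max(cf[["(Intercept)"]], 0) else 0
    if (nugget && cf[["(Intercept)"]] < 0) {
      cf <- stats::coef(stats::lm(gamma ~ 0 + dist, data = vg, weights = w))
    }
    out <- list(model = "linear", nugget = n0,
                slope = max(cf[["dist"]], 1e-12))
  } else {
    obj <- function(par) {
      n0 <- if (nugget) par[1L] else 0
      ps <- par[if (nugget) 2L else 1L]
      rg <- par[if (nugget) 3L else 2L]
      sum(w * (variogram_value(
        list(model = "spherical", nugget = n0, psill = ps, range = rg),
        vg$dist
      ) - vg$gamma)^2)
    }
    par0 <- c(if (nugget) min(vg$gamma) / 2,
              max(vg$gamma), max(vg$dist) * 0.7)
    lower <- c(if (nugget) 0, 1e-12, 1e-12)
    opt <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lower)
    par <- if (nugget) opt$par else c(0, opt$par)
    out <- list(model = "spherical", nugget = par[1L],
                psill = par[2L], range = par[3L])
  }
  class(out) <- "variogram_model"
  out
}

#' @rdname fit_variogram
#' @param vm a `variogram_model`.
#' @param h distances at which to evaluate; `gamma(0) = 0` by definition
#'   (the nugget is a discontinuity at the origin).
#' @export
variogram_value <- function(vm, h) {
  g <- switch(vm$model,
    linear = vm$nugget + vm$slope * h,
    spherical = {
      hr <- pmin(h / vm$range, 1)
      vm$nugget + vm$psill * (1.5 * hr - 0.5 * hr^3)
    }
  )
  g[h == 0] <- 0
  g
}

#' Ordinary kriging of a sparse layer
#'
#' Solves the ordinary-kriging system (semivariogram form, unbiasedness
#' via a Lagrange multiplier) at each target location. Because
#' `gamma(0) = 0`, predictions at sample locations reproduce the sample
#' values exactly, the property the interpolation is chosen for.
#'
#' @param coords n x 2 matrix of sample coordinates (planar; for
#'   lon/lat at regional extent treat degrees as planar or project
#'   first).
#' @param values n sample values.
#' @param new_coords m x 2 matrix of prediction locations.
#' @param vgm optional fitted [fit_variogram()] model; fitted from the
#'   samples when NULL.
#' @param model,nugget passed to [fit_variogram()] when fitting here.
#' @return list with `pred` (length m), `var` (kriging variance,
#'   length m) and the `vgm` used.
#' @export
krige_layer <- function(coords, values, new_coords, vgm = NULL,
                        model = "spherical", nugget = TRUE) {
  coords <- as.matrix(coords)
  new_coords <- as.matrix(new_coords)
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  dup <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup) > 0L) {
    stop("duplicate sample locations (rows ",
      paste(apply(dup, 1L, paste, collapse = "/"), collapse = ", "),
      "); the kriging system is singular",
      call. = FALSE
    )
  }
  m <- nrow(new_coords)
  if (stats::sd(values) == 0) {
    # degenerate field: every location equals the constant, no
    # uncertainty
    return(list(pred = rep(values[1L], m), var = rep(0, m), vgm = NULL))
  }
  if (is.null(vgm)) {
    vgm <- fit_variogram(empirical_variogram(coords, values),
      model = model, nugget = nugget
    )
  }
  A <- rbind(
    cbind(variogram_value(vgm, d), 1),
    c(rep(1, n), 0)
  )
  d0 <- sqrt(outer(new_coords[, 1L], coords[, 1L], "-")^2 +
               outer(new_coords[, 2L], coords[, 2L], "-")^2)
  B <- rbind(t(variogram_value(vgm, d0)), rep(1, m))
  W <- solve(A, B)
  pred <- drop(crossprod(W[seq_len(n), , drop = FALSE], values))
  kvar <- pmax(colSums(W * B), 0)
  list(pred = pred, var = kvar, vgm = vgm)
}
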