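#' Oxygen and carbon dioxide partial pressure from elevation
#'
#' Isothermal barometric decay of total pressure times a fixed mixing
#' ratio: `p(z) = p0 * exp(-z / H) * m` with scale height `H` (default
#' 8000 m) and mixing ratios 0.20946 (O2) and 4.0e-4 (CO2). Strictly
#' decreasing in elevation.
#'
#' @param elevation elevation in m (vectorised).
#' @param sea_level_pressure total pressure at sea level, kPa (> 0).
#' @param scale_height barometric scale height in m (> 0).
#' @param mixing_ratio volume mixing ratio of the gas.
#' @return partial pressure in the units of `sea_level_pressure`.
#' @export
#' @examples
#' compute_po2(0) # 101.325 * 0.20946
#' compute_po2(5500) / compute_po2(0) # exp(-5500/8000)
compute_po2 <- function(elevation, sea_level_pressure = 101.325,
                        scale_height = 8000, mixing_ratio = 0.20946) {
  if (any(!is.finite(sea_level_pressure)) || any(sea_level_pressure <= 0)) {
    stop("sea-level pressure must be positive", call. = FALSE)
  }
  if (scale_height <= 0) stop("scale height must be positive", call. = FALSE)
  sea_level_pressure * exp(-elevation / scale_height) * mixing_ratio
}

#' @rdname compute_po2
#' @export
compute_pco2 <- function(elevation, sea_level_pressure = 101.325,
                         scale_height = 8000, mixing_ratio = 4.0e-4) {
  compute_po2(elevation, sea_level_pressure, scale_height, mixing_ratio)
}

# Per-type environmental regimes of the emulated plateau survey:
# geographic bands and driver means/SDs. Wetter, warmer, low-stress
# regimes for forests; arid, cold, windy, wide-diurnal-range regimes for
# deserts. Units: MAT degC, MAP/PET mm, SOC g/kg, TN g/kg, UR MJ m-2,
# Wind m/s.
default_regimes <- function() {
  list(
    forest = list(
      lat = c(27, 31), lon = c(94, 102), elev = c(1500, 3500),
      MAT = c(8, 2.5), MAP = c(900, 150), PET = c(850, 80),
      T_diurnal = c(9.5, 1.0), Wind = c(1.8, 0.5), pH = c(5.8, 0.4),
      SOC = c(30, 8), TN = c(2.5, 0.6), UR = c(5500, 400)
    ),
    shrubland = list(
      lat = c(28, 33), lon = c(92, 100), elev = c(2800, 4000),
      MAT = c(4, 2.0), MAP = c(600, 120), PET = c(800, 80),
      T_diurnal = c(11, 1.0), Wind = c(2.5, 0.6), pH = c(6.5, 0.4),
      SOC = c(25, 6), TN = c(2.0, 0.5), UR = c(6200, 400)
    ),
    meadow = list(
      lat = c(30, 36), lon = c(90, 102), elev = c(3500, 4800),
      MAT = c(0, 1.5), MAP = c(520, 90), PET = c(750, 70),
      T_diurnal = c(12.5, 1.2), Wind = c(3.2, 0.7), pH = c(7.0, 0.4),
      SOC = c(40, 10), TN = c(3.0, 0.8), UR = c(7000, 400)
    ),
    steppe = list(
      lat = c(29, 36), lon = c(82, 94), elev = c(4200, 5100),
      MAT = c(-2, 1.5), MAP = c(300, 70), PET = c(780, 70),
      T_diurnal = c(14, 1.2), Wind = c(4.2, 0.8), pH = c(8.0, 0.4),
      SOC = c(15, 5), TN = c(1.2, 0.4), UR = c(7600, 400)
    ),
    desert = list(
      lat = c(32, 39), lon = c(78, 92), elev = c(4300, 5400),
      MAT = c(-4, 1.5), MAP = c(90, 30), PET = c(820, 80),
      T_diurnal = c(16, 1.3), Wind = c(5.5, 1.0), pH = c(8.6, 0.3),
      SOC = c(5, 2), TN = c(0.5, 0.2), UR = c(8000, 400)
    )
  )
}

# Published per-type summary of the two directly generated metrics:
# mean and SD of Height-max (m) and of Height-var (the within-plot CV).
default_metric_targets <- function() {
  list(
    forest = list(height_max = c(23.48, 8.11), height_var = c(0.38, 0.13)),
    shrubland = list(height_max = c(1.23, 0.51), height_var = c(0.79, 0.18)),
    meadow = list(height_max = c(0.17, 0.11), height_var = c(0.75, 0.35)),
    steppe = list(height_max = c(0.16, 0.08), height_var = c(0.67, 0.31)),
    desert = list(height_max = c(0.17, 0.10), height_var = c(0.64, 0.32))
  )
}

# Signed fractions of metric variance attributed to each driver, per
# vegetation type. The sign gives the direction of the standardized
# slope; magnitudes are converted to slopes on the log-metric scale by
# sqrt(fraction * total log variance) in synthetic_config(). The
# scenario realises the favorable-to-extreme shift: the aridity index
# dominates the woody regimes, while the non-resource share of the
# decomposition rises monotonically through meadow and steppe to the
# desert regime, with regime gaps wide enough for the stepwise + LMG
# chain to resolve at the bootstrap sample size.
default_effect_fractions <- function() {
  list(
    forest = list(
      height_max = c(AI = 0.352, Wind = -0.051, MAT = 0.027, UR = -0.012),
      height_var = c(AI = 0.398, MAT = 0.099, Wind = -0.074, pH = -0.021)
    ),
    shrubland = list(
      height_max = c(AI = 0.603, Wind = -0.180, pH = -0.078),
      height_var = c(AI = 0.403, Wind = -0.135)
    ),
    meadow = list(
      height_max = c(
        PO2 = 0.10, Wind = -0.08, T_diurnal = -0.05,
        MAT = 0.10, AI = 0.08
      ),
      height_var = c(MAT = 0.30, Wind = -0.24, PO2 = 0.085, AI = 0.04)
    ),
    steppe = list(
      height_max = c(T_diurnal = -0.30, Wind = -0.08, AI = 0.07,
                     MAT = 0.02),
      height_var = c(
        MAT = 0.15, Wind = -0.21, PO2 = 0.07, T_diurnal = -0.04,
        AI = 0.02, SOC = 0.02
      )
    ),
    desert = list(
      height_max = c(T_diurnal = -0.205, Wind = -0.111),
      height_var = c(Wind = -0.174, UR = -0.151, T_diurnal = -0.091,
                     MAT = 0.029)
    )
  )
}

#' Configuration of the synthetic plateau survey
#'
#' Builds the scenario the generator draws from. The defaults are the
#' emulated study conditions: per-type plot counts (456 forests, 30
#' shrublands, 669 meadows, 621 steppes, 237 deserts, totalling 2013),
#' per-type Height-max and Height-var means/SDs, and per-driver variance
#' shares in which the aridity index dominates the woody regimes while
#' diurnal temperature range and wind dominate the alpine regimes.
#'
#' Effect sizes are standardized slopes on the log-scale metric (the log
#' of a plot's Height-max, or of its within-plot CV target) per standard
#' deviation of the driver; the default slopes are derived from the
#' configured variance shares. `noise_sd` is the residual SD on that same
#' log scale (default: whatever the targets leave unexplained).
#'
#' @param n_plots named integer vector of plots per vegetation type.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param effects named list `type -> metric -> named slopes`, overriding
#'   the default slopes for the types/metrics it names. Driver names must
#'   come from [vsc_variables()].
#' @param noise_sd optional residual SD override: a single number applied
#'   everywhere, or a list `type -> metric -> sd`.
#' @param grid_shape rows x cols of the synthetic raster domain.
#' @param lambda_species Poisson mean of grassland species richness
#'   (min 1 species; 3 individuals measured per species).
#' @param lambda_trees named Poisson means of woody stem counts per plot.
#' @param regimes,metric_targets advanced overrides of the per-type
#'   environmental regimes and metric summaries.
#' @return A `vsc_config` list.
#' @export
#' @examples
#' cfg <- synthetic_config(n_plots = c(meadow = 20, desert = 10), seed = 7)
synthetic_config <- function(n_plots = c(
                               forest = 456, shrubland = 30, meadow = 669,
                               steppe = 621, desert = 237
                             ),
                             seed = 1L,
                             effects = NULL,
                             noise_sd = NULL,
                             grid_shape = c(40L, 40L),
                             lambda_species = 8,
                             lambda_trees = c(forest = 38, shrubland = 11),
                             regimes = default_regimes(),
                             metric_targets = default_metric_targets()) {
  check_veg_type(names(n_plots))
  if (any(n_plots <= 0)) stop("plot counts must be > 0", call. = FALSE)
  if (any(grid_shape <= 0)) stop("grid_shape must be positive", call. = FALSE)
  types <- names(n_plots)

  fractions <- default_effect_fractions()
  slopes <- list()
  noise <- list()
  for (ty in types) {
    for (m in c("height_max", "height_var")) {
      tg <- metric_targets[[ty]][[m]]
      v <- log(1 + (tg[2L] / tg[1L])^2) # total log-scale variance
      fr <- fractions[[ty]][[m]]
      slopes[[ty]][[m]] <- sign(fr) * sqrt(abs(fr) * v)
      noise[[ty]][[m]] <- sqrt(max(v * (1 - sum(abs(fr))), 1e-8))
    }
  }
  if (!is.null(effects)) {
    for (ty in names(effects)) {
      check_veg_type(ty)
      for (m in names(effects[[ty]])) {
        e <- effects[[ty]][[m]]
        bad <- setdiff(names(e), vsc_variables()$name)
        if (length(bad) > 0L) {
          stop("effect-size keys not among the 13 drivers: ",
            paste(bad, collapse = ", "),
            call. = FALSE
          )
        }
        slopes[[ty]][[m]] <- e
      }
    }
  }
  if (!is.null(noise_sd)) {
    if (is.numeric(noise_sd) && length(noise_sd) == 1L) {
      if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
      for (ty in types) for (m in names(noise[[ty]])) noise[[ty]][[m]] <- noise_sd
    } else {
      for (ty in names(noise_sd)) {
        for (m in names(noise_sd[[ty]])) {
          if (noise_sd[[ty]][[m]] < 0) stop("noise_sd must be >= 0", call. = FALSE)
          noise[[ty]][[m]] <- noise_sd[[ty]][[m]]
        }
      }
    }
  }

  structure(
    list(
      n_plots = n_plots, seed = as.integer(seed), effects = slopes,
      noise_sd = noise, grid_shape = as.integer(grid_shape),
      lambda_species = lambda_species, lambda_trees = lambda_trees,
      regimes = regimes, metric_targets = metric_targets
    ),
    class = "vsc_config"
  )
}

# draw the per-plot environment table for one vegetation type
gen_env_type <- function(type, n, rg) {
  rn <- function(p) stats::rnorm(n, p[1L], p[2L])
  ru <- function(p) stats::runif(n, p[1L], p[2L])
  env <- data.frame(
    plot_id = sprintf("%s_%04d", type, seq_len(n)),
    veg_type = type,
    lat = ru(rg$lat), lon = ru(rg$lon), elev_m = ru(rg$elev),
    stringsAsFactors = FALSE
  )
  env$MAT <- rn(rg$MAT)
  env$MAP <- pmax(rn(rg$MAP), 5)
  env$PET <- pmax(rn(rg$PET), 100)
  env$AI <- env$MAP / env$PET
  env$pH <- rn(rg$pH)
  env$SOC <- pmax(rn(rg$SOC), 0.1)
  env$TN <- pmax(rn(rg$TN), 0.02)
  env$T_coldest <- 0.9 * env$MAT - 17 + stats::rnorm(n, 0, 1.5)
  env$T_diurnal <- rn(rg$T_diurnal)
  env$T_annual <- 26 - 1.1 * env$MAT + stats::rnorm(n, 0, 2)
  env$PO2 <- compute_po2(env$elev_m)
  env$PCO2 <- compute_pco2(env$elev_m)
  env$UR <- rn(rg$UR)
  env$Wind <- pmax(rn(rg$Wind), 0.1)
  env
}

# Height adjustment: preserve plant order and the tallest plant's height
# while making the plot's sample CV equal its target, so the true metrics
# follow the configured linear model. The power map h' = hmax*(h/hmax)^g
# keeps heights positive for any g > 0 and its CV is monotone in g; g is
# solved by bisection. Plots whose draws cannot reach the target within
# g in [0.05, 12] keep the closest endpoint.
match_cv <- function(h, hmax, cv_t) {
  if (length(h) < 2L || stats::sd(h) == 0) return(h)
  cv_of <- function(g) {
    hh <- hmax * (h / hmax)^g
    stats::sd(hh) / mean(hh)
  }
  lo <- 0.05
  hi <- 12
  if (cv_t <= cv_of(lo)) return(hmax * (h / hmax)^lo)
  if (cv_t >= cv_of(hi)) return(hmax * (h / hmax)^hi)
  g <- stats::uniroot(function(g) cv_of(g) - cv_t, c(lo, hi),
                      tol = 1e-8)$root
  hmax * (h / hmax)^g
}

# linear predictor sum(beta_j * z(driver_j)) on the standardized drivers
linpred <- function(env, slopes) {
  eta <- numeric(nrow(env))
  for (v in names(slopes)) {
    x <- env[[v]]
    s <- stats::sd(x)
    z <- if (s > 0) (x - mean(x)) / s else rep(0, length(x))
    eta <- eta + slopes[[v]] * z
  }
  eta
}

#' Generate a synthetic plot survey
#'
#' Draws, for each vegetation type, per-plot environments from the
#' configured regime, plot-level true metrics from the configured linear
#' models (log Height-max and log CV-target = intercept + sum of
#' standardized effects + Gaussian noise), and individual plants whose
#' heights are log-normal within the plot, rescaled so the tallest plant
#' realises the plot's Height-max exactly. Grassland species carry a
#' Dirichlet coverage vector (3 measured individuals per species); woody
#' plants carry an allometric DBH/basal diameter.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `vsc_plots`: a list with elements `plants`
#'   (one row per measured plant, plot-table schema) and `env` (one row
#'   per plot, the 13 drivers plus coordinates), plus the config.
#' @export
generate_plots <- function(config) {
  stopifnot(inherits(config, "vsc_config"))
  set.seed(config$seed)
  types <- names(config$n_plots)
  env_all <- list()
  plants_all <- list()
  for (ty in types) {
    n <- config$n_plots[[ty]]
    env <- gen_env_type(ty, n, config$regimes[[ty]])

    tg <- config$metric_targets[[ty]]
    b_max <- config$effects[[ty]]$height_max
    b_var <- config$effects[[ty]]$height_var
    v_max <- sum(b_max^2) + config$noise_sd[[ty]]$height_max^2
    v_var <- sum(b_var^2) + config$noise_sd[[ty]]$height_var^2
    log_hmax <- log(tg$height_max[1L]) - v_max / 2 + linpred(env, b_max) +
      stats::rnorm(n, 0, config$noise_sd[[ty]]$height_max)
    log_cv <- log(tg$height_var[1L]) - v_var / 2 + linpred(env, b_var) +
      stats::rnorm(n, 0, config$noise_sd[[ty]]$height_var)
    hmax <- exp(log_hmax)
    cv <- pmin(pmax(exp(log_cv), 0.02), 2.5)

    woody <- ty %in% woody_types()
    plants <- vector("list", n)
    for (i in seq_len(n)) {
      if (woody) {
        np <- max(2L, stats::rpois(1L, config$lambda_trees[[ty]]))
        s0 <- sqrt(log(1 + cv[i]^2))
        h <- exp(stats::rnorm(np, 0, s0))
        h <- match_cv(h * hmax[i] / max(h), hmax[i], cv[i])
        d <- if (ty == "forest") {
          pmax(3.05, 1.2 * h^1.05 * exp(stats::rnorm(np, 0, 0.15)))
        } else {
          pmax(0.2, 1.0 * h^0.9 * exp(stats::rnorm(np, 0, 0.2)))
        }
        plants[[i]] <- data.frame(
          plot_id = env$plot_id[i], veg_type = ty,
          species = sample(sprintf("%s_sp%02d", ty, 1:20), np, replace = TRUE),
          height_m = h, coverage_frac = NA_real_, dbh_cm = d,
          lat = env$lat[i], lon = env$lon[i], elev_m = env$elev_m[i],
          stringsAsFactors = FALSE
        )
      } else {
        ns <- max(1L, stats::rpois(1L, config$lambda_species))
        s0 <- sqrt(max(log(1 + cv[i]^2) - 0.01, 1e-4))
        mh <- exp(stats::rnorm(ns, 0, s0))
        h <- rep(mh, each = 3L) * exp(stats::rnorm(3L * ns, 0, 0.1))
        h <- match_cv(h * hmax[i] / max(h), hmax[i], cv[i])
        cover <- stats::rgamma(ns, 1)
        cover <- cover / sum(cover)
        plants[[i]] <- data.frame(
          plot_id = env$plot_id[i], veg_type = ty,
          species = rep(sprintf("%s_sp%02d", ty, seq_len(ns)), each = 3L),
          height_m = h, coverage_frac = rep(cover, each = 3L),
          dbh_cm = NA_real_,
          lat = env$lat[i], lon = env$lon[i], elev_m = env$elev_m[i],
          stringsAsFactors = FALSE
        )
      }
    }
    env_all[[ty]] <- env
    plants_all[[ty]] <- do.call(rbind, plants)
  }
  out <- list(
    plants = do.call(rbind, plants_all),
    env = do.call(rbind, env_all),
    config = config
  )
  rownames(out$plants) <- rownames(out$env) <- NULL
  class(out) <- "vsc_plots"
  out
}

#' @export
print.vsc_plots <- function(x, ...) {
  cat("Synthetic plot survey:", nrow(x$env), "plots,",
      nrow(x$plants), "plants\n")
  print(table(x$env$veg_type))
  invisible(x)
}

#' Generate gridded predictor layers
#'
#' Builds one spatially smooth layer per driver over a regular
#' lon/lat grid covering the union of the configured regimes. Directly
#' generated layers are low-frequency sinusoidal gradients scaled into
#' the pooled plot-level range of the variable and carry a
#' `"gradient_bound"` attribute (an upper bound on the adjacent-cell
#' difference). AI is derived as MAP/PET, and PO2/PCO2 from the elevation
#' surface, so the layer set respects the same structural identities as
#' the plots. A rectangular block of cells is masked (NA) to emulate
#' unmapped water/ice.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `raster_stack`: `layers` (named list of
#'   matrices, row 1 = northernmost row), `lat`/`lon` cell-centre
#'   coordinates, `elevation` surface, and logical `mask` (TRUE =
#'   masked).
#' @export
generate_raster <- function(config) {
  stopifnot(inherits(config, "vsc_config"))
  set.seed(config$seed)
  nr <- config$grid_shape[1L]
  nc <- config$grid_shape[2L]
  rgs <- config$regimes[names(config$n_plots)]
  rng <- function(field) {
    lo <- min(vapply(rgs, function(r) r[[field]][1L] - 2.5 * r[[field]][2L], 0))
    hi <- max(vapply(rgs, function(r) r[[field]][1L] + 2.5 * r[[field]][2L], 0))
    c(lo, hi)
  }
  lat_r <- range(unlist(lapply(rgs, `[[`, "lat")))
  lon_r <- range(unlist(lapply(rgs, `[[`, "lon")))
  elev_r <- range(unlist(lapply(rgs, `[[`, "elev")))
  lat <- seq(lat_r[2L], lat_r[1L], length.out = nr) # row 1 = north
  lon <- seq(lon_r[1L], lon_r[2L], length.out = nc)

  cx <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
  ry <- matrix(rep(seq_len(nr) / nr, nc), nr, nc)
  smooth_layer <- function(lo, hi) {
    fx <- stats::runif(1L, 0.4, 1.2)
    fy <- stats::runif(1L, 0.4, 1.2)
    phi <- stats::runif(1L, 0, 2 * pi)
    s <- 0.5 + 0.5 * sin(2 * pi * (fx * cx + fy * ry) + phi)
    m <- lo + (hi - lo) * s
    attr(m, "gradient_bound") <- (hi - lo) * pi * (fx / nc + fy / nr)
    m
  }

  elev <- smooth_layer(elev_r[1L], elev_r[2L])
  direct <- c("MAT", "MAP", "pH", "SOC", "TN", "T_coldest", "T_diurnal",
              "T_annual", "UR", "Wind")
  layers <- list()
  for (v in direct) {
    r <- switch(v,
      T_coldest = rng("MAT") - 17,
      T_annual = rev(26 - 1.1 * rng("MAT")),
      rng(v)
    )
    layers[[v]] <- smooth_layer(r[1L], r[2L])
  }
  pet <- smooth_layer(rng("PET")[1L], rng("PET")[2L])
  layers$MAP[] <- pmax(layers$MAP, 5)
  pet[] <- pmax(pet, 100)
  layers$AI <- layers$MAP / pet
  layers$PO2 <- compute_po2(elev)
  layers$PCO2 <- compute_pco2(elev)
  layers <- layers[vsc_variables()$name]

  mask <- matrix(FALSE, nr, nc)
  if (nr >= 4L && nc >= 4L) {
    r0 <- sample.int(nr - 2L, 1L)
    c0 <- sample.int(nc - 2L, 1L)
    mask[r0:min(nr, r0 + max(1L, nr %/% 10L)),
         c0:min(nc, c0 + max(1L, nc %/% 10L))] <- TRUE
  }
  layers <- lapply(layers, function(m) {
    m[mask] <- NA_real_
    m
  })

  structure(
    list(layers = layers, lat = lat, lon = lon, elevation = elev,
         mask = mask,
         cell_size = c(
           if (nr > 1L) abs(diff(lat[1:2])) else diff(lat_r),
           if (nc > 1L) abs(diff(lon[1:2])) else diff(lon_r)
         )),
    class = "raster_stack"
  )
}

#' @export
print.raster_stack <- function(x, ...) {
  cat("raster_stack:", length(x$layers), "layers,",
      length(x$lat), "x", length(x$lon), "cells,",
      sum(x$mask), "masked\n")
  invisible(x)
}
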