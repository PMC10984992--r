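test_that("kriging is exact at sample locations and handles degenerate fields", {
  set.seed(20)
  n <- 30
  coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  vals <- sin(coords[, 1] / 3) + 0.3 * coords[, 2] + rnorm(n, 0, 0.05)
  kr <- krige_layer(coords, vals, coords)
  expect_lt(max(abs(kr$pred - vals)), 1e-6)
  expect_true(all(kr$var >= 0))
  # constant samples: constant layer, zero kriging variance
  kc <- krige_layer(coords, rep(4.2, n), cbind(c(1, 5), c(2, 8)))
  expect_equal(kc$pred, c(4.2, 4.2))
  expect_equal(kc$var, c(0, 0))
  # duplicate locations are refused
  expect_error(
    krige_layer(rbind(coords, coords[1, ]), c(vals, 1), coords),
    "duplicate"
  )
  expect_error(krige_layer(coords[1:2, ], vals[1:2], coords), "at least 3")
})

test_that("two-sample midpoint under a linear variogram is the arithmetic mean", {
  # hand solution of the 2-point ordinary-kriging system: equal distances
  # to both samples -> weights 1/2, 1/2 (any no-nugget linear variogram)
  vgm <- structure(list(model = "linear", nugget = 0, slope = 0.7),
                   class = "variogram_model")
  coords <- rbind(c(0, 0), c(4, 0), c(2, 3))
  kr <- krige_layer(coords, c(10, 20, 15), rbind(c(2, 0)), vgm = vgm)
  expect_equal(kr$pred, 15, tolerance = 1e-9)
  # degenerate further: only the two ends (padded with a third far point
  # that is equidistant, keeping symmetry) — direct 2-point check
  A <- rbind(c(0, 0.7 * 4, 1), c(0.7 * 4, 0, 1), c(1, 1, 0))
  b <- c(0.7 * 2, 0.7 * 2, 1)
  w <- solve(A, b)
  expect_equal(w[1:2], c(0.5, 0.5), tolerance = 1e-12)
})

test_that("variogram fitting recovers a known linear structure", {
  set.seed(21)
  vg <- data.frame(dist = 1:10, gamma = 0.5 * (1:10), n = rep(50, 10))
  fit <- fit_variogram(vg, model = "linear", nugget = FALSE)
  expect_equal(fit$slope, 0.5, tolerance = 1e-4)
  expect_equal(fit$nugget, 0)
  # spherical fit reproduces its own curve
  vm <- structure(list(model = "spherical", nugget = 0.1, psill = 1,
                       range = 6), class = "variogram_model")
  vg2 <- data.frame(dist = seq(0.5, 9.5, 0.5))
  vg2$gamma <- variogram_value(vm, vg2$dist)
  vg2$n <- 40
  fit2 <- fit_variogram(vg2, model = "spherical")
  expect_equal(variogram_value(fit2, vg2$dist), vg2$gamma, tolerance = 1e-3)
  expect_equal(variogram_value(vm, 0), 0) # gamma(0) = 0 despite the nugget
})

test_that("train/test split follows the 75/25 convention", {
  sp <- train_test_split(2013, 0.75, seed = 1)
  expect_equal(length(sp$train), 1509)
  expect_equal(length(sp$test), 504)
  expect_equal(sort(c(sp$train, sp$test)), 1:2013)
  # same seed, same split
  expect_identical(sp, train_test_split(2013, 0.75, seed = 1))
})

test_that("random forest upscaling separates signal from noise", {
  cfg <- synthetic_config(
    n_plots = c(steppe = 400), seed = 22,
    effects = list(steppe = list(height_max = c(AI = 0.6))),
    noise_sd = list(steppe = list(height_max = 0))
  )
  pl <- generate_plots(cfg)
  vsc <- compute_vsc(pl$plants)
  rep_s <- fit_rf(vsc, pl$env, responses = "height_max", split_seed = 1,
                  ntree = 300)
  expect_gte(rep_s$validation_r2[["height_max"]], 0.95)
  expect_true(all(rep_s$importance$height_max >= 0))
  expect_equal(names(rep_s$importance$height_max)[1L], "AI")
  # pure-noise response: hold-out R2 near zero
  vsc_noise <- vsc
  set.seed(23)
  vsc_noise$height_max <- exp(rnorm(nrow(vsc_noise)))
  rep_n <- fit_rf(vsc_noise, pl$env, responses = "height_max",
                  split_seed = 1, ntree = 300)
  expect_lte(rep_n$validation_r2[["height_max"]], 0.1)
  # fixed seed: invariant to row order of the input tables
  shuf <- sample(nrow(vsc))
  rep_p <- fit_rf(vsc[shuf, ], pl$env, responses = "height_max",
                  split_seed = 1, ntree = 300)
  expect_equal(rep_p$validation_r2, rep_s$validation_r2)
})

test_that("map prediction equals per-cell prediction and propagates the mask", {
  cfg <- synthetic_config(n_plots = c(meadow = 120, desert = 60), seed = 24,
                          grid_shape = c(6L, 6L))
  pl <- generate_plots(cfg)
  vsc <- compute_vsc(pl$plants)
  rs <- generate_raster(cfg)
  rep_m <- fit_rf(vsc, pl$env, responses = c("height_max", "height_even"),
                  split_seed = 2, ntree = 200, min_train = 20)
  maps <- predict_map(rep_m, rs)
  expect_s3_class(maps, "raster_stack")
  # per-cell oracle: loop single-cell predictions
  vars <- rep_m$predictors
  for (i in c(1, 7, 23)) {
    row <- ((i - 1) %% 6) + 1
    col <- ((i - 1) %/% 6) + 1
    cell <- as.data.frame(lapply(rs$layers[vars], function(m) m[row, col]))
    if (any(is.na(cell))) {
      expect_true(is.na(maps$layers$height_max[row, col]))
    } else {
      p <- predict(rep_m$models$height_max, cell)
      expect_equal(maps$layers$height_max[row, col], unname(10^p))
    }
  }
  # masked cells are NA in the output
  expect_true(all(is.na(maps$layers$height_max[rs$mask])))
  # predictions bounded by the training-response range (mean aggregation)
  tr <- log10(vsc$height_max[order(vsc$plot_id)][rep_m$train])
  rng <- range(10^tr)
  expect_gte(min(maps$layers$height_max, na.rm = TRUE), rng[1] - 1e-9)
  expect_lte(max(maps$layers$height_max, na.rm = TRUE), rng[2] + 1e-9)
  # constant raster: constant map equal to the single-point prediction
  rs2 <- rs
  rs2$layers <- lapply(rs$layers, function(m) {
    m[] <- mean(m, na.rm = TRUE)
    m
  })
  rs2$mask[] <- FALSE
  maps2 <- predict_map(rep_m, rs2)
  expect_equal(length(unique(round(as.vector(maps2$layers$height_even), 10))),
               1L)
  # a missing layer is named in the error
  rs3 <- rs
  rs3$layers$Wind <- NULL
  expect_error(predict_map(rep_m, rs3), "Wind")
})

test_that("observed-vs-predicted reports the squared Pearson correlation", {
  rep_fake <- list(
    observed = list(height_max = c(1, 2, 3, 4, 5)),
    predicted = list(height_max = c(1.1, 1.9, 3.3, 3.6, 5.2)),
    responses = "height_max"
  )
  tab <- observed_vs_predicted(rep_fake)
  expect_equal(attr(tab, "r2"),
               cor(tab$observed, tab$predicted)^2)
  # identical predictions give R2 = 1
  rep_id <- list(observed = list(m = 1:10), predicted = list(m = 1:10),
                 responses = "m")
  expect_equal(attr(observed_vs_predicted(rep_id, "m"), "r2"), 1)
})

test_that("kriged predictor layers reproduce plot samples on the grid", {
  cfg <- synthetic_config(n_plots = c(steppe = 40), seed = 25,
                          grid_shape = c(8L, 8L))
  pl <- generate_plots(cfg)
  rs <- generate_raster(cfg)
  rs2 <- krige_to_raster(rs, pl$env, vars = "SOC")
  expect_false(identical(rs2$layers$SOC, rs$layers$SOC))
  expect_true(all(is.na(rs2$layers$SOC[rs2$mask])))
  # interpolated surface stays within a sane envelope of the samples
  rng <- range(pl$env$SOC)
  spread <- diff(rng)
  expect_gte(min(rs2$layers$SOC, na.rm = TRUE), rng[1] - spread)
  expect_lte(max(rs2$layers$SOC, na.rm = TRUE), rng[2] + spread)
})
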