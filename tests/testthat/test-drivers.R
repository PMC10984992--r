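test_that("screening drops perfectly collinear partners and spares orthogonal tables", {
  set.seed(1)
  n <- 300
  vars <- vsc_variables()$name
  env <- as.data.frame(stats::setNames(
    lapply(vars, function(v) rnorm(n)), vars
  ))
  # orthogonal (independent) predictors: nothing dropped
  sr <- screen_variables(env)
  expect_equal(sort(sr$kept), sort(vars))
  expect_equal(nrow(sr$dropped), 0L)
  # PCO2 proportional to PO2: rule (i)
  env2 <- env
  env2$PCO2 <- 1.9e-3 * env2$PO2
  sr2 <- screen_variables(env2)
  expect_false("PCO2" %in% sr2$kept)
  expect_true("PO2" %in% sr2$kept)
  # constant column is an error naming the column
  env3 <- env
  env3$Wind <- 2
  expect_error(screen_variables(env3), "Wind")
})

test_that("LMG shares equal marginal R2 for orthogonal predictors and split duplicates evenly", {
  set.seed(2)
  n <- 4000
  x1 <- rnorm(n)
  x2 <- residuals(lm(rnorm(n) ~ x1)) # exactly orthogonal in sample
  x2 <- x2 / sd(x2)
  y <- sqrt(0.3) * x1 + sqrt(0.2) * x2 + sqrt(0.5) * rnorm(n)
  li <- lmg_importance(y, data.frame(x1 = x1, x2 = x2))
  r2_marg <- c(cor(y, x1)^2, cor(y, x2)^2)
  expect_equal(unname(li), r2_marg, tolerance = 1e-10)
  expect_equal(unname(li), c(0.3, 0.2), tolerance = 0.05)
  # duplicated predictor: perfect symmetry, each half the model R2
  li2 <- lmg_importance(y, data.frame(a = x1, b = x1))
  expect_equal(li2[["a"]], li2[["b"]])
  expect_equal(sum(li2), cor(y, x1)^2, tolerance = 1e-10)
})

test_that("LMG equals the brute-force average over all orderings", {
  set.seed(3)
  n <- 60
  z <- rnorm(n)
  x <- data.frame(
    a = z + rnorm(n, 0, 0.7),
    b = -0.5 * z + rnorm(n, 0, 0.9),
    c = rnorm(n)
  )
  y <- 1.2 * x$a + 0.8 * x$b - 0.5 * x$c + rnorm(n)
  # oracle: explicit enumeration of the 6 orderings of sequential R2
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    summary(lm(y ~ ., data = x[, cols, drop = FALSE]))$r.squared
  }
  perms <- list(
    c("a", "b", "c"), c("a", "c", "b"), c("b", "a", "c"),
    c("b", "c", "a"), c("c", "a", "b"), c("c", "b", "a")
  )
  oracle <- c(a = 0, b = 0, c = 0)
  for (p in perms) {
    for (i in seq_along(p)) {
      oracle[p[i]] <- oracle[p[i]] + (r2(p[1:i]) - r2(p[seq_len(i - 1)])) / 6
    }
  }
  li <- lmg_importance(y, x)
  expect_equal(li, oracle, tolerance = 1e-10)
  expect_equal(sum(li), r2(c("a", "b", "c")), tolerance = 1e-12)
  # the sequential alternative reproduces one ordering's increments
  si <- seq_importance(y, x[, c("a", "b", "c")])
  expect_equal(unname(cumsum(si)),
               c(r2("a"), r2(c("a", "b")), r2(c("a", "b", "c"))),
               tolerance = 1e-12)
  expect_error(lmg_importance(y, matrix(rnorm(n * 13), n)), "12 predictors")
})

test_that("VIFs match brute-force auxiliary regressions", {
  set.seed(4)
  n <- 200
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  x$c <- 0.6 * x$a - 0.5 * x$b + 0.4 * x$c
  v <- vif_values(x)
  oracle <- vapply(names(x), function(j) {
    1 / (1 - summary(lm(reformulate(setdiff(names(x), j), j), x))$r.squared)
  }, 0)
  expect_equal(v, oracle, tolerance = 1e-10)
  expect_true(all(v >= 1))
  # independent cross-check against car
  fit <- lm(rnorm(n) ~ a + b + c, data = x)
  expect_equal(unname(v), unname(car::vif(fit)), tolerance = 1e-10)
  # orthogonal pair near 1; near-duplicate far above 10
  o <- vif_values(data.frame(a = x$a, b = x$b))
  expect_equal(unname(o), c(1, 1), tolerance = 0.1)
  d <- vif_values(data.frame(a = x$a, b = x$a + rnorm(n, 0, 1e-3)))
  expect_gt(min(d), 10)
  expect_true(is.na(vif_values(x[, "a", drop = FALSE])[[1L]]))
})

test_that("stepwise selection keeps signal and discards noise", {
  # pure noise: an AIC search retains each null predictor with
  # probability ~ P(chisq_1 > 2) ~ 0.16, so on average under one of the
  # five survives and the majority are always dropped; simulation
  # oracle at n = 500
  set.seed(10)
  picks <- vapply(1:20, function(i) {
    d <- as.data.frame(matrix(rnorm(500 * 6), 500))
    names(d) <- c("y", paste0("x", 1:5))
    fit <- fit_drivers(y ~ x1 + x2 + x3 + x4 + x5, d)
    length(fit$selected)
  }, 0L)
  expect_lte(mean(picks), 5 * 0.157 + 3 * sqrt(5 * 0.157 * 0.843 / 20))
  expect_gte(mean(picks == 0L), 0.2)
  # agreement with a direct stepAIC call on one replicate
  set.seed(10)
  d <- as.data.frame(matrix(rnorm(500 * 6), 500))
  names(d) <- c("y", paste0("x", 1:5))
  direct <- MASS::stepAIC(lm(y ~ ., d), direction = "both", trace = 0)
  fit <- fit_drivers(y ~ x1 + x2 + x3 + x4 + x5, d)
  expect_setequal(fit$selected, attr(terms(direct), "term.labels"))
  # a strong predictor (R2 ~ 0.6) is always retained
  set.seed(11)
  kept <- vapply(1:10, function(i) {
    n <- 300
    d <- data.frame(
      x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n)
    )
    d$y <- sqrt(0.6) * d$x1 + sqrt(0.4) * rnorm(n)
    fit <- fit_drivers(y ~ x1 + x2 + x3 + x4, d)
    "x1" %in% fit$selected
  }, TRUE)
  expect_true(all(kept))
  # an already-minimal strong model is returned unchanged
  set.seed(12)
  d <- data.frame(x1 = rnorm(100))
  d$y <- 2 * d$x1 + rnorm(100, 0, 0.5)
  fit <- fit_drivers(y ~ x1, d)
  expect_equal(fit$selected, "x1")
  # rank-deficient designs are refused with the aliased column named
  d$x2 <- d$x1
  expect_error(fit_drivers(y ~ x1 + x2, d), "x2")
})

test_that("driver_model invariants hold and methods work", {
  set.seed(13)
  n <- 250
  d <- data.frame(
    MAT = rnorm(n), AI = rnorm(n), Wind = rnorm(n), T_diurnal = rnorm(n)
  )
  d$height_max <- 0.8 * d$AI - 0.4 * d$Wind + rnorm(n, 0, 0.6)
  fit <- fit_drivers(height_max ~ MAT + AI + Wind + T_diurnal, d,
                     coords = cbind(runif(n, 80, 100), runif(n, 28, 38)))
  # LMG shares sum to the model R2 to machine precision
  expect_equal(sum(fit$r2_by_var), fit$r2_total, tolerance = 1e-12)
  expect_true(all(fit$r2_by_var >= 0))
  expect_equal(fit$resource_share + fit$nonresource_share, 100,
               tolerance = 1e-9)
  # dropping a predictor never increases R2
  sub <- summary(lm(height_max ~ AI, d))$r.squared
  expect_lte(sub, summary(fit$fit)$r.squared + 1e-12)
  # methods
  expect_s3_class(fit, "driver_model")
  expect_named(coef(fit))
  expect_equal(length(residuals(fit)), n)
  expect_equal(unname(predict(fit, d[1:5, ])),
               unname(predict(fit$fit, d[1:5, ])))
  expect_output(print(fit), "relative importance")
  expect_output(print(summary(fit)), "significant")
  expect_false(is.null(fit$residual_moran))
})

test_that("resource_split classifies by the registry and totals 100", {
  expect_equal(
    resource_split(c(AI = 0.4)),
    c(resource = 100, nonresource = 0)
  )
  expect_equal(
    resource_split(c(Wind = 0.2, T_diurnal = 0.3)),
    c(resource = 0, nonresource = 100)
  )
  s <- resource_split(c(AI = 0.3, Wind = 0.1))
  expect_equal(unname(s), c(75, 25))
  expect_error(resource_split(c(foo = 1)), "unclassified")
})

test_that("bootstrap matching reproduces the unresampled split at full size", {
  set.seed(14)
  n <- 80
  d <- data.frame(
    veg_type = "steppe",
    AI = rnorm(n), Wind = rnorm(n), T_diurnal = rnorm(n)
  )
  d$height_max <- 0.7 * d$T_diurnal + 0.3 * d$AI + rnorm(n, 0, 0.5)
  bm <- bootstrap_match(d, "height_max", c("AI", "Wind", "T_diurnal"),
                        n_target = n, n_reps = 1, seed = 5)
  direct <- fit_drivers(height_max ~ AI + Wind + T_diurnal, d)
  expect_equal(bm$resource_share, direct$resource_share, tolerance = 1e-9)
  # fixed seed: identical draws
  b1 <- bootstrap_match(d, "height_max", c("AI", "Wind", "T_diurnal"),
                        n_target = 40, n_reps = 3, seed = 6)
  b2 <- bootstrap_match(d, "height_max", c("AI", "Wind", "T_diurnal"),
                        n_target = 40, n_reps = 3, seed = 6)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_error(
    bootstrap_match(d, "height_max", "AI", n_target = n + 1, n_reps = 1),
    "exceeds"
  )
})

test_that("partial correlation matches the closed form and its edge cases", {
  # 5-point numeric toy against the textbook formula
  x <- c(1.2, 0.4, -0.8, 2.1, -1.5)
  y <- c(0.9, 0.1, -1.1, 1.4, -0.7)
  z <- c(0.3, -0.2, -0.9, 1.8, -1.0)
  pc <- partial_correlation(x, y, z)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  expect_equal(pc$zero_order, rxy)
  expect_equal(pc$partial,
               (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)))
  # residual-regression route gives the same number
  rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
  expect_equal(pc$partial, cor(rx, ry), tolerance = 1e-12)
  # control independent of both: partial ~ zero-order at large n
  set.seed(15)
  n <- 1e4
  a <- rnorm(n); b <- 0.5 * a + rnorm(n); cc <- rnorm(n)
  pc2 <- partial_correlation(a, b, cc)
  expect_lt(abs(pc2$partial - pc2$zero_order), 0.02)
  # y equal to the control: undefined, reported NA
  expect_warning(pc3 <- partial_correlation(a, cc, cc), "undefined")
  expect_true(is.na(pc3$partial))
  expect_error(partial_correlation(a, b, rep(1, n)), "constant")
})

test_that("Moran's I matches hand evaluation and the permutation null", {
  # 2x2 rook-weighted checkerboard: exactly -1
  w <- matrix(0, 4, 4)
  w[1, c(2, 3)] <- 1; w[2, c(1, 4)] <- 1
  w[3, c(1, 4)] <- 1; w[4, c(2, 3)] <- 1
  m <- morans_i(c(1, -1, -1, 1), weights = w)
  expect_equal(m$observed, -1)
  expect_equal(m$expected, -1 / 3)
  # permutation null: mean over 1000 permutations within 3 SE of -1/(n-1)
  set.seed(16)
  n <- 30
  coords <- cbind(runif(n, 85, 95), runif(n, 28, 36))
  wm <- spatial_weights(coords)
  vals <- rnorm(n)
  perm <- vapply(1:1000, function(i) {
    morans_i(sample(vals), weights = wm)$observed
  }, 0)
  se <- sd(perm) / sqrt(length(perm))
  expect_lt(abs(mean(perm) - (-1 / (n - 1))), 3 * se)
  # smooth gradient: strongly positive
  g <- coords[, 1] + coords[, 2]
  expect_gt(morans_i(g, weights = wm)$observed, 0.2)
  # agreement with the independent implementation in ape
  av <- ape::Moran.I(vals, wm)
  expect_equal(morans_i(vals, weights = wm)$observed, av$observed,
               tolerance = 1e-12)
  expect_error(morans_i(rep(1, n), weights = wm), "constant")
  expect_error(morans_i(c(1, 2), weights = w[1:2, 1:2]), "at least 3")
})

test_that("knn weights and coincident-point capping behave", {
  set.seed(17)
  coords <- rbind(cbind(runif(10, 0, 1), runif(10, 0, 1)), c(0.5, 0.5),
                  c(0.5, 0.5))
  expect_warning(w <- spatial_weights(coords, lonlat = FALSE), "coincident")
  expect_true(all(is.finite(w)))
  wk <- spatial_weights(coords[1:10, ], scheme = "knn", k = 3,
                        lonlat = FALSE, row_standardize = FALSE)
  expect_true(all(rowSums(wk) == 3))
  expect_true(all(diag(wk) == 0))
})
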