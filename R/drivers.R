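#' Pearson screening of the 13 candidate drivers
#'
#' Applies, in order: (i) drop PCO2 when |r(PO2, PCO2)| >= `r_drop`
#' (the two are proportional whenever both derive from the same pressure
#' profile); (ii) among the temperature trio (T_coldest, T_annual,
#' T_diurnal), when the trio is mutually redundant, keep only the member
#' least correlated with MAT and drop the others that are redundant with
#' it (|r| >= `r_redundant`); (iii) drop MAP when AI is present and
#' |r(AI, MAP)| >= `r_drop`. Orthogonal tables pass through untouched.
#'
#' @param env data frame containing the 13 driver columns (extra columns
#'   are ignored).
#' @param r_drop absolute-correlation threshold for rules (i) and (iii).
#' @param r_redundant threshold above which temperature-trio members are
#'   treated as redundant in rule (ii).
#' @return An object of class `screen_report`: `kept` (character),
#'   `dropped` (data frame `name`, `rule`), and the Pearson
#'   `correlation_matrix`.
#' @export
screen_variables <- function(env, r_drop = 0.9, r_redundant = 0.5) {
  vars <- vsc_variables()$name
  missing_cols <- setdiff(vars, names(env))
  if (length(missing_cols) > 0L) {
    stop("missing driver columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  x <- env[, vars]
  if (nrow(x) < 3L) stop("need at least 3 plots to screen", call. = FALSE)
  sds <- vapply(x, stats::sd, 0)
  if (any(sds == 0)) {
    stop("constant column(s), correlation undefined: ",
      paste(vars[sds == 0], collapse = ", "),
      call. = FALSE
    )
  }
  cm <- stats::cor(x)
  kept <- vars
  dropped <- data.frame(name = character(), rule = character(),
                        stringsAsFactors = FALSE)
  drop <- function(v, rule) {
    kept <<- setdiff(kept, v)
    dropped <<- rbind(dropped, data.frame(name = v, rule = rule,
                                          stringsAsFactors = FALSE))
  }

  # (i) PCO2 redundant with PO2
  if (abs(cm["PO2", "PCO2"]) >= r_drop) {
    drop("PCO2", sprintf("|r(PO2,PCO2)| = %.2f >= %.2f", abs(cm["PO2", "PCO2"]),
                         r_drop))
  }
  # (ii) temperature trio: keep the member least correlated with MAT
  trio <- intersect(c("T_coldest", "T_annual", "T_diurnal"), kept)
  if (length(trio) > 1L) {
    keep <- trio[which.min(abs(cm[trio, "MAT"]))]
    for (v in setdiff(trio, keep)) {
      if (abs(cm[v, keep]) >= r_redundant) {
        drop(v, sprintf("redundant with %s (|r| = %.2f); %s least correlated with MAT",
                        keep, abs(cm[v, keep]), keep))
      }
    }
  }
  # (iii) MAP redundant with AI
  if ("AI" %in% kept && "MAP" %in% kept && abs(cm["AI", "MAP"]) >= r_drop) {
    drop("MAP", sprintf("|r(AI,MAP)| = %.2f >= %.2f", abs(cm["AI", "MAP"]),
                        r_drop))
  }

  structure(
    list(kept = kept, dropped = dropped, correlation_matrix = cm),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Variable screen:", length(x$kept), "kept,", nrow(x$dropped),
      "dropped\n")
  cat("kept:", paste(x$kept, collapse = ", "), "\n")
  if (nrow(x$dropped) > 0L) {
    for (i in seq_len(nrow(x$dropped))) {
      cat(" -", x$dropped$name[i], ":", x$dropped$rule[i], "\n")
    }
  }
  invisible(x)
}

# R-squared of y on a subset of predictors, from a joint covariance
# matrix with y in position 1. Rank-deficient subsets (duplicated or
# collinear predictors) fall back to a maximal independent subset, so
# the R2 is that of the spanned column space.
r2_from_cov <- function(S, idx) {
  if (length(idx) == 0L) return(0)
  Sxx <- S[idx + 1L, idx + 1L, drop = FALSE]
  q <- qr(Sxx)
  if (q$rank < length(idx)) {
    keep <- q$pivot[seq_len(q$rank)]
    Sxx <- Sxx[keep, keep, drop = FALSE]
    idx <- idx[keep]
  }
  sxy <- S[idx + 1L, 1L]
  drop(crossprod(sxy, solve(Sxx, sxy))) / S[1L, 1L]
}

#' LMG relative-importance decomposition
#'
#' For each predictor, the average over all orders of predictor entry of
#' its incremental R-squared when added to the preceding set, computed by
#' the subset-weighted form: the increment over every subset not
#' containing the predictor, weighted by `|S|! (p - |S| - 1)! / p!`.
#' Shares are non-negative and sum exactly to the full-model R-squared.
#'
#' @param y numeric response.
#' @param x data frame or matrix of predictors (at most 12; enumeration
#'   is exact).
#' @return named numeric vector of per-predictor R-squared shares.
#' @export
lmg_importance <- function(y, x) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p > 12L) {
    stop("more than 12 predictors: exact enumeration is impractical, ",
      "sampling of orderings is not implemented",
      call. = FALSE
    )
  }
  if (p == 0L) return(stats::setNames(numeric(0), character(0)))
  S <- stats::cov(cbind(y, x))
  nsub <- 2L^p
  r2 <- numeric(nsub) # r2[m + 1] = R2 of subset with bitmask m
  sizes <- integer(nsub)
  for (m in seq_len(nsub - 1L)) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) > 0L)
    sizes[m + 1L] <- length(idx)
    r2[m + 1L] <- r2_from_cov(S, idx)
  }
  wt <- factorial(0:(p - 1L)) * factorial(p - 1L - 0:(p - 1L)) / factorial(p)
  out <- numeric(p)
  for (j in seq_len(p)) {
    bj <- bitwShiftL(1L, j - 1L)
    for (m in 0:(nsub - 1L)) {
      if (bitwAnd(m, bj) == 0L) {
        out[j] <- out[j] + wt[sizes[m + 1L] + 1L] *
          (r2[bitwOr(m, bj) + 1L] - r2[m + 1L])
      }
    }
  }
  stats::setNames(out, colnames(x))
}

#' Sequential (entry-order) R-squared decomposition
#'
#' The increment in R-squared as each predictor is added in the order of
#' the columns of `x`; an order-dependent alternative to
#' [lmg_importance()].
#'
#' @inheritParams lmg_importance
#' @return named numeric vector of sequential increments.
#' @export
seq_importance <- function(y, x) {
  x <- as.matrix(x)
  p <- ncol(x)
  S <- stats::cov(cbind(y, x))
  out <- numeric(p)
  prev <- 0
  for (j in seq_len(p)) {
    cur <- r2_from_cov(S, seq_len(j))
    out[j] <- cur - prev
    prev <- cur
  }
  stats::setNames(out, colnames(x))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing predictor j on the others;
#' equivalently the diagonal of the inverse correlation matrix. A single
#' predictor has no VIF (NA); exact collinearity yields Inf with a
#' warning.
#'
#' @param x data frame or matrix of predictors.
#' @return named numeric vector of VIFs (all >= 1).
#' @export
vif_values <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2L) {
    return(stats::setNames(rep(NA_real_, p), colnames(x)))
  }
  cm <- stats::cor(x)
  out <- tryCatch(diag(solve(cm)), error = function(e) {
    warning("exact collinearity among predictors; VIFs are infinite",
      call. = FALSE
    )
    rep(Inf, p)
  })
  stats::setNames(pmax(out, 1), colnames(x))
}

#' Split relative importance into resource and non-resource shares
#'
#' @param r2_by_var named per-variable R-squared shares (e.g. from
#'   [lmg_importance()]).
#' @param registry driver registry with `name` and `class` columns
#'   (default [vsc_variables()]).
#' @return named numeric `c(resource, nonresource)`, percentages of the
#'   summed shares (they add to 100).
#' @export
resource_split <- function(r2_by_var, registry = vsc_variables()) {
  cls <- registry$class[match(names(r2_by_var), registry$name)]
  if (any(is.na(cls))) {
    stop("unclassified variable(s): ",
      paste(names(r2_by_var)[is.na(cls)], collapse = ", "),
      call. = FALSE
    )
  }
  tot <- sum(r2_by_var)
  res <- sum(r2_by_var[cls == "resource"]) / tot * 100
  c(resource = res, nonresource = 100 - res)
}

#' First-order partial correlation
#'
#' Pearson r(x, y) and the partial r(x, y | control) =
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`. When the
#' residuals of y on the control vanish (e.g. y equals the control) the
#' partial correlation is undefined and reported as NA.
#'
#' @param x,y,control numeric vectors of equal length (n >= 4).
#' @return list with `zero_order`, `partial`, `n`.
#' @export
partial_correlation <- function(x, y, control) {
  n <- length(x)
  if (n < 4L || length(y) != n || length(control) != n) {
    stop("x, y and control must have equal length >= 4", call. = FALSE)
  }
  for (v in list(x, y, control)) {
    if (stats::sd(v) == 0) stop("constant input", call. = FALSE)
  }
  rxy <- stats::cor(x, y)
  rxz <- stats::cor(x, control)
  ryz <- stats::cor(y, control)
  den <- (1 - rxz^2) * (1 - ryz^2)
  partial <- if (den <= sqrt(.Machine$double.eps)) {
    warning("residual variance vanishes; partial correlation undefined",
      call. = FALSE
    )
    NA_real_
  } else {
    (rxy - rxz * ryz) / sqrt(den)
  }
  list(zero_order = rxy, partial = partial, n = n)
}

#' Spatial weight matrix for Moran's I
#'
#' Row-standardized inverse-distance weights (default) or k-nearest-
#' neighbour indicator weights. Distances are great-circle (haversine)
#' for lon/lat coordinates, Euclidean otherwise. Coincident points would
#' give infinite weight; their weight is capped at the largest finite
#' weight, with a warning.
#'
#' @param coords two-column matrix/data frame (lon, lat) or (x, y).
#' @param scheme `"idw"` or `"knn"`.
#' @param k neighbour count for `"knn"`.
#' @param lonlat treat coords as lon/lat degrees (great-circle
#'   distances).
#' @param row_standardize divide each row by its sum.
#' @return n x n weight matrix with zero diagonal.
#' @export
spatial_weights <- function(coords, scheme = c("idw", "knn"), k = 8L,
                            lonlat = TRUE, row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  d <- if (lonlat) {
    geosphere::distm(coords) / 1000 # km
  } else {
    as.matrix(stats::dist(coords))
  }
  if (scheme == "idw") {
    w <- matrix(0, n, n)
    off <- row(d) != col(d)
    zero <- off & d == 0
    w[off] <- 1 / d[off]
    if (any(zero)) {
      warning("coincident points; capping their weight", call. = FALSE)
      w[zero] <- max(w[is.finite(w)])
    }
  } else {
    w <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[-1L][seq_len(min(k, n - 1L))]
      w[i, nb] <- 1
    }
  }
  diag(w) <- 0
  if (row_standardize) w <- w / rowSums(w)
  w
}

#' Moran's I spatial autocorrelation
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with centred values
#' z and weight sum S0. The null expectation is `-1/(n-1)`.
#'
#' @param values numeric vector (non-constant).
#' @param coords coordinates passed to [spatial_weights()]; ignored when
#'   `weights` is supplied.
#' @param weights optional pre-built weight matrix.
#' @param ... further arguments to [spatial_weights()].
#' @return list with `observed`, `expected` and `n`.
#' @export
morans_i <- function(values, coords = NULL, weights = NULL, ...) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 locations", call. = FALSE)
  if (stats::sd(values) == 0) stop("constant values", call. = FALSE)
  if (is.null(weights)) {
    if (is.null(coords)) stop("supply coords or weights", call. = FALSE)
    weights <- spatial_weights(coords, ...)
  }
  z <- values - mean(values)
  s0 <- sum(weights)
  obs <- (n / s0) * drop(crossprod(z, weights %*% z)) / sum(z^2)
  list(observed = obs, expected = -1 / (n - 1), n = n)
}
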