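#' Maximum plant height in a plot
#'
#' @param heights numeric vector of plant heights in m, all > 0.
#' @return Height-max in m.
#' @export
#' @examples
#' height_max(c(0.12, 0.17, 0.09))
height_max <- function(heights) {
  check_heights(heights, min_n = 1L)
  max(heights)
}

#' Coefficient of variation of plant height
#'
#' Height-var = SD of plant heights divided by their mean. The sample
#' (n - 1) standard deviation is used by default; survey plots are samples
#' of the community.
#'
#' @inheritParams height_max
#' @param sd_mode `"sample"` (n - 1 denominator, default) or
#'   `"population"` (n denominator).
#' @return Height-var (dimensionless, >= 0).
#' @export
#' @examples
#' height_var(c(1, 3)) # sqrt(2)/2
height_var <- function(heights, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  check_heights(heights, min_n = 2L)
  n <- length(heights)
  s <- stats::sd(heights)
  if (sd_mode == "population") s <- s * sqrt((n - 1) / n)
  s / mean(heights)
}

#' Height-class weight shares (Pk)
#'
#' Bins heights into half-open classes `[k*w, (k+1)*w)` anchored at zero
#' and returns the weight share of each occupied class. Weights are basal
#' areas for woody plots and species importance values for grassland plots
#' (see [compute_vsc()]); unweighted counts are used when `weights` is
#' `NULL`.
#'
#' @inheritParams height_max
#' @param weights optional non-negative weights, same length as `heights`;
#'   they are normalised to sum to 1.
#' @param class_width class width in m (> 0).
#' @return Data frame with columns `class` (lower class bound, m) and `pk`
#'   (weight share; sums to 1).
#' @export
height_class_weights <- function(heights, weights = NULL, class_width) {
  check_heights(heights, min_n = 1L)
  stopifnot(is.numeric(class_width), length(class_width) == 1L, class_width > 0)
  if (is.null(weights)) weights <- rep(1, length(heights))
  if (length(weights) != length(heights)) {
    stop("weights must match heights in length", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with a positive sum", call. = FALSE)
  }
  k <- floor(heights / class_width)
  w <- tapply(weights, k, sum)
  pk <- as.numeric(w) / sum(weights)
  data.frame(class = as.numeric(names(w)) * class_width, pk = pk)
}

#' Shannon evenness of plant height classes
#'
#' Height-even = `[-sum(Pk log Pk)] / log(Nh)` where `Pk` is the weight
#' share of the kth occupied height class and `Nh` the number of occupied
#' classes. A plot whose plants all fall into a single class is maximally
#' uniform and scores 1, consistent with Height-var = 0 there.
#'
#' @inheritParams height_class_weights
#' @param nh_mode `"occupied"` (default): `Nh` counts occupied classes
#'   only; `"span"`: `Nh` counts all classes between the lowest and
#'   highest occupied class, so gaps in the height profile lower the
#'   score.
#' @return Height-even in \[0, 1\].
#' @export
#' @examples
#' height_even(c(0.5, 1.5), class_width = 1) # two equal classes -> 1
height_even <- function(heights, weights = NULL, class_width,
                        nh_mode = c("occupied", "span")) {
  nh_mode <- match.arg(nh_mode)
  tab <- height_class_weights(heights, weights, class_width)
  pk <- tab$pk[tab$pk > 0]
  nh <- switch(nh_mode,
    occupied = length(pk),
    span = diff(range(tab$class)) / class_width + 1
  )
  if (nh <= 1) return(1)
  h <- -sum(pk * log(pk))
  # guard against rounding just past the [0, 1] bounds
  min(1, max(0, h / log(nh)))
}

#' Species importance value
#'
#' IV = (relative height + relative coverage) / 2. Over the species of a
#' plot the IVs sum to 1 whenever each relative quantity does.
#'
#' @param relative_height,relative_coverage fractions in \[0, 1\].
#' @return importance values, same length as the inputs.
#' @export
importance_value <- function(relative_height, relative_coverage) {
  for (x in list(relative_height, relative_coverage)) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop("relative height and coverage must lie in [0, 1]", call. = FALSE)
    }
  }
  (relative_height + relative_coverage) / 2
}

#' Shannon-Wiener diversity from importance values
#'
#' `-sum(IV log IV)` with the IVs renormalised to sum to 1 (they must
#' already be within 1% of that).
#'
#' @param iv positive importance values, summing to approximately 1.
#' @return Shannon-Wiener index (dimensionless, >= 0).
#' @export
shannon_wiener <- function(iv) {
  if (length(iv) == 0L || any(!is.finite(iv)) || any(iv < 0) || sum(iv) <= 0) {
    stop("importance values must be non-negative with a positive sum",
      call. = FALSE
    )
  }
  if (abs(sum(iv) - 1) > 0.01) {
    stop("importance values must sum to 1 (within 1%)", call. = FALSE)
  }
  iv <- iv / sum(iv)
  iv <- iv[iv > 0]
  -sum(iv * log(iv))
}

#' Per-plot vertical structural complexity
#'
#' Computes Height-max, Height-var and Height-even for every plot of a
#' plant-record table, applying the vegetation-type conventions: woody
#' plots (forest, shrubland) weight height classes by basal area
#' `pi * (d/2)^2` from the DBH/basal diameter; grassland plots aggregate
#' to species (mean height, recorded coverage), weight classes by the
#' species importance value and also report the Shannon-Wiener diversity
#' used in the sampling-bias check.
#'
#' @param plants data frame in the plot-table schema of
#'   [read_plot_table()]: `plot_id`, `veg_type`, `species`, `height_m`,
#'   `coverage_frac`, `dbh_cm`, `lat`, `lon`, `elev_m`.
#' @param widths named height-class widths in m, by vegetation type
#'   (default [class_widths()]).
#' @param sd_mode,nh_mode passed to [height_var()] / [height_even()].
#' @return Data frame, one row per plot: `plot_id`, `veg_type`,
#'   `height_max`, `height_var` (NA for single-plant plots),
#'   `height_even`, `shannon` (grassland plots, else NA), `n_plants`,
#'   `n_classes`, `lat`, `lon`, `elev_m`.
#' @export
compute_vsc <- function(plants, widths = class_widths(),
                        sd_mode = c("sample", "population"),
                        nh_mode = c("occupied", "span")) {
  sd_mode <- match.arg(sd_mode)
  nh_mode <- match.arg(nh_mode)
  check_veg_type(plants$veg_type)
  rows <- lapply(split(plants, plants$plot_id, drop = TRUE), function(p) {
    type <- p$veg_type[1L]
    w <- widths[[type]]
    h <- p$height_m
    woody <- type %in% woody_types()
    if (woody) {
      if (any(is.na(p$dbh_cm))) {
        stop("plot ", p$plot_id[1L], ": woody plot with missing dbh_cm",
          call. = FALSE
        )
      }
      ba <- pi * (p$dbh_cm / 2)^2
      tab <- height_class_weights(h, ba, w)
      even <- height_even(h, ba, w, nh_mode = nh_mode)
      shan <- NA_real_
    } else {
      if (any(is.na(p$coverage_frac))) {
        stop("plot ", p$plot_id[1L], ": grassland plot with missing coverage",
          call. = FALSE
        )
      }
      mh <- tapply(p$height_m, p$species, mean)
      cv <- tapply(p$coverage_frac, p$species, function(x) x[1L])
      iv <- importance_value(mh / sum(mh), cv / sum(cv))
      tab <- height_class_weights(as.numeric(mh), as.numeric(iv), w)
      even <- height_even(as.numeric(mh), as.numeric(iv), w, nh_mode = nh_mode)
      shan <- shannon_wiener(as.numeric(iv))
    }
    data.frame(
      plot_id = p$plot_id[1L], veg_type = type,
      height_max = max(h),
      height_var = if (length(h) >= 2L) height_var(h, sd_mode) else NA_real_,
      height_even = even,
      shannon = shan,
      n_plants = length(h),
      n_classes = nrow(tab),
      lat = p$lat[1L], lon = p$lon[1L], elev_m = p$elev_m[1L],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean VSC along a latitude or elevation gradient
#'
#' Bins plots into fixed bands (3 degrees of latitude or 1000 m of
#' elevation by default) and reports per-band means of the three metrics.
#'
#' @param vsc per-plot VSC table from [compute_vsc()].
#' @param axis `"latitude"` or `"elevation"`.
#' @param width band width; defaults to 3 (degrees) for latitude and 1000
#'   (m) for elevation.
#' @return Data frame with `bin_lower`, `bin_upper`, `n`, and the mean of
#'   each metric per band (NaN where `n` = 0 bands are absent).
#' @export
gradient_bins <- function(vsc, axis = c("latitude", "elevation"),
                          width = NULL) {
  axis <- match.arg(axis)
  x <- switch(axis, latitude = vsc$lat, elevation = vsc$elev_m)
  if (is.null(width)) width <- switch(axis, latitude = 3, elevation = 1000)
  lo <- floor(x / width) * width
  agg <- function(v) tapply(v, lo, mean, na.rm = TRUE)
  out <- data.frame(
    bin_lower = sort(unique(lo)),
    n = as.integer(table(lo)),
    height_max = as.numeric(agg(vsc$height_max)),
    height_var = as.numeric(agg(vsc$height_var)),
    height_even = as.numeric(agg(vsc$height_even))
  )
  out$bin_upper <- out$bin_lower + width
  out[, c("bin_lower", "bin_upper", "n", "height_max", "height_var",
          "height_even")]
}

#' Ratio of mean Height-max between two gradient bands
#'
#' @param bins output of [gradient_bins()].
#' @param a,b lower bounds of the numerator and denominator bands.
#' @param metric metric column to compare.
#' @return the ratio of band means.
#' @export
bin_ratio <- function(bins, a, b, metric = "height_max") {
  ia <- match(a, bins$bin_lower)
  ib <- match(b, bins$bin_lower)
  if (is.na(ia) || is.na(ib)) stop("band not present", call. = FALSE)
  bins[[metric]][ia] / bins[[metric]][ib]
}

check_heights <- function(heights, min_n) {
  if (length(heights) < min_n) {
    stop("need at least ", min_n, " plant height(s); CV is undefined for ",
      "fewer than 2 plants",
      call. = FALSE
    )
  }
  if (any(!is.finite(heights)) || any(heights <= 0)) {
    stop("plant heights must be finite and > 0", call. = FALSE)
  }
  invisible(heights)
}
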