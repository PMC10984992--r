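# Shared fixtures, built in code.

# scaled-down survey covering all five vegetation types
small_config <- function(seed = 7L) {
  synthetic_config(
    n_plots = c(forest = 60, shrubland = 20, meadow = 70, steppe = 70,
                desert = 40),
    seed = seed, grid_shape = c(12L, 12L)
  )
}

# hand-built woody plot table: one plot, given heights and dbh
woody_plot <- function(heights, dbh = rep(10, length(heights)),
                       type = "forest", id = "p1") {
  data.frame(
    plot_id = id, veg_type = type,
    species = paste0("sp", seq_along(heights)),
    height_m = heights, coverage_frac = NA_real_, dbh_cm = dbh,
    lat = 30, lon = 95, elev_m = 3000,
    stringsAsFactors = FALSE
  )
}

# hand-built grassland plot: one row per species (one individual each)
grass_plot <- function(heights, coverage, type = "meadow", id = "g1") {
  data.frame(
    plot_id = id, veg_type = type,
    species = paste0("sp", seq_along(heights)),
    height_m = heights, coverage_frac = coverage, dbh_cm = NA_real_,
    lat = 33, lon = 90, elev_m = 4000,
    stringsAsFactors = FALSE
  )
}

# Gaussian predictor with a target correlation to an existing standard
# normal variable: x = r*base + sqrt(1-r^2)*noise
corr_with <- function(base, r, noise) r * base + sqrt(1 - r^2) * noise
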