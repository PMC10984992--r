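#' Registry of the 13 candidate environmental drivers
#'
#' The driver-attribution analysis distinguishes *resource* variables
#' (supply of water, heat and soil nutrients: MAT, MAP, AI, pH, SOC, TN)
#' from *non-resource limiting* variables (stressors that restrict growth
#' without supplying a resource: minimum temperature of the coldest month,
#' diurnal and annual temperature range, atmospheric O2 and CO2 partial
#' pressure, ultraviolet radiation, wind speed).
#'
#' @return A data frame with columns `name` and `class`
#'   (`"resource"` or `"nonresource"`), one row per driver.
#' @export
#' @examples
#' vsc_variables()
vsc_variables <- function() {
  data.frame(
    name = c(
      "MAT", "MAP", "AI", "pH", "SOC", "TN",
      "T_coldest", "T_diurnal", "T_annual", "PO2", "PCO2", "UR", "Wind"
    ),
    class = c(rep("resource", 6L), rep("nonresource", 7L)),
    stringsAsFactors = FALSE
  )
}

#' @rdname vsc_variables
#' @export
resource_vars <- function() {
  reg <- vsc_variables()
  reg$name[reg$class == "resource"]
}

#' @rdname vsc_variables
#' @export
nonresource_vars <- function() {
  reg <- vsc_variables()
  reg$name[reg$class == "nonresource"]
}

#' Vegetation types and their conventions
#'
#' Five vegetation types are recognised. Forests and shrublands are
#' "woody" (plants carry a DBH or basal diameter, height-class weights are
#' basal-area shares); meadows, steppes and deserts are "grassland"
#' (species carry a coverage fraction, weights are species importance
#' values). Height-class widths follow the survey convention: 1 m for
#' forests, 0.10 m for shrublands and 0.01 m for grasslands.
#'
#' @return `veg_types()`: character vector of the five types.
#' @export
veg_types <- function() c("forest", "shrubland", "meadow", "steppe", "desert")

#' @rdname veg_types
#' @export
woody_types <- function() c("forest", "shrubland")

#' @rdname veg_types
#' @export
grassland_types <- function() c("meadow", "steppe", "desert")

#' @rdname veg_types
#' @return `class_widths()`: named numeric vector of height-class widths in m.
#' @export
class_widths <- function() {
  c(forest = 1, shrubland = 0.10, meadow = 0.01, steppe = 0.01, desert = 0.01)
}

# internal: check a veg_type vector, returning it invisibly
check_veg_type <- function(x) {
  bad <- setdiff(unique(x), veg_types())
  if (length(bad) > 0L) {
    stop("unknown veg_type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
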