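plot_table_cols <- c(
  "plot_id", "veg_type", "species", "height_m", "coverage_frac", "dbh_cm",
  "lat", "lon", "elev_m"
)

#' Read and validate a plot survey table
#'
#' Comma-delimited, UTF-8, one row per measured plant:
#' `plot_id, veg_type, species, height_m, coverage_frac, dbh_cm, lat,
#' lon, elev_m`. Grassland rows must carry `coverage_frac`, woody rows
#' `dbh_cm`; a plot may not mix the two schemas. Validation errors name
#' the offending data row.
#'
#' @param path file path.
#' @return validated data frame in the plot-table schema.
#' @export
read_plot_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(plot_table_cols, names(d))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  validate_plot_table(d)
}

validate_plot_table <- function(d) {
  rowmsg <- function(i, msg) {
    stop("row ", i[1L], ": ", msg, call. = FALSE)
  }
  bad <- which(!d$veg_type %in% veg_types())
  if (length(bad) > 0L) rowmsg(bad, paste("unknown veg_type", d$veg_type[bad[1L]]))
  bad <- which(!is.finite(d$height_m) | d$height_m <= 0)
  if (length(bad) > 0L) rowmsg(bad, "non-positive height_m")
  woody <- d$veg_type %in% woody_types()
  bad <- which(woody & is.na(d$dbh_cm))
  if (length(bad) > 0L) rowmsg(bad, "woody row without dbh_cm")
  bad <- which(woody & !is.na(d$coverage_frac))
  if (length(bad) > 0L) rowmsg(bad, "woody row with coverage_frac")
  bad <- which(!woody & is.na(d$coverage_frac))
  if (length(bad) > 0L) rowmsg(bad, "grassland row without coverage_frac")
  bad <- which(!woody & !is.na(d$dbh_cm))
  if (length(bad) > 0L) rowmsg(bad, "grassland row with dbh_cm")
  bad <- which(!is.na(d$dbh_cm) & d$dbh_cm <= 0)
  if (length(bad) > 0L) rowmsg(bad, "non-positive dbh_cm")
  bad <- which(!is.na(d$coverage_frac) &
                 (d$coverage_frac <= 0 | d$coverage_frac > 1))
  if (length(bad) > 0L) rowmsg(bad, "coverage_frac outside (0, 1]")
  mixed <- tapply(d$veg_type, d$plot_id, function(v) length(unique(v)) > 1L)
  if (any(mixed)) {
    stop("plot ", names(mixed)[mixed][1L], ": mixed veg_type within a plot",
      call. = FALSE
    )
  }
  d
}

#' @rdname read_plot_table
#' @param plants plot table to write.
#' @export
write_plot_table <- function(plants, path) {
  utils::write.csv(plants[, plot_table_cols], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read/write the per-plot environment table
#'
#' One row per plot; the 13 driver columns carry the registry names
#' verbatim, alongside `plot_id`, `veg_type`, `lat`, `lon`, `elev_m`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_env_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(vsc_variables()$name, names(d))
  if (length(missing_cols) > 0L) {
    stop("missing driver column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  d
}

#' @rdname read_env_table
#' @param env environment table to write.
#' @export
write_env_table <- function(env, path) {
  utils::write.csv(env, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read/write a gridded layer as plain text
#'
#' ESRI ASCII grid dialect: a 6-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by the
#' rows of the matrix, northernmost row first.
#'
#' @param m numeric matrix (row 1 = north).
#' @param path file path.
#' @param xll,yll lower-left corner coordinates.
#' @param cellsize cell size.
#' @param nodata sentinel written for NA cells.
#' @export
write_grid <- function(m, path, xll = 0, yll = 0, cellsize = 1,
                       nodata = -9999) {
  hdr <- c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", xll), paste("yllcorner", yll),
    paste("cellsize", cellsize), paste("NODATA_value", nodata)
  )
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_grid
#' @return `read_grid()`: the matrix with NODATA cells as NA and the
#'   header fields as attributes.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ln <- readLines(path)
  hdr <- strsplit(ln[1:6], "\\s+")
  val <- stats::setNames(
    vapply(hdr, function(x) as.numeric(x[2L]), 0),
    vapply(hdr, `[[`, "", 1L)
  )
  m <- do.call(rbind, lapply(ln[-(1:6)], function(s) {
    as.numeric(strsplit(trimws(s), "\\s+")[[1L]])
  }))
  m[m == val[["NODATA_value"]]] <- NA_real_
  attr(m, "xllcorner") <- val[["xllcorner"]]
  attr(m, "yllcorner") <- val[["yllcorner"]]
  attr(m, "cellsize") <- val[["cellsize"]]
  m
}

#' Table-1-style summary of VSC by vegetation type
#'
#' @param vsc per-plot VSC table from [compute_vsc()].
#' @return data frame with per-type mean and SD of each metric and the
#'   plot count N.
#' @export
vsc_summary <- function(vsc) {
  sp <- split(vsc, vsc$veg_type)
  sp <- sp[intersect(veg_types(), names(sp))]
  rows <- lapply(sp, function(d) {
    data.frame(
      veg_type = d$veg_type[1L],
      height_max_mean = mean(d$height_max),
      height_max_sd = stats::sd(d$height_max),
      height_var_mean = mean(d$height_var, na.rm = TRUE),
      height_var_sd = stats::sd(d$height_var, na.rm = TRUE),
      height_even_mean = mean(d$height_even),
      height_even_sd = stats::sd(d$height_even),
      N = nrow(d),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
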