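#' Concentric circular sample plot (CCSP) design
#'
#' The nested-ring design of the inventory: trees in progressively larger
#' DBH classes are measured on progressively larger concentric subplots.
#' Ring areas are stored at full precision (`pi * r^2`); the field
#' manual's 2-dp printed areas are reproduced within 0.01 m^2 but are not
#' used in arithmetic (the printed roundings are internally inconsistent).
#'
#' DBH class intervals are half-open `[min, max)`: a tree recorded at
#' exactly 10.0, 20.0 or 30.0 cm falls in the larger ring, consistent
#' with class labels such as "20.0-29.9" and ">30" at 0.1 cm recording
#' precision.
#'
#' @param radius_m ring radii, m, largest DBH class first.
#' @param dbh_min_cm,dbh_max_cm half-open DBH class bounds, cm
#'   (`Inf` for the open top class).
#' @return A tibble of class `ccsp_design` with columns `radius_m`,
#'   `area_m2`, `dbh_min_cm`, `dbh_max_cm`.
#' @examples
#' ccsp_design() # the inventory default: 20/15/8/4 m rings
#' @export
ccsp_design <- function(radius_m = c(20, 15, 8, 4),
                        dbh_min_cm = c(30, 20, 10, 5),
                        dbh_max_cm = c(Inf, 30, 20, 10)) {
  if (length(radius_m) != length(dbh_min_cm) ||
      length(radius_m) != length(dbh_max_cm)) {
    stopf("radius and DBH class vectors must have equal length")
  }
  check_number(radius_m, "radius_m", lower = 0, strict_lower = TRUE)
  design <- tibble::tibble(
    radius_m   = radius_m,
    area_m2    = pi * radius_m^2,
    dbh_min_cm = dbh_min_cm,
    dbh_max_cm = dbh_max_cm
  )
  design <- design[order(design$dbh_min_cm), , drop = FALSE]
  if (any(design$dbh_min_cm >= design$dbh_max_cm)) {
    stopf("each DBH class needs dbh_min_cm < dbh_max_cm")
  }
  n <- nrow(design)
  if (n > 1L &&
      any(design$dbh_max_cm[-n] != design$dbh_min_cm[-1L])) {
    stopf("DBH classes must be disjoint and contiguous (half-open [min, max))")
  }
  class(design) <- c("ccsp_design", class(design))
  design
}

#' Assign a tree to its CCSP ring by DBH class
#'
#' @param dbh DBH in cm (vectorised).
#' @param design a [ccsp_design()].
#' @return Integer row index into `design` for each tree, or `NA` for
#'   trees below the smallest measured class (DBH < 5.0 cm by default).
#' @examples
#' d <- ccsp_design()
#' assign_subplot(c(4.9, 5, 10, 29.9, 30), d)
#' @export
assign_subplot <- function(dbh, design = ccsp_design()) {
  check_number(dbh, "dbh", lower = 0, strict_lower = TRUE)
  idx <- findInterval(dbh, c(design$dbh_min_cm, Inf),
                      left.open = FALSE, rightmost.closed = FALSE)
  idx[idx == 0L | idx > nrow(design)] <- NA_integer_
  idx
}

#' Per-hectare expansion factor of a CCSP ring
#'
#' Each tree measured on a subplot of area `A` m^2 represents
#' `10000 / A` trees per hectare.
#'
#' @param area_m2 subplot area, m^2.
#' @return Trees-per-hectare multiplier.
#' @examples
#' expansion_factor(pi * 4^2) # ~198.9 for the 4 m ring
#' @export
expansion_factor <- function(area_m2) {
  check_number(area_m2, "area_m2", lower = 0, strict_lower = TRUE)
  10000 / area_m2
}
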