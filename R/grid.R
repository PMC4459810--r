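#' The Humphrey 24-2 test grid
#'
#' Canonical test-point locations of the Humphrey Field Analyzer 24-2
#' pattern, in field-view coordinates (as the patient sees the field):
#' `x` is horizontal eccentricity in degrees with temporal positive for a
#' right eye, `y` is vertical with superior positive. Points sit on a 6
#' degree lattice at `x, y in {+-3, +-9, +-15, +-21}` with a single nasal
#' extension column at 27 degrees on the rows `y = +-3`, giving 54 tested
#' locations per eye. The physiological blind spot falls on the two
#' temporal points at 15 degrees (`(+15, +-3)` for a right eye,
#' `(-15, +-3)` for a left eye); dropping them leaves the 52 locations
#' used for all summaries.
#'
#' @param eye `"right"` or `"left"`. The two grids are mirror images in
#'   `x`; a left-eye field mirrored by `x -> -x` lands exactly on the
#'   right-eye grid, blind spot included.
#' @param drop_blind_spot if `TRUE` (default) the two blind-spot
#'   locations are removed, returning 52 points.
#' @return A data frame with integer columns `x` and `y`, one row per
#'   location, ordered row-major from superior-temporal.
#' @examples
#' nrow(vf_grid("right"))                      # 52
#' nrow(vf_grid("left", drop_blind_spot = FALSE))  # 54
#' @export
vf_grid <- function(eye = c("right", "left"), drop_blind_spot = TRUE) {
  eye <- match.arg(eye)
  rows <- list(
    `21` = c(-9L, -3L, 3L, 9L),
    `15` = c(-15L, -9L, -3L, 3L, 9L, 15L),
    `9`  = c(-21L, -15L, -9L, -3L, 3L, 9L, 15L, 21L),
    `3`  = c(-27L, -21L, -15L, -9L, -3L, 3L, 9L, 15L, 21L)
  )
  ys <- c(21L, 15L, 9L, 3L, -3L, -9L, -15L, -21L)
  g <- do.call(rbind, lapply(ys, function(y) {
    x <- rows[[as.character(abs(y))]]
    data.frame(x = x, y = rep(y, length(x)))
  }))
  if (eye == "left") g$x <- -g$x
  if (drop_blind_spot) {
    bs <- blind_spot(eye)
    keep <- !(paste(g$x, g$y) %in% paste(bs$x, bs$y))
    g <- g[keep, , drop = FALSE]
  }
  g <- g[order(-g$y, g$x), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Blind-spot locations for one eye
#'
#' @param eye `"right"` or `"left"`.
#' @return Data frame with the two field-view blind-spot locations.
#' @export
blind_spot <- function(eye = c("right", "left")) {
  eye <- match.arg(eye)
  x <- if (eye == "right") 15L else -15L
  data.frame(x = c(x, x), y = c(3L, -3L))
}

#' Default central-region point set
#'
#' The 16 locations of the 24-2 grid lying within the central ten degrees
#' (`|x| <= 9` and `|y| <= 9`), i.e. the 24-2 points that coincide with
#' the 10-2 pattern's footprint. Used by [summarize_ivf()] to split the
#' integrated field into central and peripheral regions; pass a different
#' point set there to use an alternative mapping.
#'
#' @return Data frame of 16 `(x, y)` locations in right-eye format.
#' @export
central_points_default <- function() {
  g <- vf_grid("right")
  g[abs(g$x) <= 9 & abs(g$y) <= 9, , drop = FALSE]
}

# region label per point of a right-eye-format 52-point grid;
# the 24-2 has no points on y == 0, so superior/inferior is a total split
# (asserted rather than assumed).
region_labels <- function(points, central = central_points_default()) {
  stopifnot(all(points$y != 0))
  cen <- paste(central$x, central$y)
  is_central <- paste(points$x, points$y) %in% cen
  is_sup <- points$y > 0
  ifelse(is_sup & !is_central, "sup_periph",
    ifelse(is_sup & is_central, "sup_cent",
      ifelse(!is_sup & is_central, "inf_cent", "inf_periph")
    )
  )
}
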