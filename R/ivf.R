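#' Integrate two monocular fields into a binocular IVF
#'
#' Builds the binocular integrated visual field (IVF) by the
#' best-sensitivity rule: the left-eye field is mirrored horizontally
#' (`x -> -x`) into right-eye format, which superimposes the two 52-point
#' grids exactly (the blind spots coincide), and at every location the
#' IVF total deviation is the maximum of the two monocular values — the
#' field the patient effectively sees with both eyes open.
#'
#' @param left a [monocular_vf()] for the left eye.
#' @param right a [monocular_vf()] for the right eye of the same subject.
#' @return An object of class `integrated_vf`: list with `subject_id`
#'   and `points` (52 rows, right-eye format, columns `x`, `y`, `td`).
#' @examples
#' cfg <- synthetic_config(n_subjects = 1, seed = 1)
#' coh <- generate_cohort(cfg)
#' ivf <- integrate_vf(coh$fields[[1]], coh$fields[[2]])
#' @export
integrate_vf <- function(left, right) {
  stopifnot(inherits(left, "monocular_vf"), inherits(right, "monocular_vf"))
  if (left$subject_id != right$subject_id) {
    stop(
      "cannot integrate fields of different subjects: ",
      left$subject_id, " vs ", right$subject_id
    )
  }
  if (left$eye != "left" || right$eye != "right") {
    stop("integrate_vf() needs one left and one right eye, in that order")
  }
  mirrored <- left$points
  mirrored$x <- -mirrored$x
  grid <- vf_grid("right")
  gkey <- paste(grid$x, grid$y)
  lt <- mirrored$td[match(gkey, paste(mirrored$x, mirrored$y))]
  rt <- right$points$td[match(gkey, paste(right$points$x, right$points$y))]
  stopifnot(!anyNA(lt), !anyNA(rt)) # guaranteed by monocular_vf invariants
  structure(
    list(
      subject_id = right$subject_id,
      points = data.frame(x = grid$x, y = grid$y, td = pmax(lt, rt))
    ),
    class = "integrated_vf"
  )
}

#' @export
print.integrated_vf <- function(x, ...) {
  cat(
    "<integrated_vf> subject", x$subject_id, ";",
    "IVF MD", sprintf("%.1f dB", mean(x$points$td)), "\n"
  )
  invisible(x)
}

#' Regional summary of an integrated visual field
#'
#' Splits the 52-point IVF into four regions — superior/inferior crossed
#' with central/peripheral, where "central" is the point set within the
#' central ten degrees (default [central_points_default()]: the 16
#' locations with `|x|, |y| <= 9`, the 24-2 points shared with the 10-2
#' pattern) — and returns the mean total deviation of each region along
#' with the whole-field mean (`ivf_md`, the IVF mean deviation). With the
#' default central set the region sizes are 18 (superior peripheral),
#' 8 (superior central), 8 (inferior central) and 18 (inferior
#' peripheral), and `ivf_md` equals their point-count-weighted mean.
#'
#' @param ivf an `integrated_vf` from [integrate_vf()].
#' @param central data frame of `(x, y)` locations treated as central;
#'   swap in an alternative mapping (e.g. a 12-point set) if desired.
#' @return A one-row data frame: `subject_id`, `mtd_sup_periph`,
#'   `mtd_sup_cent`, `mtd_inf_cent`, `mtd_inf_periph`, `ivf_md` (all dB).
#' @export
summarize_ivf <- function(ivf, central = central_points_default()) {
  stopifnot(inherits(ivf, "integrated_vf"))
  lab <- region_labels(ivf$points, central)
  m <- vapply(
    c("sup_periph", "sup_cent", "inf_cent", "inf_periph"),
    function(r) mean(ivf$points$td[lab == r]),
    numeric(1)
  )
  data.frame(
    subject_id = ivf$subject_id,
    mtd_sup_periph = m[["sup_periph"]],
    mtd_sup_cent = m[["sup_cent"]],
    mtd_inf_cent = m[["inf_cent"]],
    mtd_inf_periph = m[["inf_periph"]],
    ivf_md = mean(ivf$points$td),
    stringsAsFactors = FALSE
  )
}

#' Integrate and summarise a collection of monocular fields
#'
#' Pairs each subject's two eyes, integrates them and stacks the
#' regional summaries.
#'
#' @param fields list of [monocular_vf()] objects containing a left and a
#'   right eye for every subject.
#' @param central central-region point set, see [summarize_ivf()].
#' @return Data frame with one summary row per subject.
#' @export
summarize_cohort_ivf <- function(fields, central = central_points_default()) {
  ids <- vapply(fields, `[[`, character(1), "subject_id")
  eyes <- vapply(fields, `[[`, character(1), "eye")
  out <- lapply(unique(ids), function(id) {
    l <- which(ids == id & eyes == "left")
    r <- which(ids == id & eyes == "right")
    if (length(l) != 1 || length(r) != 1) {
      stop("subject ", id, " does not have exactly one field per eye")
    }
    summarize_ivf(integrate_vf(fields[[l]], fields[[r]]), central)
  })
  do.call(rbind, out)
}
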