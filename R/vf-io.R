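#' Construct a monocular visual field
#'
#' A `monocular_vf` holds one eye's Humphrey 24-2 total-deviation (TD)
#' grid: the per-location difference, in dB, between measured sensitivity
#' and the age-matched normative value (negative = loss). Construction
#' validates the full grid: exactly the 52 non-blind-spot locations for
#' that eye, no duplicates, and TD values inside the instrument's
#' plausible range of -40 to +15 dB.
#'
#' @param subject_id subject identifier (coerced to character).
#' @param eye `"left"` or `"right"`.
#' @param points data frame with columns `x`, `y` (degrees, field view)
#'   and `td` (dB).
#' @return An object of class `monocular_vf`: a list with elements
#'   `subject_id`, `eye` and `points` (rows ordered canonically).
#' @seealso [read_vf_table()], [integrate_vf()]
#' @export
monocular_vf <- function(subject_id, eye, points) {
  eye <- match.arg(eye, c("left", "right"))
  subject_id <- as.character(subject_id)
  stopifnot(is.data.frame(points), all(c("x", "y", "td") %in% names(points)))
  if (!is.numeric(points$td)) {
    stop("non-numeric td values for subject ", subject_id, ", ", eye, " eye")
  }
  key <- paste(points$x, points$y)
  if (anyDuplicated(key)) {
    stop(
      "duplicate grid location(s) for subject ", subject_id, ", ", eye,
      " eye: ", paste(unique(key[duplicated(key)]), collapse = "; ")
    )
  }
  bs <- blind_spot(eye)
  hit_bs <- key %in% paste(bs$x, bs$y)
  if (any(hit_bs)) {
    stop(
      "blind-spot location present for subject ", subject_id, ", ", eye,
      " eye: (", paste(key[hit_bs], collapse = "), ("), ")"
    )
  }
  grid <- vf_grid(eye)
  gkey <- paste(grid$x, grid$y)
  extra <- setdiff(key, gkey)
  if (length(extra)) {
    stop(
      "location(s) not on the 24-2 grid for subject ", subject_id, ", ",
      eye, " eye: (", paste(extra, collapse = "), ("), ")"
    )
  }
  missing <- setdiff(gkey, key)
  if (length(missing)) {
    stop(
      "incomplete grid for subject ", subject_id, ", ", eye,
      " eye: missing location(s) (", paste(missing, collapse = "), ("), ")"
    )
  }
  if (any(points$td < -40 | points$td > 15)) {
    stop(
      "td outside [-40, 15] dB for subject ", subject_id, ", ", eye, " eye"
    )
  }
  points <- points[match(gkey, key), c("x", "y", "td")]
  rownames(points) <- NULL
  structure(
    list(subject_id = subject_id, eye = eye, points = points),
    class = "monocular_vf"
  )
}

#' @export
print.monocular_vf <- function(x, ...) {
  cat(
    "<monocular_vf> subject", x$subject_id, "-", x$eye, "eye;",
    "mean TD", sprintf("%.1f dB", mean(x$points$td)), "\n"
  )
  invisible(x)
}

#' Read monocular visual fields from a CSV table
#'
#' The file dialect is plain comma-separated with a required header and
#' columns `subject_id`, `eye` (`"left"`/`"right"`), `x_deg`, `y_deg`,
#' `td_db`; one row per tested location. Each `(subject_id, eye)` group
#' must contain the complete 52-point grid for that eye.
#'
#' @param path path to the CSV file.
#' @return A list of [monocular_vf()] objects, named `"<subject>/<eye>"`.
#' @export
read_vf_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("subject_id", "eye", "x_deg", "y_deg", "td_db")
  if (!all(need %in% names(raw))) {
    stop(
      "visual-field table ", path, " must have columns ",
      paste(need, collapse = ", ")
    )
  }
  if (nrow(raw) == 0) return(list())
  td <- suppressWarnings(as.numeric(raw$td_db))
  if (anyNA(td)) {
    bad <- which(is.na(td))[1]
    stop(
      "non-numeric td_db value '", raw$td_db[bad], "' at data row ", bad,
      " of ", path
    )
  }
  xy <- suppressWarnings(cbind(as.numeric(raw$x_deg), as.numeric(raw$y_deg)))
  if (anyNA(xy)) {
    stop("non-numeric x_deg/y_deg at data row ", which(is.na(rowSums(xy)))[1])
  }
  grp <- paste(raw$subject_id, raw$eye, sep = "/")
  idx <- split(seq_len(nrow(raw)), factor(grp, levels = unique(grp)))
  out <- lapply(idx, function(i) {
    monocular_vf(
      subject_id = raw$subject_id[i[1]],
      eye = raw$eye[i[1]],
      points = data.frame(x = xy[i, 1], y = xy[i, 2], td = td[i])
    )
  })
  out
}

#' Write monocular visual fields to a CSV table
#'
#' Inverse of [read_vf_table()]: TD values are printed to one decimal
#' place (the resolution of HFA printouts), so a write/read round trip is
#' lossless for values stored at that resolution.
#'
#' @param fields a list of [monocular_vf()] objects (may be empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vf_table <- function(fields, path) {
  stopifnot(is.list(fields))
  rows <- lapply(fields, function(f) {
    stopifnot(inherits(f, "monocular_vf"))
    data.frame(
      subject_id = f$subject_id, eye = f$eye,
      x_deg = f$points$x, y_deg = f$points$y,
      td_db = sprintf("%.1f", f$points$td),
      stringsAsFactors = FALSE
    )
  })
  tab <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      subject_id = character(), eye = character(), x_deg = integer(),
      y_deg = integer(), td_db = character()
    )
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
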