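# The trauma-risk rating scale: an ordinal grade 0-IV assigned to each
# insertion step from the geometric overlap features. In clinical use such
# scales are subjective expert ratings; here the scale is operationalized as
# a deterministic
# first-match cascade evaluated from grade IV down to grade 0 using the
# scale's quantitative anchors (half / whole tip size, a quarter / the whole
# body cross-section, restraint between the walls, far outside the contour).

grade_default_config <- function() {
  list(
    body_slight = 0.25,      # grade I/II boundary: fraction of cross section
    tip_half = 0.5,          # grade II: tip overlap beyond half its size
    tip_incidence_deg = 45,  # grade II: tip oriented head-on into the wall
    regions_extensive = 3L   # grade IV: secondary contacts while restrained
  )
}

#' Trauma-risk grade of one overlap report
#'
#' Cascade, first match wins:
#' * IV  - outline far outside the contour, or restraint with extensive
#'         secondary contact areas;
#' * III - tip fully outside the lumen, body penetrated by more than its
#'         whole cross section, or restraint between inner and outer walls;
#' * II  - tip overlap beyond half the tip size, body penetration beyond a
#'         quarter of the cross section, or a penetrating tip oriented
#'         head-on into the wall;
#' * I   - any remaining contact (slight penetration up to 0.25 of the
#'         cross section);
#' * 0   - no contact.
#'
#' @param report an `overlap_report`.
#' @param config overrides for [grade_default_config()].
#' @return a `trauma_grade`: integer 0..4 with a Roman-numeral label.
#' @export
grade <- function(report, config = list()) {
  cfg <- utils::modifyList(grade_default_config(), config)
  r <- report
  g <- if (r$far_outside_flag ||
           (r$restraint_flag && r$contact_regions >= cfg$regions_extensive)) {
    4L
  } else if (r$tip_outside_whole ||
             r$body_penetration_fraction >= 1 ||
             r$restraint_flag) {
    3L
  } else if (r$tip_overlap_fraction > cfg$tip_half ||
             r$body_penetration_fraction > cfg$body_slight ||
             (r$tip_overlap_fraction > 0 &&
              !is.na(r$tip_incidence_deg) &&
              r$tip_incidence_deg < cfg$tip_incidence_deg)) {
    2L
  } else if (r$body_penetration_fraction > 0 ||
             r$tip_overlap_fraction > 0 ||
             r$total_overlap_area > 0 ||
             r$contact_regions > 0) {
    1L
  } else {
    0L
  }
  structure(g, class = "trauma_grade")
}

.grade_labels <- c("0", "I", "II", "III", "IV")

#' @export
print.trauma_grade <- function(x, ...) {
  cat(sprintf("trauma risk grade %s\n", .grade_labels[unclass(x) + 1L]))
  invisible(x)
}

#' @export
format.trauma_grade <- function(x, ...) .grade_labels[unclass(x) + 1L]

#' Normalized grade distribution
#'
#' Five-bin histogram of trauma-risk grades normalized by the number of
#' investigated steps; sums to one.
#'
#' @param grades vector of grades (integers 0..4 or `trauma_grade`s).
#' @return named numeric vector over grades 0, I, II, III, IV.
#' @export
grade_distribution <- function(grades) {
  g <- as.integer(unlist(grades))
  if (!length(g)) {
    stop(errorCondition("cannot build a grade distribution from zero grades",
                        class = c("cochsim_invalid_input", "error")))
  }
  if (any(g < 0 | g > 4)) {
    stop(errorCondition("grades must lie in 0..4",
                        class = c("cochsim_invalid_input", "error")))
  }
  h <- tabulate(g + 1L, nbins = 5L) / length(g)
  names(h) <- .grade_labels
  h
}
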