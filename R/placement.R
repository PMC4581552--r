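# Rigid placement kinematics. A pose is (dx, dy, dphi): feed along -x
# (positive = deeper), lateral offset, and a rotation about the cochleostomy.

#' Insertion pose
#'
#' @param dx feed along -x, mm; positive values insert deeper.
#' @param dy lateral offset, mm.
#' @param dphi rotation about the cochleostomy point, degrees.
#' @return an `insertion_pose`.
#' @export
insertion_pose <- function(dx = 0, dy = 0, dphi = 0) {
  structure(list(dx = dx, dy = dy, dphi = dphi), class = "insertion_pose")
}

#' Place an electrode outline relative to the cochlea
#'
#' Applies the rigid transform of a pose: rotation by `dphi` about the
#' cochleostomy point, then translation by (-dx, dy). Areas and arc lengths
#' are preserved exactly.
#'
#' @param x a `shape_state` (the outline is built first) or an
#'   `electrode_outline`.
#' @param pose an `insertion_pose` (or list with dx, dy, dphi).
#' @param cochleostomy length-2 pivot point, mm (default origin).
#' @param outline_config passed to [build_outline()] when `x` is a state.
#' @return the placed `electrode_outline`.
#' @export
place_electrode <- function(x, pose, cochleostomy = c(0, 0),
                            outline_config = list()) {
  outline <- if (inherits(x, "electrode_outline")) x else
    build_outline(x, outline_config)
  tf <- function(xy) {
    out <- rotate_about(xy, pose$dphi, cochleostomy)
    out[, 1] <- out[, 1] - pose$dx
    out[, 2] <- out[, 2] + pose$dy
    out
  }
  a <- pose$dphi * pi / 180
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  outline$polygon <- tf(outline$polygon)
  outline$tip_region <- tf(outline$tip_region)
  outline$stations <- tf(outline$stations)
  outline$normals <- outline$normals %*% t(rot)
  outline$tip_dir <- drop(rot %*% outline$tip_dir)
  outline$pose <- pose
  outline
}
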