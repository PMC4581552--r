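# Optional figures (ggplot2, Suggests): curling profiles, grade
# histograms, and per-step parameter profiles of an insertion plan.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop(errorCondition("ggplot2 is required for plotting",
                        class = c("cochsim_missing_suggests", "error")))
  }
}

#' Plot curling-profile curves (tip trajectories) of several arrays
#'
#' @param profiles list of `curling_profile`s.
#' @return a ggplot object.
#' @export
plot_curling_profiles <- function(profiles) {
  need_ggplot()
  df <- do.call(rbind, lapply(profiles, function(p) {
    tr <- curling_profile_curve(p)
    data.frame(label = p$label, x = tr[, 1], y = tr[, 2])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                   colour = label)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "array",
                  title = "Curling profiles (tip trajectories)")
}

#' Plot normalized grade histograms of one or more traces
#'
#' @param traces named list of `simulation_trace`s (names used as facets).
#' @return a ggplot object.
#' @export
plot_grade_histograms <- function(traces) {
  need_ggplot()
  df <- do.call(rbind, lapply(names(traces), function(nm) {
    h <- traces[[nm]]$histogram
    data.frame(run = nm, grade = factor(names(h), levels = names(h)),
               share = as.numeric(h))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = grade, y = share)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~run) +
    ggplot2::labs(x = "trauma-risk grade",
                  y = "share of investigated steps")
}

#' Plot the per-step parameter profiles of an insertion plan
#'
#' dx(s), dy(s) and dphi(s), the exportable summaries of an optimized
#' insertion.
#'
#' @param plan an `insertion_plan`.
#' @return a ggplot object.
#' @export
plot_parameter_profiles <- function(plan) {
  need_ggplot()
  st <- plan$steps
  df <- rbind(
    data.frame(s = st$s, value = st$dx, parameter = "dx (mm)"),
    data.frame(s = st$s, value = st$dy, parameter = "dy (mm)"),
    data.frame(s = st$s, value = st$dphi, parameter = "dphi (deg)"))
  ggplot2::ggplot(df, ggplot2::aes(x = s, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "stylet extraction s (mm)", y = NULL,
                  title = plan$strategy)
}

utils::globalVariables(c("x", "y", "label", "grade", "share", "run", "s",
                         "value", "parameter"))
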