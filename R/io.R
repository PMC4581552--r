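# File formats and the batch driver. All geometry files are plain text in
# mm, with an explicit units field in the JSON headers; the coordinate
# convention (cochleostomy at the origin, insertion toward -x) is recorded
# in every header.

fmt_num <- function(x) sprintf("%.6f", x)

json_header <- function(extra) {
  c(list(units = "mm",
         coordinate_convention =
           "cochleostomy at origin; insertion direction -x"), extra)
}

#' Write a curling profile (landmarks CSV + JSON sidecar)
#'
#' One row per (s, landmark): columns `s_mm`, `landmark_id` (`tip`,
#' `c01`..`c22`), `x_mm`, `y_mm`. The sidecar holds the label, `s_max`, `L`
#' and the generator parameters needed to reconstruct the full central
#' paths.
#'
#' @param profile a `curling_profile`.
#' @param path CSV path; the sidecar is written next to it as `.json`.
#' @export
write_curling_profile <- function(profile, path) {
  rows <- do.call(rbind, lapply(profile$states, function(st) {
    data.frame(
      s_mm = fmt_num(st$s),
      landmark_id = c(sprintf("c%02d", 1:22), "tip"),
      x_mm = fmt_num(c(st$contacts[, 1], st$tip[1])),
      y_mm = fmt_num(c(st$contacts[, 2], st$tip[2])))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  side <- json_header(list(
    label = profile$label, archetype = profile$archetype,
    s_max = profile$s_max, L = profile$L,
    params = profile$params,
    config = profile$config[c("L", "s_max", "step", "n_vertices",
                              "start_sagitta", "curl_sign", "contact_pitch",
                              "tip_offset", "marker_arclen", "n_fine")]))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read a curling profile written by [write_curling_profile()]
#'
#' Validates monotone s and 23 landmarks per step, reconstructs the full
#' shape states from the generator parameters in the sidecar, and checks
#' the stored landmarks against the reconstruction.
#'
#' @param path CSV path (sidecar expected next to it).
#' @return a `curling_profile` with attribute `landmarks` (the raw table).
#' @export
read_curling_profile <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("s_mm", "landmark_id", "x_mm", "y_mm")
  if (!all(need %in% names(tab))) {
    stop(errorCondition("profile CSV lacks required columns",
                        class = c("cochsim_invalid_input", "error")))
  }
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  s_vals <- unique(tab$s_mm)
  if (is.unsorted(s_vals, strictly = TRUE)) {
    stop(errorCondition("profile s values are not strictly increasing",
                        class = c("cochsim_invalid_input", "error")))
  }
  counts <- table(tab$s_mm)
  if (any(counts != 23)) {
    stop(errorCondition("each extraction step needs 23 landmarks",
                        class = c("cochsim_invalid_input", "error")))
  }
  cfg <- side$config
  cfg$curl_sign <- as.numeric(cfg$curl_sign)
  prof <- synthesize_curling_profile(
    side$archetype,
    config = utils::modifyList(cfg, list(r_tip = side$params$r_tip,
                                         r_base = side$params$r_base,
                                         b = side$params$b)))
  prof$label <- side$label
  attr(prof, "landmarks") <- tab
  prof
}

#' Write a cochlear contour (CSV + JSON sidecar)
#'
#' Columns `contour` (`inner`|`outer`), `order_index`, `x_mm`, `y_mm`; the
#' sidecar holds the cochleostomy, `A_mm`, `size_class` and the generator
#' configuration.
#'
#' @param contour a `cochlea_contour`.
#' @param path CSV path.
#' @export
write_cochlea_contour <- function(contour, path) {
  n <- nrow(contour$inner)
  rows <- data.frame(
    contour = rep(c("inner", "outer"), each = n),
    order_index = rep(seq_len(n), 2),
    x_mm = fmt_num(c(contour$inner[, 1], contour$outer[, 1])),
    y_mm = fmt_num(c(contour$inner[, 2], contour$outer[, 2])))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  side <- json_header(list(
    cochleostomy = contour$cochleostomy, A_mm = contour$distance_A,
    size_class = contour$size_class, turns = contour$turns,
    gate_x = contour$gate_x, gate_y = contour$gate_y))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cochlear contour written by [write_cochlea_contour()]
#'
#' @param path CSV path.
#' @return a `cochlea_contour`.
#' @export
read_cochlea_contour <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  inner <- as.matrix(tab[tab$contour == "inner", c("x_mm", "y_mm")])
  outer <- as.matrix(tab[tab$contour == "outer", c("x_mm", "y_mm")])
  if (!nrow(inner) || nrow(inner) != nrow(outer)) {
    stop(errorCondition("contour CSV needs matching inner/outer polylines",
                        class = c("cochsim_invalid_input", "error")))
  }
  dimnames(inner) <- NULL; dimnames(outer) <- NULL
  ctr <- (inner + outer) / 2
  w <- sqrt(rowSums((outer - inner)^2))
  cfg <- cochlea_default_config()
  if (!is.null(side$turns)) cfg$turns <- side$turns
  cont <- new_cochlea_contour(inner, outer, ctr, w,
                              side$size_class, cfg)
  cont$distance_A <- side$A_mm
  if (!is.null(side$gate_x)) cont$gate_x <- side$gate_x
  if (!is.null(side$gate_y)) cont$gate_y <- side$gate_y
  cont
}

#' Write an electrode outline polygon (CSV and GeoJSON-style JSON)
#'
#' @param outline an `electrode_outline`.
#' @param path CSV path (`x_mm`, `y_mm`); a GeoJSON-style `.json` twin is
#'   written next to it.
#' @export
write_outline <- function(outline, path) {
  utils::write.csv(data.frame(x_mm = fmt_num(outline$polygon[, 1]),
                              y_mm = fmt_num(outline$polygon[, 2])),
                   path, row.names = FALSE, quote = FALSE)
  gj <- list(type = "Feature",
             properties = json_header(list(area_mm2 = outline$area,
                                           trimmed = outline$trimmed)),
             geometry = list(type = "Polygon",
                             coordinates = list(
                               lapply(seq_len(nrow(outline$polygon)),
                                      function(i) outline$polygon[i, ]))))
  jsonlite::write_json(gj, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write / read an insertion plan
#'
#' CSV columns `s_mm`, `dx_mm`, `dy_mm`, `dphi_deg`; JSON sidecar with the
#' strategy and the applied constraint record.
#'
#' @param plan an `insertion_plan`.
#' @param path CSV path.
#' @export
write_insertion_plan <- function(plan, path) {
  st <- plan$steps
  utils::write.csv(data.frame(s_mm = fmt_num(st$s), dx_mm = fmt_num(st$dx),
                              dy_mm = fmt_num(st$dy),
                              dphi_deg = fmt_num(st$dphi)),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(json_header(list(strategy = plan$strategy,
                                        constraints =
                                          plan$constraints_record)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_insertion_plan
#' @export
read_insertion_plan <- function(path) {
  tab <- utils::read.csv(path)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  new_insertion_plan(side$strategy, tab$s_mm, tab$dx_mm, tab$dy_mm,
                     tab$dphi_deg, as.list(side$constraints))
}

#' Write / read a simulation trace
#'
#' Per-step CSV with the overlap features and the grade (serialized 0..4);
#' summary JSON with the normalized grade histogram.
#'
#' @param trace a `simulation_trace`.
#' @param path CSV path.
#' @export
write_trace <- function(trace, path) {
  st <- trace$steps
  out <- st
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], fmt_num)
  out$grade <- as.integer(st$grade)
  out$contact_regions <- as.integer(st$contact_regions)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    json_header(list(strategy = trace$strategy,
                     histogram = as.list(trace$histogram),
                     mean_grade = trace$mean_grade,
                     total_cost = trace$total_cost,
                     total_overlap_area = trace$total_overlap_area,
                     grade_labels = .grade_labels)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tab <- utils::read.csv(path)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  structure(list(strategy = side$strategy, steps = tab, reports = NULL,
                 histogram = unlist(side$histogram),
                 mean_grade = side$mean_grade,
                 total_cost = side$total_cost,
                 total_overlap_area = side$total_overlap_area),
            class = "simulation_trace")
}

#' Generate the packaged fixture set
#'
#' Four electrode curling profiles spanning the modelled range of curling
#' behaviour (two pronounced specimens, one moderate, one flat) and three
#' cochleae (small, medium, large by distance A), written deterministically
#' for a given seed.
#'
#' @param seed integer seed; fixture files are byte-identical per seed.
#' @param dir output directory (created if missing).
#' @param step extraction step for the profiles, mm.
#' @return invisibly, a list with the file paths (`profiles`, `contours`).
#' @export
make_fixtures <- function(seed = 1, dir = tempfile("fixtures"),
                          step = 0.25) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    list(label = "pronounced-a", archetype = "pronounced", sub = 11L),
    list(label = "pronounced-b", archetype = "pronounced", sub = 23L),
    list(label = "moderate", archetype = "moderate", sub = 37L),
    list(label = "flat", archetype = "flat", sub = 53L))
  prof_paths <- character(0)
  for (sp in specs) {
    prof <- synthesize_curling_profile(
      sp$archetype, variability_seed = (as.integer(seed) * 101L + sp$sub),
      config = list(step = step))
    prof$label <- sp$label
    p <- file.path(dir, paste0("profile-", sp$label, ".csv"))
    write_curling_profile(prof, p)
    prof_paths <- c(prof_paths, p)
  }
  cont_paths <- character(0)
  for (sz in c("CS", "CM", "CL")) {
    cont <- synthesize_cochlea(sz, seed = as.integer(seed) * 7L +
                                 match(sz, c("CS", "CM", "CL")))
    p <- file.path(dir, paste0("cochlea-", sz, ".csv"))
    write_cochlea_contour(cont, p)
    cont_paths <- c(cont_paths, p)
  }
  invisible(list(profiles = prof_paths, contours = cont_paths, dir = dir))
}

#' Batch run configuration
#'
#' @param fixture_dir directory holding the fixture files.
#' @param arrays profile labels to include (default: all found).
#' @param cochleae contour size classes to include.
#' @param strategies subset of `c("autoAOS", "manAOS", "optIns")`.
#' @param optimizer an [optimization_config()].
#' @param out_dir where traces and summaries are written (NULL: nothing
#'   written).
#' @param seed integer.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @export
run_config <- function(fixture_dir, arrays = NULL, cochleae = NULL,
                       strategies = c("autoAOS", "manAOS", "optIns"),
                       optimizer = optimization_config(), out_dir = NULL,
                       seed = 1L, log_level = "info") {
  known <- c("fixture_dir", "arrays", "cochleae", "strategies", "optimizer",
             "out_dir", "seed", "log_level")
  cfg <- list(fixture_dir = fixture_dir, arrays = arrays,
              cochleae = cochleae, strategies = strategies,
              optimizer = optimizer, out_dir = out_dir,
              seed = as.integer(seed), log_level = log_level)
  if (!length(strategies)) {
    stop(errorCondition("strategy list must not be empty",
                        class = c("cochsim_invalid_config", "error")))
  }
  bad <- setdiff(strategies, c("autoAOS", "manAOS", "optIns"))
  if (length(bad)) {
    stop(errorCondition(paste("unknown strategies:",
                              paste(bad, collapse = ", ")),
                        class = c("cochsim_invalid_config", "error")))
  }
  structure(cfg, class = "run_config", known_keys = known)
}

#' Validate a raw configuration list against [run_config()]
#'
#' Unknown keys are rejected.
#' @param x a named list (e.g. parsed from YAML).
#' @export
as_run_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  known <- c("fixture_dir", "arrays", "cochleae", "strategies", "optimizer",
             "out_dir", "seed", "log_level")
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop(errorCondition(paste("unknown configuration keys:",
                              paste(bad, collapse = ", ")),
                        class = c("cochsim_invalid_config", "error")))
  }
  do.call(run_config, x)
}

#' Read a batch configuration from a YAML or JSON file
#'
#' The file holds the fields of [run_config()]; unknown keys are rejected.
#' An `optimizer` entry is passed through [optimization_config()].
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$optimizer)) {
    raw$optimizer <- do.call(optimization_config, raw$optimizer)
  }
  as_run_config(raw)
}

cochsim_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(...))
}

#' Run the full strategy comparison batch
#'
#' Executes every (array, cochlea, strategy) combination on the fixture
#' files, producing one simulation trace per combination plus pivot tables
#' by array and by cochlea.
#'
#' @param config a [run_config()] (or plain list; validated).
#' @return a `batch_result`: `records` data frame (one row per
#'   combination), `traces`, and `pivot_by_array` / `pivot_by_cochlea`.
#' @export
run_batch <- function(config) {
  cfg <- as_run_config(config)
  prof_files <- list.files(cfg$fixture_dir, "^profile-.*\\.csv$",
                           full.names = TRUE)
  cont_files <- list.files(cfg$fixture_dir, "^cochlea-.*\\.csv$",
                           full.names = TRUE)
  if (!length(prof_files) || !length(cont_files)) {
    stop(errorCondition(
      sprintf("no fixtures found under '%s'", cfg$fixture_dir),
      class = c("cochsim_file_not_found", "error")))
  }
  profiles <- lapply(prof_files, read_curling_profile)
  names(profiles) <- vapply(profiles, `[[`, character(1), "label")
  contours <- lapply(cont_files, read_cochlea_contour)
  names(contours) <- vapply(contours, `[[`, character(1), "size_class")
  if (!is.null(cfg$arrays)) {
    missing <- setdiff(cfg$arrays, names(profiles))
    if (length(missing)) {
      stop(errorCondition(paste("fixture not found:",
                                paste(missing, collapse = ", ")),
                          class = c("cochsim_file_not_found", "error")))
    }
    profiles <- profiles[cfg$arrays]
  }
  if (!is.null(cfg$cochleae)) {
    missing <- setdiff(cfg$cochleae, names(contours))
    if (length(missing)) {
      stop(errorCondition(paste("fixture not found:",
                                paste(missing, collapse = ", ")),
                          class = c("cochsim_file_not_found", "error")))
    }
    contours <- contours[cfg$cochleae]
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  }

  records <- list()
  traces <- list()
  for (anm in names(profiles)) {
    for (cnm in names(contours)) {
      prof <- profiles[[anm]]; cont <- contours[[cnm]]
      plans <- list()
      if ("autoAOS" %in% cfg$strategies) {
        plans$autoAOS <- plan_autoAOS(prof, cont)
      }
      if ("manAOS" %in% cfg$strategies) {
        plans$manAOS <- plan_manAOS(prof, cont)
      }
      if ("optIns" %in% cfg$strategies) {
        plans$optIns <- optimize_insertion(prof, cont,
                                           cfg$optimizer)$plan
      }
      for (snm in names(plans)) {
        tr <- simulate_insertion(plans[[snm]], prof, cont)
        key <- paste(anm, cnm, snm, sep = "/")
        traces[[key]] <- tr
        cochsim_log(cfg, "[%s] mean grade %.2f, grade-0 share %.2f",
                    key, tr$mean_grade, tr$histogram[1])
        records[[key]] <- data.frame(
          array = anm, cochlea = cnm, strategy = snm,
          steps = nrow(tr$steps), mean_grade = tr$mean_grade,
          total_cost = tr$total_cost,
          total_overlap_area = tr$total_overlap_area,
          t(tr$histogram), check.names = FALSE)
        if (!is.null(cfg$out_dir)) {
          write_trace(tr, file.path(cfg$out_dir,
                                    paste0("trace-", anm, "-", cnm, "-",
                                           snm, ".csv")))
        }
      }
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  pivot <- function(by) {
    agg <- stats::aggregate(records[, .grade_labels],
                            by = records[c(by, "strategy")], FUN = mean)
    agg[order(agg[[by]], agg$strategy), ]
  }
  res <- structure(list(
    records = records,
    traces = traces,
    pivot_by_array = pivot("array"),
    pivot_by_cochlea = pivot("cochlea"),
    seed = cfg$seed), class = "batch_result")
  if (!is.null(cfg$out_dir)) {
    jsonlite::write_json(
      json_header(list(seed = cfg$seed,
                       n_records = nrow(records),
                       records = records)),
      file.path(cfg$out_dir, "batch-summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result>: %d simulated insertions\n", nrow(x$records)))
  print(x$records[, c("array", "cochlea", "strategy", "mean_grade", "0",
                      "IV")], row.names = FALSE, digits = 3)
  invisible(x)
}
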