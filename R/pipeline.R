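## Orchestration: simulate -> fit -> register -> validate, emitting a
## per-subject mean/SD/max error table with an overall "Mean" row per
## reference type (unweighted mean across subjects).

#' Run a simulate-fit-validate experiment
#'
#' For every subject of a truth scenario: fits the morphable model to the
#' subject's (noisy) landmarks, reconstructs the mesh, registers it by
#' trimmed similarity ICP to two degraded references derived from the
#' subject's true mesh — a depth-sensor-like reference (`kinect`) and a
#' smooth-bias reference (`mri`) — and computes the symmetric
#' surface-distance report against each. Per-subject failures are recorded
#' in the report, not raised.
#'
#' @param scenario a `truth_scenario` from [make_scenario()].
#' @param config a [fit_config()].
#' @param references character subset of `c("kinect", "mri")`.
#' @param posture pass-through posture tag recorded in every row.
#' @return an object of class `experiment_report`: a `data.frame` with
#'   columns `method`, `subject`, `posture`, `reference`, `mean_mm`,
#'   `sd_mm`, `max_mm`, `n_points`, including one `subject = "Mean"` row
#'   per reference (arithmetic mean of the subject means), plus attributes
#'   `errors` (per-subject failure messages) and `seed`.
#' @export
run_experiment <- function(scenario, config = fit_config(),
                           references = c("kinect", "mri"),
                           posture = "neutral") {
  if (!inherits(scenario, "truth_scenario"))
    stop("'scenario' must be a truth_scenario", call. = FALSE)
  references <- match.arg(references, several.ok = TRUE)
  rows <- list(); errors <- character(0)
  for (i in seq_along(scenario$subjects)) {
    subj <- scenario$subjects[[i]]
    res <- tryCatch({
      fit <- fit_landmarks(scenario$model, subj$landmarks, config)
      recon <- predict(fit, type = "mesh")
      out <- list()
      for (ref in references) {
        refmesh <- degrade_mesh(subj$mesh, scenario$mesh_noise_sd,
                                seed = derive_seed(scenario$seed,
                                                   1000L + 10L * i +
                                                     match(ref, c("kinect", "mri"))),
                                mode = ref)
        tr <- rigid_register(recon, refmesh, allow_scale = TRUE)
        rep_ <- distance_report(apply_transform(recon, tr), refmesh,
                                direction = "symmetric")
        out[[ref]] <- data.frame(method = "landmark_fit",
                                 subject = sprintf("S%02d", i),
                                 posture = posture, reference = ref,
                                 mean_mm = rep_$mean, sd_mm = rep_$sd,
                                 max_mm = rep_$max, n_points = rep_$n_points,
                                 stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }, error = function(e) {
      errors <<- c(errors, sprintf("subject %d: %s", i, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(method = character(0), subject = character(0),
               posture = character(0), reference = character(0),
               mean_mm = numeric(0), sd_mm = numeric(0),
               max_mm = numeric(0), n_points = integer(0))
  for (ref in references) {
    sub <- df[df$reference == ref & df$subject != "Mean", , drop = FALSE]
    if (nrow(sub))
      df <- rbind(df, data.frame(method = "landmark_fit", subject = "Mean",
                                 posture = posture, reference = ref,
                                 mean_mm = mean(sub$mean_mm),
                                 sd_mm = mean(sub$sd_mm),
                                 max_mm = mean(sub$max_mm),
                                 n_points = sum(sub$n_points),
                                 stringsAsFactors = FALSE))
  }
  rownames(df) <- NULL
  structure(df, errors = errors, seed = scenario$seed,
            class = c("experiment_report", "data.frame"))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Surface-error report (symmetric point-to-surface, mm)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  errs <- attr(x, "errors")
  if (length(errs))
    cat("failures:\n ", paste(errs, collapse = "\n  "), "\n")
  invisible(x)
}

#' Write / read an experiment report
#'
#' JSON (`.json`) or CSV (`.csv`); numeric values are written at full
#' precision so the round trip is lossless.
#'
#' @param report an `experiment_report`.
#' @param path output path; extension selects the format.
#' @return `path` invisibly; `read_report()` returns the report.
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(report)
  if (ext == "json") {
    jsonlite::write_json(list(rows = df, errors = attr(report, "errors"),
                              seed = attr(report, "seed")),
                         path, digits = NA, auto_unbox = TRUE)
  } else if (ext == "csv") {
    utils::write.csv(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
  } else stop("unsupported report format: '.", ext, "'", call. = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(obj$rows)
    structure(df, errors = as.character(unlist(obj$errors)), seed = obj$seed,
              class = c("experiment_report", "data.frame"))
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    structure(df, errors = character(0), seed = NA_integer_,
              class = c("experiment_report", "data.frame"))
  } else stop("unsupported report format: '.", ext, "'", call. = FALSE)
}

## ---- landmark file I/O -----------------------------------------------------

#' Read / write 2D landmarks
#'
#' CSV files have columns `id,x,y` (pixel coordinates, origin top-left);
#' JSON files are an array of `{id, x, y}` objects.
#'
#' @param path file path (`.csv` or `.json`).
#' @return a `landmarks2d`.
#' @export
read_landmarks <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "csv") utils::read.csv(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported landmark format: '.", ext, "'", call. = FALSE)
  if (!all(c("id", "x", "y") %in% names(df)))
    stop("landmark file must have fields id, x, y", call. = FALSE)
  landmarks2d(cbind(df$x, df$y), df$id)
}

#' @rdname read_landmarks
#' @param landmarks a `landmarks2d`.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(id = landmarks$ids, x = landmarks$points[, 1],
                   y = landmarks$points[, 2])
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv")
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  else if (ext == "json")
    jsonlite::write_json(df, path, digits = NA)
  else stop("unsupported landmark format: '.", ext, "'", call. = FALSE)
  invisible(path)
}

#' Read a landmark-to-vertex map
#'
#' JSON object mapping landmark id to 0-based vertex index (the common
#' interchange convention); returned as a named integer vector of 1-based
#' vertex indices ready for `build_morphable_model()`.
#'
#' @param path JSON file path.
#' @return named integer vector (names = landmark ids, values = 1-based
#'   vertex indices).
#' @export
read_landmark_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as.integer(unlist(obj)) + 1L
  names(out) <- names(obj)
  out
}
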