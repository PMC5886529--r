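#' Write a trajectory dataset to disk
#'
#' Writes the trajectory CSV dialect (`trial_id,t_ms,x_cm,depth_cm`, one row
#' per sample) plus a JSON sidecar of per-trial metadata next to it
#' (`<path stem>_meta.json`). Positions round-trip at full double precision.
#'
#' @param dataset a `reach_dataset`.
#' @param path CSV file path.
#' @return the CSV path, invisibly.
#' @export
write_trajectories <- function(dataset, path) {
  stopifnot(nrow(dataset$trajectories) > 0)
  readr::write_csv(dataset$trajectories, path)
  meta_list <- lapply(seq_len(nrow(dataset$meta)), function(i) {
    row <- as.list(dataset$meta[i, setdiff(names(dataset$meta), "trial_id")])
    row
  })
  names(meta_list) <- as.character(dataset$meta$trial_id)
  jsonlite::write_json(meta_list, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.csv$", "", path), "_meta.json")
}

#' Read a trajectory dataset from disk
#'
#' Parses the trajectory CSV dialect and, when present, the JSON metadata
#' sidecar. Validates the header and per-trial time monotonicity.
#'
#' @param path CSV file path.
#' @return a `reach_dataset`; `meta_present` is `FALSE` when the sidecar is
#'   missing (metadata then holds only trial ids).
#' @export
read_trajectories <- function(path) {
  traj <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("trial_id", "t_ms", "x_cm", "depth_cm")
  if (!identical(names(traj)[seq_along(required)], required)) {
    stop(sprintf("malformed header in %s: expected '%s'", path,
                 paste(required, collapse = ",")), call. = FALSE)
  }
  for (id in unique(traj$trial_id)) {
    tt <- traj$t_ms[traj$trial_id == id]
    bad <- which(diff(tt) <= 0)
    if (length(bad) > 0) {
      row <- which(traj$trial_id == id)[bad[1] + 1]
      stop(sprintf("non-monotone t_ms in trial %s (data row %d)",
                   as.character(id), row), call. = FALSE)
    }
  }
  sc <- sidecar_path(path)
  meta_present <- file.exists(sc)
  if (meta_present) {
    ml <- jsonlite::read_json(sc)
    meta <- dplyr::bind_rows(lapply(names(ml), function(id) {
      row <- ml[[id]]
      row <- lapply(row, function(v) if (is.null(v)) NA else v)
      tibble::as_tibble(c(list(trial_id = as.integer(id)), row))
    }))
  } else {
    meta <- tibble::tibble(trial_id = unique(traj$trial_id))
  }
  ids <- meta$trial_id
  norm <- matrix(NA_real_, length(ids), 101)
  split_tr <- split(traj, traj$trial_id)
  for (i in seq_along(ids)) {
    tr <- split_tr[[as.character(ids[i])]]
    if (!is.null(tr) && nrow(tr) >= 2) {
      norm[i, ] <- normalize_time(tr$t_ms, tr$x_cm)
    }
  }
  structure(list(trajectories = traj, meta = meta, norm = norm,
                 norm_liftoff = norm,
                 design = NULL, seed = NA, meta_present = meta_present),
            class = "reach_dataset")
}

#' Write a fit result to disk
#'
#' Serializes a [fit_threshold_free()] / [fit_ddm()] result as `fit.json`
#' (best parameters, loss, evaluation count, seed, flags) plus the full
#' evaluation trace as `trace.csv`.
#'
#' @param fit a `fit_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit_result <- function(fit, dir) {
  stopifnot(inherits(fit, "fit_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  best <- unclass(fit$best_params)
  jsonlite::write_json(
    list(best_params = best[!vapply(best, is.null, logical(1))],
         loss = fit$loss, loss_refit = as.list(fit$loss_refit),
         n_evaluations = fit$n_evaluations, seed = fit$seed,
         converged = fit$converged, unidentifiable = fit$unidentifiable,
         free = fit$free),
    file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(fit$trace, file.path(dir, "trace.csv"))
  invisible(dir)
}

#' Write per-ratio summary table
#'
#' CSV with columns `ratio,hp_cm,accuracy,mean_rt_ms,com_rate`.
#'
#' @param summary tibble from [flip_and_average()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_summary <- function(summary, path) {
  cols <- c("ratio", "hp_cm", "accuracy", "mean_rt_ms", "com_rate")
  readr::write_csv(summary[, cols], path)
  invisible(path)
}
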