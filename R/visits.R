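#' Worker trajectory table
#'
#' Validates and normalises a table of trajectory fixes. Fixes are
#' time-ordered per worker; the nominal sampling rate is 2 frames per
#' second but gaps are allowed. Invalid fixes (lost tag) carry no usable
#' position.
#'
#' @param df data.frame with columns `worker_id`, `time_s`, `x_mm`,
#'   `y_mm`, and optionally `orientation_rad`, `side` (default 1) and
#'   `valid` (default `TRUE`).
#' @return The normalised data.frame with class `trajectories`.
#' @export
trajectories <- function(df) {
  req <- c("worker_id", "time_s", "x_mm", "y_mm")
  if (!all(req %in% names(df)))
    stop("trajectory table needs columns ", paste(req, collapse = ", "))
  n <- nrow(df)
  if (is.null(df$orientation_rad)) df$orientation_rad <- rep(NA_real_, n)
  if (is.null(df$side)) df$side <- rep(1L, n)
  if (is.null(df$valid)) df$valid <- rep(TRUE, n)
  df <- df[order(df$worker_id, df$time_s), , drop = FALSE]
  dup <- stats::ave(df$time_s, df$worker_id,
                    FUN = function(t) c(1, diff(t)))
  if (any(dup <= 0)) stop("fix times must be strictly increasing per worker")
  rownames(df) <- NULL
  class(df) <- c("trajectories", "data.frame")
  df
}

#' Read / write trajectory CSV
#'
#' Standard trajectory file: CSV with header
#' `worker_id,time_s,x_mm,y_mm,orientation_rad,side,valid`.
#'
#' @param path file path.
#' @return [trajectories()] data.frame.
#' @export
read_trajectories_csv <- function(path) {
  trajectories(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_trajectories_csv
#' @param traj a `trajectories` table.
#' @export
write_trajectories_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("worker_id", "time_s", "x_mm",
                                           "y_mm", "orientation_rad",
                                           "side", "valid")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Extract site-visit events from trajectories
#'
#' A visit to a site opens when the worker's fix first falls in the site
#' and closes when a subsequent valid fix falls elsewhere (or the track is
#' lost), regardless of the time spent inside. To stop workers parked on a
#' border from accruing many single-frame visits, a re-entry to the same
#' site is merged into the previous visit unless at least `refractory`
#' seconds elapsed between the end of the previous visit and the start of
#' the next. Crossings are detected at fix resolution (2 fps); a side
#' switch is a site change.
#'
#' @param traj a [trajectories()] table.
#' @param grid a `hex_grid`.
#' @param refractory minimum gap (s) for a re-entry to count as a new
#'   visit; default 20.
#' @return data.frame of visit events: `worker_id`, `site_id`, `t_start`,
#'   `t_end`, sorted by worker, site, time.
#' @export
extract_visits <- function(traj, grid, refractory = 20) {
  if (nrow(traj) == 0)
    return(data.frame(worker_id = character(), site_id = integer(),
                      t_start = numeric(), t_end = numeric()))
  ok <- traj$valid & is.finite(traj$x_mm) & is.finite(traj$y_mm)
  t <- traj[ok, , drop = FALSE]
  if (nrow(t) == 0)
    return(data.frame(worker_id = character(), site_id = integer(),
                      t_start = numeric(), t_end = numeric()))
  site <- locate_site(grid, t$x_mm, t$y_mm, t$side)
  keep <- !is.na(site)
  t <- t[keep, , drop = FALSE]; site <- site[keep]
  if (nrow(t) == 0)
    return(data.frame(worker_id = character(), site_id = integer(),
                      t_start = numeric(), t_end = numeric()))
  # raw runs of consecutive fixes in the same site for the same worker;
  # tracking gaps longer than the refractory window close the run (a
  # shorter gap keeps it open: the merge step would rejoin it anyway)
  wid <- as.character(t$worker_id)
  gap <- diff(t$time_s)
  new_run <- c(TRUE, wid[-1] != wid[-length(wid)] |
                 site[-1] != site[-length(site)] |
                 gap >= refractory)
  run <- cumsum(new_run)
  raw <- data.frame(worker_id = wid[new_run], site_id = site[new_run],
                    t_start = t$time_s[new_run],
                    t_end = as.numeric(tapply(t$time_s, run, max)[
                      as.character(run[new_run])]))
  rownames(raw) <- NULL
  # merge re-entries within the refractory window, per (worker, site)
  o <- order(raw$worker_id, raw$site_id, raw$t_start)
  raw <- raw[o, , drop = FALSE]
  grp <- paste(raw$worker_id, raw$site_id, sep = "\r")
  prev_end <- c(-Inf, raw$t_end[-nrow(raw)])
  same <- c(FALSE, grp[-1] == grp[-length(grp)])
  new_visit <- !(same & (raw$t_start - prev_end) < refractory)
  vid <- cumsum(new_visit)
  out <- data.frame(
    worker_id = raw$worker_id[new_visit],
    site_id = raw$site_id[new_visit],
    t_start = raw$t_start[new_visit],
    t_end = as.numeric(tapply(raw$t_end, vid, max)[
      as.character(vid[new_visit])]))
  out <- out[order(out$worker_id, out$site_id, out$t_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count visits per worker and site
#'
#' @param events visit events from [extract_visits()].
#' @return integer matrix of visit counts, workers x sites, with dimnames.
#' @export
count_visits <- function(events) {
  if (nrow(events) == 0) stop("no visit events to count")
  tab <- table(worker = as.character(events$worker_id),
               site = events$site_id)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(worker = rownames(tab), site = colnames(tab)))
  m
}

#' Count side switches in a worker's trajectory
#'
#' Number of consecutive valid-fix pairs whose comb-face labels differ.
#'
#' @param traj a [trajectories()] table (one or more workers).
#' @return named integer vector, one entry per worker.
#' @export
count_side_switches <- function(traj) {
  t <- traj[traj$valid, , drop = FALSE]
  if (nrow(t) == 0) return(stats::setNames(integer(0), character(0)))
  vapply(split(t$side, as.character(t$worker_id)),
         function(s) sum(diff(as.integer(s)) != 0L), integer(1))
}

#' Write visit events to CSV
#' @param events visit events data.frame.
#' @param path output path.
#' @export
write_visits_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
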