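#' Framewise displacement from rigid-body motion parameters
#'
#' Summarizes per-frame head motion as framewise displacement (FD): the
#' L1 norm of the frame-to-frame change in the six rigid-body realignment
#' parameters, with rotations converted to millimeters of arc on a sphere
#' approximating the head.
#'
#' \deqn{FD_t = \sum |\Delta d_{x,y,z}| + r \sum |\Delta \theta_{x,y,z}|}
#'
#' The first frame has no predecessor and its FD is defined as 0.
#'
#' @param motion_params numeric matrix, frames x 6: three translations in
#'   mm followed by three rotations in radians.
#' @param head_radius_mm sphere radius used to convert rotations to arc
#'   length; 50 mm is the field-standard convention.
#' @return numeric vector of per-frame FD in mm (class `"fd_trace"`).
#' @export
compute_fd <- function(motion_params, head_radius_mm = 50) {
  motion_params <- as.matrix(motion_params)
  if (ncol(motion_params) != 6L) {
    stop_nla("nla_bad_motion", "motion_params must have 6 columns (3 translations mm, 3 rotations rad)")
  }
  if (nrow(motion_params) < 1L) stop_nla("nla_bad_motion", "need at least one frame")
  stopifnot(head_radius_mm > 0)
  d <- apply(motion_params, 2L, function(x) c(0, diff(x)))
  if (nrow(motion_params) == 1L) d <- matrix(0, 1L, 6L)
  fd <- rowSums(abs(d[, 1:3, drop = FALSE])) +
    head_radius_mm * rowSums(abs(d[, 4:6, drop = FALSE]))
  structure(as.numeric(fd), class = "fd_trace")
}

#' Motion censoring of high-FD frames
#'
#' Frames with FD above `fd_threshold_mm` are censored (dropped, not
#' interpolated). A subject retaining fewer than `min_frames` frames is
#' flagged excluded; the default of 600 frames corresponds to 8 minutes of
#' data at a repetition time of 0.8 s. FD exactly at the threshold is
#' retained (exclusion applies to FD strictly greater than the threshold).
#'
#' @param fd per-frame FD in mm (e.g. from [compute_fd()]).
#' @param fd_threshold_mm censoring threshold; default 0.2 mm.
#' @param min_frames minimum retained frames for inclusion; default 600.
#' @return list of class `"censor_result"`: `mask` (logical, TRUE =
#'   retained), `n_retained`, `excluded` (logical flag), and the settings.
#' @export
censor_frames <- function(fd, fd_threshold_mm = 0.2, min_frames = 600) {
  fd <- as.numeric(fd)
  stopifnot(fd_threshold_mm > 0, min_frames >= 0)
  if (any(!is.finite(fd)) || any(fd < 0)) {
    stop_nla("nla_bad_motion", "FD must be finite and non-negative")
  }
  mask <- fd <= fd_threshold_mm
  structure(list(
    mask = mask,
    n_retained = sum(mask),
    excluded = sum(mask) < min_frames,
    fd_threshold_mm = fd_threshold_mm,
    min_frames = min_frames
  ), class = "censor_result")
}

#' Minimum-frame threshold for a scan-time requirement
#'
#' @param minutes required minutes of retained data.
#' @param tr_s repetition time in seconds.
#' @return number of frames, rounded up.
#' @examples
#' min_frames_for(8, 0.8)  # 600
#' @export
min_frames_for <- function(minutes, tr_s) {
  stopifnot(minutes > 0, tr_s > 0)
  ceiling(minutes * 60 / tr_s)
}
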