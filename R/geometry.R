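#' Geometry configuration
#'
#' @param epsilon_coincident Minimum allowed distance, in pixels, between
#'   any two landmarks required by the same parameter. The default is
#'   relative: 1e-9 times the skull-fixed eye_back to ear_orifice distance
#'   (falling back to an absolute 1e-12 when either point is absent), so
#'   the degeneracy test itself is zoom-free.
#' @return Object of class `geometry_config`.
#' @export
geometry_config <- function(epsilon_coincident = NULL) {
  if (!is.null(epsilon_coincident) && epsilon_coincident <= 0) {
    stop("epsilon_coincident must be > 0")
  }
  structure(list(epsilon_coincident = epsilon_coincident,
                 angle_units = "degrees"),
            class = "geometry_config")
}

.geom_eps <- function(lm, cfg) {
  if (!is.null(cfg$epsilon_coincident)) return(cfg$epsilon_coincident)
  if (.lm_has(lm, c("eye_back", "ear_orifice"))) {
    1e-9 * sqrt(sum((.lm_point(lm, "eye_back") -
                     .lm_point(lm, "ear_orifice"))^2))
  } else {
    1e-12
  }
}

.dist2d <- function(a, b) sqrt(sum((a - b)^2))

.check_geometry <- function(lm, parameter, cfg = geometry_config()) {
  req <- required_landmarks(parameter)
  miss <- setdiff(req, rownames(lm$points))
  if (length(miss)) {
    stop("incomplete landmark set for ", parameter, ": missing ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  eps <- .geom_eps(lm, cfg)
  pts <- lm$points[req, , drop = FALSE]
  d <- as.matrix(stats::dist(pts))
  d[upper.tri(d, diag = TRUE)] <- Inf
  hit <- which(d <= eps, arr.ind = TRUE)
  if (nrow(hit)) {
    stop("degenerate geometry for ", parameter, ": coincident landmarks ",
         req[hit[1, 2]], " and ", req[hit[1, 1]], call. = FALSE)
  }
  invisible(TRUE)
}

#' Interior angle at a vertex
#'
#' Angle, in degrees, at `vertex` between the rays vertex->a and vertex->b.
#' Symmetric in its last two arguments and invariant under rotation,
#' translation, uniform scaling and reflection of the plane.
#'
#' @param vertex,a,b Numeric length-2 points (x, y).
#' @return Angle in degrees, in [0, 180].
#' @export
#' @examples
#' angle_at(c(0, 0), c(1, 0), c(0, 1)) # 90
angle_at <- function(vertex, a, b) {
  u <- a - vertex
  v <- b - vertex
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("degenerate geometry: ray endpoint coincides with vertex",
         call. = FALSE)
  }
  # atan2 of cross/dot is numerically stable near 0 and 180 degrees
  cr <- u[1] * v[2] - u[2] * v[1]
  dt <- sum(u * v)
  unname(atan2(abs(cr), dt) * 180 / pi)
}

#' @rdname compute_parameters
#' @export
eye_opening <- function(lm, cfg = geometry_config()) {
  lm <- landmark_set(lm)
  .check_geometry(lm, "eye_opening", cfg)
  .dist2d(.lm_point(lm, "eye_top"), .lm_point(lm, "eye_bottom")) /
    .dist2d(.lm_point(lm, "eye_front"), .lm_point(lm, "eye_back"))
}

#' @rdname compute_parameters
#' @export
ear_opening <- function(lm, cfg = geometry_config()) {
  lm <- landmark_set(lm)
  .check_geometry(lm, "ear_opening", cfg)
  bf <- .lm_point(lm, "ear_base_front")
  bb <- .lm_point(lm, "ear_base_back")
  mid <- (bf + bb) / 2
  .dist2d(bf, bb) / .dist2d(mid, .lm_point(lm, "ear_tip"))
}

#' @rdname compute_parameters
#' @export
ear_angle <- function(lm, cfg = geometry_config()) {
  lm <- landmark_set(lm)
  .check_geometry(lm, "ear_angle", cfg)
  bf <- .lm_point(lm, "ear_base_front")
  bb <- .lm_point(lm, "ear_base_back")
  mid <- (bf + bb) / 2
  ear_axis <- .lm_point(lm, "ear_tip") - mid
  face_axis <- .lm_point(lm, "ear_orifice") - .lm_point(lm, "eye_back")
  cr <- ear_axis[1] * face_axis[2] - ear_axis[2] * face_axis[1]
  dt <- sum(ear_axis * face_axis)
  unname(atan2(abs(cr), dt) * 180 / pi)
}

#' @rdname compute_parameters
#' @export
ear_position <- function(lm, cfg = geometry_config()) {
  lm <- landmark_set(lm)
  req <- c("eye_back", "ear_base_front", "ear_orifice")
  miss <- setdiff(req, rownames(lm$points))
  if (length(miss)) {
    stop("incomplete landmark set for ear_position: missing ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  eb <- .lm_point(lm, "eye_back")
  eo <- .lm_point(lm, "ear_orifice")
  # the skull-fixed denominator must be nonzero; ear_base_front may
  # legitimately coincide with eye_back (ratio 0) or ear_orifice (ratio 1)
  den <- .dist2d(eb, eo)
  if (den <= .geom_eps(lm, cfg)) {
    stop("degenerate geometry for ear_position: coincident landmarks ",
         "eye_back and ear_orifice", call. = FALSE)
  }
  .dist2d(eb, .lm_point(lm, "ear_base_front")) / den
}

#' @rdname compute_parameters
#' @export
snout_position <- function(lm, cfg = geometry_config()) {
  lm <- landmark_set(lm)
  .check_geometry(lm, "snout_position", cfg)
  angle_at(.lm_point(lm, "snout_tip"),
           .lm_point(lm, "nose_top"),
           .lm_point(lm, "lower_snout"))
}

#' @rdname compute_parameters
#' @export
mouth_position <- function(lm, cfg = geometry_config()) {
  lm <- landmark_set(lm)
  req <- c("snout_tip", "lower_lip", "eye_back")
  miss <- setdiff(req, rownames(lm$points))
  if (length(miss)) {
    stop("incomplete landmark set for mouth_position: missing ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  st <- .lm_point(lm, "snout_tip")
  eb <- .lm_point(lm, "eye_back")
  den <- .dist2d(st, eb)
  if (den <= .geom_eps(lm, cfg)) {
    stop("degenerate geometry for mouth_position: coincident landmarks ",
         "snout_tip and eye_back", call. = FALSE)
  }
  # lower_lip at snout_tip is the legitimate extreme (lip maximally forward)
  .dist2d(st, .lm_point(lm, "lower_lip")) / den
}

#' @rdname compute_parameters
#' @export
face_inclination <- function(lm, cfg = geometry_config()) {
  lm <- landmark_set(lm)
  .check_geometry(lm, "face_inclination", cfg)
  angle_at(.lm_point(lm, "eye_back"),
           .lm_point(lm, "lower_snout"),
           .lm_point(lm, "ear_orifice")) - 90
}

#' Compute the seven facial parameters from a landmark set
#'
#' The seven parameters quantify the facial regions that carry expression
#' changes in rodents (eye, ear, snout, mouth, global face shape). All are
#' pure ratios or angles over the canonical landmarks, hence invariant to
#' camera translation, rotation, zoom, and mirroring of the profile:
#'
#' \describe{
#'   \item{eye_opening}{dist(eye_top, eye_bottom) / dist(eye_front,
#'     eye_back). 1 for a perfectly round eye; smaller for a narrowed eye.}
#'   \item{ear_opening}{ear base width / (base midpoint to ear_tip).
#'     Near 1 for a fully deployed pavilion; smaller when the ear is held
#'     higher on the head.}
#'   \item{ear_angle}{angle between the ear axis (base midpoint to
#'     ear_tip) and the skull-fixed face axis (eye_back to ear_orifice);
#'     near 90 for a straight ear, decreasing as the ear tilts.}
#'   \item{ear_position}{dist(eye_back, ear_base_front) / dist(eye_back,
#'     ear_orifice); larger when the ear sits further back.}
#'   \item{snout_position}{angle at snout_tip between nose_top and
#'     lower_snout; smaller for a pointier snout.}
#'   \item{mouth_position}{dist(snout_tip, lower_lip) / dist(snout_tip,
#'     eye_back); smaller when the lower lip is brought forward.}
#'   \item{face_inclination}{angle at eye_back between lower_snout and
#'     ear_orifice, minus 90 degrees; smaller for a more convex profile.}
#' }
#'
#' @param lm A [landmark_set()] (or coercible matrix/data frame).
#' @param cfg A [geometry_config()].
#' @param partial If `TRUE`, parameters whose required landmarks are
#'   missing or degenerate are returned as `NA` with a status attribute
#'   instead of aborting.
#' @return Named numeric vector over [facial_parameters()]; in partial
#'   mode, with attribute `"status"` (`"ok"`, `"missing"`, `"degenerate"`).
#' @export
#' @examples
#' compute_parameters(make_template())
compute_parameters <- function(lm, cfg = geometry_config(), partial = FALSE) {
  lm <- landmark_set(lm)
  fns <- list(eye_opening = eye_opening, ear_opening = ear_opening,
              ear_angle = ear_angle, ear_position = ear_position,
              snout_position = snout_position,
              mouth_position = mouth_position,
              face_inclination = face_inclination)
  out <- stats::setNames(rep(NA_real_, 7L), names(fns))
  status <- stats::setNames(rep("ok", 7L), names(fns))
  for (p in names(fns)) {
    res <- tryCatch(fns[[p]](lm, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      if (!partial) stop(conditionMessage(res), call. = FALSE)
      status[p] <- if (grepl("incomplete landmark set", conditionMessage(res)))
        "missing" else "degenerate"
    } else {
      out[p] <- res
    }
  }
  if (partial) attr(out, "status") <- status
  out
}

#' Measure facial parameters for a table of frames
#'
#' Applies [compute_parameters()] to each frame of a long-format landmark
#' table and returns a frame-level parameter table with one status column
#' per parameter (`ok` / `missing` / `degenerate`).
#'
#' @param landmarks Long-format data frame as returned by
#'   [read_landmarks()] or [simulate_experiment()]: one row per
#'   (frame, landmark), with columns `frame_id`, `animal_id`,
#'   `experiment_id`, `condition`, `phase_time_s`, `excluded`,
#'   `exclusion_reason`, `side`, `landmark`, `x`, `y` (optionally
#'   `observer_id`, `confidence`).
#' @param cfg A [geometry_config()].
#' @return Data frame with one row per frame: metadata, the seven
#'   parameter columns, and `<parameter>_status` columns.
#' @export
measure_frames <- function(landmarks, cfg = geometry_config()) {
  stopifnot(is.data.frame(landmarks))
  meta_cols <- intersect(
    c("frame_id", "animal_id", "experiment_id", "condition",
      "phase_time_s", "observer_id", "excluded", "exclusion_reason", "side"),
    names(landmarks))
  split_idx <- split(seq_len(nrow(landmarks)), landmarks$frame_id)
  # preserve first-appearance frame order
  split_idx <- split_idx[unique(as.character(landmarks$frame_id))]
  rows <- lapply(split_idx, function(i) {
    sub <- landmarks[i, , drop = FALSE]
    side <- if ("side" %in% names(sub)) as.character(sub$side[1]) else "right"
    lm <- landmark_set(sub[, c("landmark", "x", "y")],
                       side = if (side %in% c("right", "left")) side else "right")
    vals <- compute_parameters(lm, cfg, partial = TRUE)
    st <- attr(vals, "status")
    meta <- sub[1, meta_cols, drop = FALSE]
    cbind(meta,
          as.data.frame(as.list(vals)),
          stats::setNames(as.data.frame(as.list(st)),
                          paste0(names(st), "_status")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
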