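#' Canonical profile landmark vocabulary
#'
#' The thirteen named points on a mouse profile from which all seven facial
#' parameters are computed. Coordinates are image (pixel) coordinates with
#' the y axis increasing downward; every downstream quantity is a ratio or
#' an angle, so the convention never reaches the outputs.
#'
#' @return Character vector of the 13 canonical landmark names.
#' @export
#' @examples
#' landmark_vocabulary()
landmark_vocabulary <- function() {
  c("eye_front", "eye_back", "eye_top", "eye_bottom",
    "ear_tip", "ear_base_front", "ear_base_back", "ear_orifice",
    "nose_top", "snout_tip", "lower_snout", "mouth_corner", "lower_lip")
}

#' Names of the seven facial parameters
#'
#' @return Character vector, in canonical order.
#' @export
facial_parameters <- function() {
  c("eye_opening", "ear_opening", "ear_angle", "ear_position",
    "snout_position", "mouth_position", "face_inclination")
}

#' Landmarks required to compute one facial parameter
#'
#' Each parameter is a pure ratio or angle over a fixed subset of the
#' canonical vocabulary; the subset is the parameter's contract: it may be
#' computed only when all of its required landmarks are present and
#' pairwise non-coincident.
#'
#' @param parameter One of [facial_parameters()].
#' @return Character vector of landmark names.
#' @export
#' @examples
#' required_landmarks("face_inclination")
required_landmarks <- function(parameter) {
  req <- list(
    eye_opening      = c("eye_top", "eye_bottom", "eye_front", "eye_back"),
    ear_opening      = c("ear_base_front", "ear_base_back", "ear_tip"),
    ear_angle        = c("ear_base_front", "ear_base_back", "ear_tip",
                         "eye_back", "ear_orifice"),
    ear_position     = c("eye_back", "ear_base_front", "ear_orifice"),
    snout_position   = c("nose_top", "snout_tip", "lower_snout"),
    mouth_position   = c("snout_tip", "lower_lip", "eye_back"),
    face_inclination = c("lower_snout", "eye_back", "ear_orifice")
  )
  if (length(parameter) != 1L || !parameter %in% names(req)) {
    stop("unknown facial parameter: ", paste(parameter, collapse = ", "),
         call. = FALSE)
  }
  req[[parameter]]
}

#' Construct a landmark set for one frame
#'
#' @param points Numeric matrix with two columns (x, y) and row names drawn
#'   from [landmark_vocabulary()], or a data frame with columns
#'   `landmark`, `x`, `y`.
#' @param side `"right"` or `"left"` profile. Retained for provenance; all
#'   parameters are reflection-invariant, so both sides are analyzed as-is.
#' @return An object of class `landmark_set`.
#' @export
#' @examples
#' lm <- landmark_set(make_template())
landmark_set <- function(points, side = c("right", "left")) {
  if (inherits(points, "landmark_set")) return(points)
  side <- match.arg(side)
  if (is.data.frame(points)) {
    m <- as.matrix(points[, c("x", "y")])
    rownames(m) <- as.character(points$landmark)
    points <- m
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("landmark points must have two columns (x, y)")
  colnames(points) <- c("x", "y")
  nm <- rownames(points)
  if (is.null(nm)) stop("landmark points must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate landmark name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  bad <- setdiff(nm, landmark_vocabulary())
  if (length(bad)) {
    stop("landmark name(s) outside canonical vocabulary: ",
         paste(bad, collapse = ", "))
  }
  if (!all(is.finite(points))) stop("landmark coordinates must be finite")
  structure(list(points = points, side = side), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", nrow(x$points), " points, ", x$side,
      "-profile\n", sep = "")
  print(x$points, ...)
  invisible(x)
}

.lm_point <- function(lm, name) {
  i <- match(name, rownames(lm$points))
  if (is.na(i)) stop("incomplete landmark set: missing ", name, call. = FALSE)
  lm$points[i, ]
}

.lm_has <- function(lm, names) all(names %in% rownames(lm$points))

#' Construct a frame record
#'
#' A frame record carries one analyzed video frame: identifiers, the time
#' since condition onset, the exclusion flag used to drop frames in which
#' the animal displayed a confounding behavior (licking the pipet,
#' self-scratching), and the landmarks and/or pre-measured parameters. A
#' record may carry measured parameters without landmarks, supporting
#' manual measurement workflows where angles and ratios are read off an
#' on-screen measuring tool.
#'
#' @param frame_id,animal_id,experiment_id Identifiers.
#' @param condition Condition label (e.g. `"baseline"`, `"sucrose"`).
#' @param phase_time_s Seconds since condition onset.
#' @param observer_id Optional observer identifier.
#' @param excluded Logical; `TRUE` drops the frame from all aggregation.
#' @param exclusion_reason One of `"licking"`, `"scratching"`, `"other"`,
#'   `"none"`.
#' @param landmarks Optional [landmark_set()].
#' @param parameters Optional named numeric vector over
#'   [facial_parameters()].
#' @return Object of class `frame_record`.
#' @export
frame_record <- function(frame_id, animal_id, experiment_id = "exp1",
                         condition = "baseline", phase_time_s = 0,
                         observer_id = NA_character_,
                         excluded = FALSE, exclusion_reason = "none",
                         landmarks = NULL, parameters = NULL) {
  structure(list(
    frame_id = frame_id, animal_id = animal_id,
    experiment_id = experiment_id, condition = condition,
    phase_time_s = phase_time_s, observer_id = observer_id,
    excluded = isTRUE(excluded), exclusion_reason = exclusion_reason,
    landmarks = landmarks, parameters = parameters
  ), class = "frame_record")
}

#' Validate a frame record
#'
#' Checks every structural invariant of a frame record and returns the
#' violations as character descriptors; an empty vector means the record is
#' well formed. Validation never aborts, is side-effect free and idempotent.
#'
#' Checked rules: at least one of landmarks/parameters present; an excluded
#' frame names a reason; landmark names belong to the vocabulary with
#' finite coordinates and confidence (when present) in [0, 1]; no two
#' landmarks required by the same parameter are coincident; measured
#' parameter values are finite and angles lie in their declared ranges.
#'
#' @param record A [frame_record()].
#' @return Character vector of violation descriptors (possibly empty).
#' @export
validate_frame <- function(record) {
  v <- character(0)
  if (is.null(record$landmarks) && is.null(record$parameters)) {
    v <- c(v, "record: neither landmarks nor parameters present")
  }
  if (isTRUE(record$excluded) &&
      (is.null(record$exclusion_reason) ||
       record$exclusion_reason %in% c("none", NA))) {
    v <- c(v, "exclusion_reason: excluded frame must name a reason")
  }
  if (!is.null(record$exclusion_reason) &&
      !record$exclusion_reason %in% c("licking", "scratching", "other", "none")) {
    v <- c(v, paste0("exclusion_reason: unknown label '",
                     record$exclusion_reason, "'"))
  }
  lm <- record$landmarks
  if (!is.null(lm)) {
    nm <- rownames(lm$points)
    if (!all(is.finite(lm$points))) {
      v <- c(v, "landmarks: non-finite coordinate(s)")
    }
    conf <- attr(lm, "confidence")
    if (!is.null(conf) && any(conf < 0 | conf > 1, na.rm = TRUE)) {
      v <- c(v, "landmarks: confidence outside [0, 1]")
    }
    # coincident pairs among each parameter's required landmarks
    for (p in facial_parameters()) {
      req <- required_landmarks(p)
      if (!all(req %in% nm)) next
      pts <- lm$points[req, , drop = FALSE]
      d <- as.matrix(stats::dist(pts))
      d[upper.tri(d, diag = TRUE)] <- NA
      hit <- which(d == 0, arr.ind = TRUE)
      if (nrow(hit)) {
        for (k in seq_len(nrow(hit))) {
          v <- c(v, paste0(p, ": coincident required landmarks ",
                           req[hit[k, 2]], " and ", req[hit[k, 1]]))
        }
      }
    }
  }
  par <- record$parameters
  if (!is.null(par)) {
    par <- as.list(par)[intersect(names(par), facial_parameters())]
    if (!all(is.finite(unlist(par)))) {
      v <- c(v, "parameters: non-finite value(s)")
    } else {
      rng <- list(ear_angle = c(0, 180), snout_position = c(0, 180),
                  face_inclination = c(-90, 90))
      for (p in intersect(names(rng), names(par))) {
        if (!is.null(par[[p]]) &&
            (par[[p]] < rng[[p]][1] || par[[p]] > rng[[p]][2])) {
          v <- c(v, paste0("parameters: ", p, " outside [",
                           rng[[p]][1], ", ", rng[[p]][2], "]"))
        }
      }
      neg <- intersect(names(par),
                       c("eye_opening", "ear_opening", "ear_position",
                         "mouth_position"))
      for (p in neg) {
        if (par[[p]] < 0) v <- c(v, paste0("parameters: ", p, " negative"))
      }
    }
  }
  unique(v)
}
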