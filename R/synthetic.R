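#' Canonical synthetic face template
#'
#' A fixed right-profile landmark configuration (pixel coordinates,
#' y-down) used as the neutral face for all synthetic data. It is built
#' so that reference values are exact: the four eye landmarks lie on a
#' circle (eye opening = 1) and the ear axis is perpendicular to the
#' skull-fixed face axis (ear angle = 90 degrees).
#'
#' @return A [landmark_set()] (right profile).
#' @export
#' @examples
#' compute_parameters(make_template())
make_template <- function() {
  eye_back <- c(188, 100)
  ear_orifice <- c(120, 115)
  base_front <- c(140, 60)
  base_back <- c(100, 60)
  mid <- (base_front + base_back) / 2
  face_axis <- ear_orifice - eye_back
  perp <- c(face_axis[2], -face_axis[1]) # rotate -90 deg: points upward here
  perp <- perp / sqrt(sum(perp^2))
  ear_tip <- mid + 50 * perp
  pts <- rbind(
    eye_front = c(212, 100), eye_back = eye_back,
    eye_top = c(200, 88), eye_bottom = c(200, 112),
    ear_tip = ear_tip, ear_base_front = base_front,
    ear_base_back = base_back, ear_orifice = ear_orifice,
    nose_top = c(300, 80), snout_tip = c(330, 100),
    lower_snout = c(300, 120), mouth_corner = c(290, 125),
    lower_lip = c(280, 135))
  colnames(pts) <- c("x", "y")
  landmark_set(pts, side = "right")
}

.rotate_about <- function(p, center, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  as.numeric(center + R %*% (p - center))
}

.angle_params <- function() c("ear_angle", "snout_position", "face_inclination")

#' Deform the template to shift exactly one facial parameter
#'
#' Constructs a landmark set whose named parameter differs from the
#' template's by exactly `delta` — additive degrees for angle parameters,
#' a multiplicative factor for ratio parameters — using a
#' parameter-specific geometric construction (e.g. rotating the ear tip
#' about the ear-base midpoint for ear angle, scaling the
#' eye_top/eye_bottom separation for eye opening). Landmarks not involved
#' in the construction are untouched; parameters sharing a moved landmark
#' may co-vary, as on a real face.
#'
#' @param template A [landmark_set()], normally [make_template()].
#' @param parameter One of [facial_parameters()].
#' @param delta Degrees (angles) or positive factor (ratios).
#' @return A new [landmark_set()].
#' @export
#' @examples
#' ear_angle(deform(make_template(), "ear_angle", -17))
deform <- function(template, parameter, delta) {
  lm <- landmark_set(template)
  pts <- lm$points
  is_angle <- parameter %in% .angle_params()
  if (!parameter %in% facial_parameters()) {
    stop("unknown facial parameter: ", parameter, call. = FALSE)
  }
  if (!is_angle && delta <= 0) {
    stop("ratio parameters take a multiplicative delta > 0", call. = FALSE)
  }
  scale_pair <- function(a, b, f) {
    m <- (pts[a, ] + pts[b, ]) / 2
    pts[a, ] <<- m + f * (pts[a, ] - m)
    pts[b, ] <<- m + f * (pts[b, ] - m)
  }
  if (parameter == "eye_opening") {
    scale_pair("eye_top", "eye_bottom", delta)
  } else if (parameter == "ear_opening") {
    scale_pair("ear_base_front", "ear_base_back", delta)
  } else if (parameter == "ear_position") {
    eb <- pts["eye_back", ]
    pts["ear_base_front", ] <- eb + delta * (pts["ear_base_front", ] - eb)
  } else if (parameter == "mouth_position") {
    st <- pts["snout_tip", ]
    pts["lower_lip", ] <- st + delta * (pts["lower_lip", ] - st)
  } else {
    move <- switch(parameter,
                   ear_angle = list(point = "ear_tip",
                                    center = (pts["ear_base_front", ] +
                                              pts["ear_base_back", ]) / 2),
                   snout_position = list(point = "nose_top",
                                         center = pts["snout_tip", ]),
                   face_inclination = list(point = "lower_snout",
                                           center = pts["eye_back", ]))
    fn <- switch(parameter, ear_angle = ear_angle,
                 snout_position = snout_position,
                 face_inclination = face_inclination)
    base <- fn(lm)
    target <- base + delta
    best <- NULL; best_err <- Inf
    for (s in c(1, -1)) {
      cand <- pts
      cand[move$point, ] <- .rotate_about(pts[move$point, ], move$center,
                                          s * delta)
      got <- fn(landmark_set(cand, side = lm$side))
      err <- abs(got - target)
      if (err < best_err) { best_err <- err; best <- cand }
    }
    if (best_err > 1e-6) {
      stop("delta ", delta, " out of range for ", parameter,
           " (target ", signif(target, 6), " not constructible)",
           call. = FALSE)
    }
    pts <- best
  }
  out <- landmark_set(pts, side = lm$side)
  # refuse deformations that leave any parameter incomputable
  compute_parameters(out)
  out
}

#' Apply a similarity transform (camera jitter) to a landmark set
#'
#' Rotation, uniform scaling, translation, and optional horizontal
#' mirroring with the profile side swapped — the family of nuisance
#' transforms a camera can introduce, under which all seven parameters
#' are invariant.
#'
#' @param lm A [landmark_set()].
#' @param rotation_deg,scale,translation Transform components
#'   (`translation` is length-2, pixels).
#' @param mirror Reflect x and swap the recorded side.
#' @return Transformed [landmark_set()].
#' @export
similarity_transform <- function(lm, rotation_deg = 0, scale = 1,
                                 translation = c(0, 0), mirror = FALSE) {
  lm <- landmark_set(lm)
  stopifnot(scale > 0, length(translation) == 2L)
  pts <- lm$points
  side <- lm$side
  if (mirror) {
    pts[, 1] <- -pts[, 1]
    side <- if (side == "right") "left" else "right"
  }
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- t(scale * R %*% t(pts)) +
    matrix(translation, nrow(pts), 2, byrow = TRUE)
  colnames(pts) <- c("x", "y")
  landmark_set(pts, side = side)
}

#' Specify a simulated experiment
#'
#' Encodes the study conditions emulated by the simulator: a multi-animal
#' session with a baseline phase followed by stimulus phases, a handful of
#' clear-profile frames per condition, per-individual variation,
#' per-frame measurement noise, camera similarity jitter, and occasional
#' behavioral exclusions.
#'
#' @param n_animals Number of animals.
#' @param conditions Ordered condition labels; the first is the baseline.
#' @param frames_range Inclusive integer range of frames drawn per animal
#'   per condition (default 4:6, i.e. about five usable frames per unit).
#' @param condition_duration_s Duration of each condition phase.
#' @param schedule Optional named list (condition -> vector of frame
#'   times in seconds) overriding `frames_range`, e.g. the one-frame-per-
#'   minute formalin schedule.
#' @param animal_sd Per-individual random-effect SD, as a fraction of the
#'   parameter's template value.
#' @param frame_sd Per-frame measurement-noise SD, same scale.
#' @param exclusion_rate Probability a frame is flagged excluded
#'   (licking/scratching/other).
#' @param jitter List with `rotation` (max degrees), `scale`
#'   (length-2 factor range), `translation` (max pixels) for per-frame
#'   camera jitter (landmark mechanism only).
#' @param landmark_noise_px SD, in template pixels, of independent
#'   Gaussian labeling noise added to every landmark before camera
#'   jitter (landmark mechanism only; emulates manual/pose-estimation
#'   placement error).
#' @param mechanism `"parameter"` (noise and effects applied to the seven
#'   parameters directly; used for statistical studies) or `"landmark"`
#'   (effects realized as geometric deformations of the template plus
#'   camera jitter; used for geometry studies).
#' @param experiment_id Label carried into the frame table.
#' @param seed Integer seed; simulation is bitwise reproducible.
#' @return List of class `simulation_design`.
#' @export
simulation_design <- function(n_animals = 10,
                              conditions = c("baseline", "stimulus"),
                              frames_range = 4:6,
                              condition_duration_s = 300,
                              schedule = NULL,
                              animal_sd = 0.05, frame_sd = 0.03,
                              exclusion_rate = 0,
                              jitter = list(rotation = 10,
                                            scale = c(0.8, 1.25),
                                            translation = 20),
                              landmark_noise_px = 0,
                              mechanism = c("parameter", "landmark"),
                              experiment_id = "sim",
                              seed = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(n_animals >= 1, length(conditions) >= 1,
            all(frames_range >= 1), animal_sd >= 0, frame_sd >= 0,
            exclusion_rate >= 0, exclusion_rate < 1,
            landmark_noise_px >= 0)
  if (!is.null(schedule) && !all(names(schedule) %in% conditions)) {
    stop("schedule names must be design conditions")
  }
  structure(list(n_animals = n_animals, conditions = conditions,
                 frames_range = frames_range,
                 condition_duration_s = condition_duration_s,
                 schedule = schedule, animal_sd = animal_sd,
                 frame_sd = frame_sd, exclusion_rate = exclusion_rate,
                 jitter = jitter,
                 landmark_noise_px = landmark_noise_px,
                 mechanism = mechanism,
                 experiment_id = experiment_id, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Formalin-test simulation design
#'
#' One frame per minute across a 30-min baseline phase and a 30-min
#' post-injection phase — 60 frames per animal.
#'
#' @param n_animals Number of animals.
#' @param ... Passed to [simulation_design()].
#' @inheritParams simulation_design
#' @export
formalin_design <- function(n_animals = 10, seed = 1, ...) {
  simulation_design(
    n_animals = n_animals,
    conditions = c("baseline", "formalin"),
    schedule = list(baseline = seq(0, 29) * 60,
                    formalin = seq(0, 29) * 60),
    condition_duration_s = 1800,
    experiment_id = "formalin",
    seed = seed, ...)
}

.template_params <- function() compute_parameters(make_template())

# delta -> true proportional change on the template
.effect_truth <- function(parameter, delta) {
  tp <- .template_params()
  if (parameter %in% .angle_params()) delta / tp[[parameter]]
  else delta - 1
}

.effect_at <- function(effects, condition, parameter, time_s) {
  e <- effects[[condition]]
  if (is.null(e) || is.null(e[[parameter]])) {
    return(if (parameter %in% .angle_params()) 0 else 1)
  }
  v <- e[[parameter]]
  if (is.function(v)) v(time_s) else v
}

#' Simulate an experiment with known ground truth
#'
#' Generates a frame table emulating a multi-animal session under
#' `design`, with per-condition effects given as `effects`: a named list
#' (condition -> named list/vector over parameters), where each entry is
#' an additive degree shift for angle parameters, a multiplicative factor
#' for ratio parameters, or a function of time (seconds since condition
#' onset) returning such a value — the latter supports time-varying
#' effects such as the biphasic formalin response.
#'
#' In the `"parameter"` mechanism each frame's parameter value is
#' template value with the condition effect applied, times
#' `(1 + animal effect) * (1 + frame noise)`, both Gaussian. In the
#' `"landmark"` mechanism the condition effect is realized by [deform()]
#' and each frame receives camera similarity jitter, which leaves all
#' parameters untouched.
#'
#' @param design A [simulation_design()].
#' @param effects Named list of per-condition effects (may be empty).
#' @return List with `frames` (frame-level parameter table; in the
#'   landmark mechanism also `landmarks`, a long-format landmark table)
#'   and `ground_truth` (true per condition/parameter proportional
#'   changes, per-animal effects, template values, seed).
#' @export
simulate_experiment <- function(design, effects = list()) {
  stopifnot(inherits(design, "simulation_design"))
  bad <- setdiff(names(effects), design$conditions)
  if (length(bad)) {
    stop("effects for unknown condition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pars <- facial_parameters()
  tp <- .template_params()
  template <- make_template()
  .with_seed(design$seed, {
    animal_ids <- sprintf("a%02d", seq_len(design$n_animals))
    animal_eff <- matrix(stats::rnorm(design$n_animals * 7,
                                      sd = design$animal_sd),
                         design$n_animals, 7,
                         dimnames = list(animal_ids, pars))
    frame_rows <- list()
    landmark_rows <- list()
    fid <- 0L
    for (ai in seq_along(animal_ids)) {
      an <- animal_ids[ai]
      for (cond in design$conditions) {
        if (!is.null(design$schedule) &&
            !is.null(design$schedule[[cond]])) {
          times <- design$schedule[[cond]]
        } else {
          nf <- sample(design$frames_range, 1L)
          times <- sort(stats::runif(nf, 0, design$condition_duration_s))
        }
        for (t in times) {
          fid <- fid + 1L
          excl <- stats::runif(1) < design$exclusion_rate
          reason <- if (excl)
            sample(c("licking", "scratching", "other"), 1L) else "none"
          meta <- data.frame(
            frame_id = sprintf("f%06d", fid), animal_id = an,
            experiment_id = design$experiment_id, condition = cond,
            phase_time_s = t, excluded = excl, exclusion_reason = reason)
          if (design$mechanism == "parameter") {
            vals <- vapply(pars, function(p) {
              eff <- .effect_at(effects, cond, p, t)
              base <- if (p %in% .angle_params()) tp[[p]] + eff
                      else tp[[p]] * eff
              base * (1 + animal_eff[an, p]) *
                (1 + stats::rnorm(1, sd = design$frame_sd))
            }, numeric(1))
            frame_rows[[fid]] <- cbind(meta, as.data.frame(as.list(vals)))
          } else {
            lm <- template
            e <- effects[[cond]]
            for (p in names(e)) {
              eff <- .effect_at(effects, cond, p, t)
              neutral <- if (p %in% .angle_params()) 0 else 1
              if (eff != neutral) lm <- deform(lm, p, eff)
            }
            if (design$landmark_noise_px > 0) {
              pts <- lm$points +
                matrix(stats::rnorm(26, sd = design$landmark_noise_px),
                       13, 2)
              lm <- landmark_set(pts, side = lm$side)
            }
            j <- design$jitter
            lm <- similarity_transform(
              lm,
              rotation_deg = stats::runif(1, -j$rotation, j$rotation),
              scale = stats::runif(1, j$scale[1], j$scale[2]),
              translation = stats::runif(2, -j$translation, j$translation))
            vals <- compute_parameters(lm)
            frame_rows[[fid]] <- cbind(meta, as.data.frame(as.list(vals)))
            landmark_rows[[fid]] <- cbind(
              meta[rep(1L, nrow(lm$points)), , drop = FALSE],
              data.frame(side = lm$side,
                         landmark = rownames(lm$points),
                         x = lm$points[, 1], y = lm$points[, 2]))
          }
        }
      }
    }
    frames <- do.call(rbind, frame_rows)
    rownames(frames) <- NULL
    truth_change <- NULL
    if (length(effects)) {
      truth_change <- do.call(rbind, lapply(names(effects), function(cond) {
        do.call(rbind, lapply(names(effects[[cond]]), function(p) {
          v <- effects[[cond]][[p]]
          data.frame(condition = cond, parameter = p,
                     true_change = if (is.function(v)) NA_real_
                                   else .effect_truth(p, v),
                     time_varying = is.function(v))
        }))
      }))
    }
    out <- list(frames = frames,
                ground_truth = list(true_change = truth_change,
                                    animal_effects = animal_eff,
                                    template = tp, seed = design$seed,
                                    mechanism = design$mechanism))
    if (design$mechanism == "landmark") {
      lms <- do.call(rbind, landmark_rows)
      rownames(lms) <- NULL
      out$landmarks <- lms
    }
    out
  })
}
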