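# Shared fixtures: independent geometric oracles and random generators.
# The oracles deliberately use acos / explicit sums rather than the
# package's atan2 route, so agreement is a genuine cross-check.

oracle_dist <- function(a, b) sqrt(sum((a - b)^2))

oracle_angle <- function(vertex, a, b) {
  u <- a - vertex
  v <- b - vertex
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

oracle_parameters <- function(lm) {
  p <- lm$points
  mid <- (p["ear_base_front", ] + p["ear_base_back", ]) / 2
  c(eye_opening = oracle_dist(p["eye_top", ], p["eye_bottom", ]) /
      oracle_dist(p["eye_front", ], p["eye_back", ]),
    ear_opening = oracle_dist(p["ear_base_front", ], p["ear_base_back", ]) /
      oracle_dist(mid, p["ear_tip", ]),
    ear_angle = oracle_angle(c(0, 0), p["ear_tip", ] - mid,
                             p["ear_orifice", ] - p["eye_back", ]),
    ear_position = oracle_dist(p["eye_back", ], p["ear_base_front", ]) /
      oracle_dist(p["eye_back", ], p["ear_orifice", ]),
    snout_position = oracle_angle(p["snout_tip", ], p["nose_top", ],
                                  p["lower_snout", ]),
    mouth_position = oracle_dist(p["snout_tip", ], p["lower_lip", ]) /
      oracle_dist(p["snout_tip", ], p["eye_back", ]),
    face_inclination = oracle_angle(p["eye_back", ], p["lower_snout", ],
                                    p["ear_orifice", ]) - 90)
}

# a valid random landmark set: jittered template, rejecting the rare
# draw in which some parameter becomes incomputable
random_landmark_set <- function(sd = 6) {
  repeat {
    pts <- make_template()$points +
      matrix(stats::rnorm(26, sd = sd), 13, 2)
    lm <- landmark_set(pts, side = "right")
    ok <- !inherits(try(compute_parameters(lm), silent = TRUE),
                    "try-error")
    if (ok) return(lm)
  }
}

random_similarity <- function(lm) {
  similarity_transform(
    lm,
    rotation_deg = stats::runif(1, -180, 180),
    scale = exp(stats::runif(1, log(0.2), log(5))),
    translation = stats::runif(2, -500, 500),
    mirror = stats::runif(1) < 0.5)
}

# small frame-level parameter table with known values
param_frame_table <- function(values, animal_id = "a01",
                              condition = "baseline",
                              phase_time_s = NULL) {
  n <- nrow(values)
  data.frame(frame_id = sprintf("f%03d", seq_len(n)),
             animal_id = animal_id, experiment_id = "exp1",
             condition = condition,
             phase_time_s = if (is.null(phase_time_s)) seq_len(n)
                            else phase_time_s,
             excluded = FALSE, exclusion_reason = "none",
             values)
}

constant_params <- function(n, vals = compute_parameters(make_template())) {
  as.data.frame(lapply(vals, rep, n))
}
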