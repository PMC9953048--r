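test_that("angle_at: reference angles and symmetry", {
  expect_equal(angle_at(c(0, 0), c(1, 0), c(0, 1)), 90)
  expect_equal(angle_at(c(0, 0), c(1, 0), c(-1, 0)), 180)
  expect_equal(angle_at(c(0, 0), c(1, 0), c(5, 0)), 0)
  expect_equal(angle_at(c(2, 3), c(7, 3), c(2, 9)), 90)
  expect_error(angle_at(c(0, 0), c(0, 0), c(1, 1)), "degenerate")
  set.seed(11)
  for (i in 1:50) {
    v <- rnorm(2); a <- rnorm(2); b <- rnorm(2)
    expect_equal(angle_at(v, a, b), angle_at(v, b, a))
  }
})

test_that("angle_at matches an independent arc-cosine oracle", {
  set.seed(42)
  for (i in 1:200) {
    v <- runif(2, -10, 10); a <- runif(2, -10, 10); b <- runif(2, -10, 10)
    if (all(a == v) || all(b == v)) next
    expect_equal(angle_at(v, a, b), oracle_angle(v, a, b),
                 tolerance = 1e-9)
  }
})

test_that("eye_opening: circle reference and linearity in lid closure", {
  circ <- landmark_set(rbind(eye_top = c(0, 1), eye_bottom = c(0, -1),
                             eye_front = c(-1, 0), eye_back = c(1, 0)))
  expect_equal(eye_opening(circ), 1)
  half <- landmark_set(rbind(eye_top = c(0, 1), eye_bottom = c(0, -1),
                             eye_front = c(-2, 0), eye_back = c(2, 0)))
  expect_equal(eye_opening(half), 0.5)
  tmpl <- make_template()
  base <- eye_opening(tmpl)
  for (s in seq(0.1, 1, by = 0.1)) {
    expect_equal(eye_opening(deform(tmpl, "eye_opening", s)), s * base,
                 tolerance = 1e-12)
  }
})

test_that("ear_opening: reference values and foreshortening monotonicity", {
  mk <- function(w, tipy) landmark_set(
    rbind(ear_base_front = c(w, 0), ear_base_back = c(-w, 0),
          ear_tip = c(0, tipy)))
  expect_equal(ear_opening(mk(2, 4)), 1)
  expect_equal(ear_opening(mk(1, 4)), 0.5)
  # out-of-plane rotation shrinks visible base width by cos(theta)
  thetas <- seq(5, 85, by = 10) * pi / 180
  vals <- sapply(thetas, function(th) ear_opening(mk(2 * cos(th), 4)))
  expect_true(all(diff(vals) < 0))
})

test_that("ear_angle: axis alignment references and exact rotation", {
  tmpl <- make_template()
  expect_equal(ear_angle(tmpl), 90) # template built perpendicular
  # ear axis parallel to face axis -> 0
  p <- tmpl$points
  mid <- (p["ear_base_front", ] + p["ear_base_back", ]) / 2
  axis <- p["ear_orifice", ] - p["eye_back", ]
  p["ear_tip", ] <- mid + axis
  expect_equal(ear_angle(landmark_set(p)), 0, tolerance = 1e-12)
  expect_equal(ear_angle(deform(tmpl, "ear_angle", -17)), 90 - 17,
               tolerance = 1e-9)
})

test_that("ear_position: coincidence references and backward monotonicity", {
  p <- make_template()$points
  p1 <- p; p1["ear_base_front", ] <- p1["ear_orifice", ]
  expect_equal(ear_position(landmark_set(p1)), 1)
  p2 <- p; p2["ear_base_front", ] <- p2["eye_back", ]
  expect_equal(ear_position(landmark_set(p2)), 0)
  # translate the ear backward along the face axis
  axis <- p["ear_orifice", ] - p["eye_back", ]
  axis <- axis / sqrt(sum(axis^2))
  vals <- sapply(seq(0, 50, by = 10), function(d) {
    q <- p
    ear <- c("ear_tip", "ear_base_front", "ear_base_back")
    q[ear, ] <- q[ear, ] + matrix(d * axis, 3, 2, byrow = TRUE)
    ear_position(landmark_set(q))
  })
  expect_true(all(diff(vals) > 0))
})

test_that("snout_position and mouth_position references", {
  sn <- landmark_set(rbind(nose_top = c(0, 1), snout_tip = c(-1, 0),
                           lower_snout = c(0, -1)))
  expect_equal(snout_position(sn), 90)
  flat <- landmark_set(rbind(nose_top = c(0, 1), snout_tip = c(0, 0),
                             lower_snout = c(0, -1)))
  expect_equal(snout_position(flat), 180)

  p <- make_template()$points
  p1 <- p; p1["lower_lip", ] <- p1["snout_tip", ]
  expect_equal(mouth_position(landmark_set(p1)), 0)
  p2 <- p; p2["lower_lip", ] <- p2["eye_back", ]
  expect_equal(mouth_position(landmark_set(p2)), 1)
  # slide the lip backward along the jaw line
  jaw <- p["eye_back", ] - p["snout_tip", ]
  vals <- sapply(seq(0.1, 1, by = 0.1), function(f) {
    q <- p; q["lower_lip", ] <- p["snout_tip", ] + f * jaw
    mouth_position(landmark_set(q))
  })
  expect_true(all(diff(vals) > 0))
})

test_that("face_inclination is the eye-corner angle minus 90", {
  ra <- landmark_set(rbind(lower_snout = c(1, 0), eye_back = c(0, 0),
                           ear_orifice = c(0, 1)))
  expect_equal(face_inclination(ra), 0)
  col <- landmark_set(rbind(lower_snout = c(1, 0), eye_back = c(0, 0),
                            ear_orifice = c(-1, 0)))
  expect_equal(face_inclination(col), 90)
  set.seed(7)
  for (i in 1:50) {
    lm <- random_landmark_set()
    expect_equal(face_inclination(lm),
                 angle_at(lm$points["eye_back", ],
                          lm$points["lower_snout", ],
                          lm$points["ear_orifice", ]) - 90)
  }
})

test_that("compute_parameters: vector form, partial mode, errors", {
  tmpl <- make_template()
  v <- compute_parameters(tmpl)
  expect_named(v, facial_parameters())
  expect_true(all(is.finite(v)))
  expect_identical(v["eye_opening"], c(eye_opening = eye_opening(tmpl)))

  no_tip <- landmark_set(
    tmpl$points[setdiff(rownames(tmpl$points), "ear_tip"), ])
  expect_error(compute_parameters(no_tip), "ear_tip")
  part <- compute_parameters(no_tip, partial = TRUE)
  st <- attr(part, "status")
  expect_identical(unname(st[c("ear_opening", "ear_angle")]),
                   c("missing", "missing"))
  expect_identical(sum(st == "ok"), 5L)
  expect_true(all(is.finite(part[st == "ok"])))

  degen <- tmpl$points
  degen["eye_top", ] <- degen["eye_bottom", ]
  expect_error(compute_parameters(landmark_set(degen)),
               "degenerate geometry for eye_opening")
  pd <- compute_parameters(landmark_set(degen), partial = TRUE)
  expect_identical(unname(attr(pd, "status")["eye_opening"]), "degenerate")
})

test_that("angles stay in their declared ranges on random inputs", {
  set.seed(99)
  for (i in 1:100) {
    v <- compute_parameters(random_landmark_set(sd = 10))
    expect_gte(v[["ear_angle"]], 0);  expect_lte(v[["ear_angle"]], 180)
    expect_gt(v[["snout_position"]], 0)
    expect_lte(v[["snout_position"]], 180)
    expect_gte(v[["face_inclination"]], -90)
    expect_lte(v[["face_inclination"]], 90)
    expect_true(all(v[c("eye_opening", "ear_opening", "ear_position",
                        "mouth_position")] >= 0))
  }
})

test_that("measure_frames produces per-frame values with status columns", {
  tmpl <- make_template()
  sim <- simulate_experiment(simulation_design(
    n_animals = 2, conditions = c("baseline", "stimulus"),
    mechanism = "landmark", seed = 5))
  tab <- measure_frames(sim$landmarks)
  expect_identical(nrow(tab), length(unique(sim$landmarks$frame_id)))
  expect_true(all(facial_parameters() %in% names(tab)))
  expect_true(all(tab$eye_opening_status == "ok"))
  # camera jitter must not move any parameter off the template
  expect_equal(max(abs(tab$eye_opening - eye_opening(tmpl))), 0,
               tolerance = 1e-9)

  # drop ear_tip everywhere -> ear columns flagged missing
  lms <- sim$landmarks[sim$landmarks$landmark != "ear_tip", ]
  tab2 <- measure_frames(lms)
  expect_true(all(tab2$ear_opening_status == "missing"))
  expect_true(all(tab2$ear_angle_status == "missing"))
  expect_true(all(is.na(tab2$ear_angle)))
  expect_true(all(is.finite(tab2$eye_opening)))
})
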