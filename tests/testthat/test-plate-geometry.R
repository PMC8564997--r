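test_that("default layout has the designed dual-plate structure", {
  layout <- default_layout()
  expect_equal(nrow(layout$centers), 18)
  expect_setequal(rownames(layout$centers), concave_labels())
  expect_equal(sum(concave_jaw(rownames(layout$centers)) == "maxillary"), 9)
  expect_equal(layout$concave_radius, 3)

  # every maxillary concave sits vertically above its mandibular partner
  for (lab in concave_labels("maxillary")) {
    partner <- pair_of(lab)
    expect_equal(layout$centers[lab, c("x", "y")],
                 layout$centers[partner, c("x", "y")])
    expect_gt(layout$centers[lab, "z"], layout$centers[partner, "z"])
  }

  # three concaves per face: right lateral, front, left lateral
  x <- layout$centers[, "x"]; y <- layout$centers[, "y"]
  right <- c("12", "13", "14", "42", "43", "44")
  left <- c("22", "23", "24", "32", "33", "34")
  front <- c("11", "0", "21", "41", "0'", "31")
  expect_true(all(x[right] == min(x)))
  expect_true(all(x[left] == max(x)))
  expect_true(all(y[front] == min(y)))

  # opening axes are unit vectors pointing out of the respective face
  expect_equal(unname(sqrt(rowSums(layout$axes^2))), rep(1, 18),
               tolerance = 1e-12)
  expect_true(all(layout$axes[right, "x"] == -1))
  expect_true(all(layout$axes[left, "x"] == 1))
  expect_true(all(layout$axes[front, "y"] == -1))

  # the observation-frame triple must be non-collinear by construction
  tri <- layout$centers[c("12", "0", "22"), ]
  area <- sqrt(sum(platealign:::.cross3(tri[2, ] - tri[1, ],
                                        tri[3, ] - tri[1, ])^2)) / 2
  expect_gt(area, 1)
})

test_that("layout parameters pass through and invalid overrides are rejected", {
  small <- default_layout(concave_radius = 2)
  expect_equal(small$concave_radius, 2)
  expect_equal(small$centers, default_layout()$centers)
  expect_error(default_layout(concave_radius = 0), "positive")
  expect_error(default_layout(concave_radius = -3), "positive")
  expect_error(default_layout(jaw_separation = 0), "positive")
})

test_that("pair_of maps the nine canonical pairs and is an involution", {
  expect_equal(pair_of("14"), "44")
  expect_equal(pair_of("0"), "0'")
  expect_equal(pair_of("21"), "31")
  for (lab in concave_labels()) {
    expect_equal(pair_of(pair_of(lab)), lab)
  }
  # restricted to maxillary labels it is a bijection onto mandibular labels
  image <- pair_of(concave_labels("maxillary"))
  expect_setequal(image, concave_labels("mandibular"))
  expect_equal(anyDuplicated(image), 0L)
  expect_equal(nrow(canonical_pairs()), 9)
  expect_error(pair_of("99"), "invalid")
})

test_that("concave label validation and jaw derivation", {
  expect_equal(concave_jaw("0"), "maxillary")
  expect_equal(concave_jaw("0'"), "mandibular")
  expect_equal(concave_jaw(c("13", "33")), c("maxillary", "mandibular"))
  expect_error(landmark_set(matrix(0, 1, 3, dimnames = list("xx", NULL))),
               "invalid")
  expect_error(concave_jaw("15"), "invalid")
})

test_that("rigid transforms apply, compose and invert consistently", {
  set.seed(101)
  layout <- default_layout()
  lms <- nominal_landmarks(layout)

  expect_equal(apply_transform(identity_transform(), lms)$points, lms$points)

  shifted <- apply_transform(rigid_transform(diag(3), c(0, 0, 5)), lms)
  expect_equal(shifted$points[, "z"], lms$points[, "z"] + 5)
  expect_equal(shifted$points[, c("x", "y")], lms$points[, c("x", "y")])

  # pairwise distances among all 18 landmarks survive any rigid motion
  for (i in 1:5) {
    tf <- rand_transform()
    moved <- apply_transform(tf, lms$points)
    expect_lt(max_pairwise_distance_change(lms$points, moved), 1e-9)
  }

  # compose(a, b) applies b first; matches point-wise sequential mapping
  for (i in 1:5) {
    a <- rand_transform(); b <- rand_transform()
    pts <- matrix(rnorm(30, sd = 10), 10, 3)
    seq_map <- apply_transform(a, apply_transform(b, pts))
    expect_equal(apply_transform(compose_transform(a, b), pts), seq_map,
                 tolerance = 1e-9)
    ident <- compose_transform(a, invert_transform(a))
    expect_lt(max(abs(ident$rotation - diag(3))), 1e-10)
    expect_lt(max(abs(ident$translation)), 1e-10)
  }
})

test_that("non-rotations are rejected unless explicitly repaired", {
  bad <- diag(3); bad[1, 1] <- 1.001
  expect_error(rigid_transform(bad), "proper orthogonal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper orthogonal")
  repaired <- rigid_transform(bad, repair = TRUE)
  expect_equal(det(repaired$rotation), 1, tolerance = 1e-12)
})

test_that("observation frame satisfies the 12/0/22 construction", {
  layout <- default_layout()
  lms <- nominal_landmarks(layout)
  tf <- build_observation_frame(lms)
  obs <- apply_transform(tf, lms)

  expect_equal(unname(obs$points["0", ]), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(unname(obs$points[c("12", "0", "22"), "z"]), rep(0, 3),
               tolerance = 1e-10)
  expect_equal(obs$points["12", "y"], obs$points["22", "y"],
               tolerance = 1e-10)
  # X runs from 12 toward 22 (left to right); Z points toward the maxilla
  expect_gt(obs$points["22", "x"], obs$points["12", "x"])
  expect_gt(obs$points["13", "z"], obs$points["43", "z"])
  expect_equal(det(tf$rotation), 1, tolerance = 1e-10)

  # a frame-satisfying set yields the identity
  tf2 <- build_observation_frame(obs)
  expect_lt(max(abs(tf2$rotation - diag(3))), 1e-10)
  expect_lt(max(abs(tf2$translation)), 1e-10)
})

test_that("observation frame inverts an arbitrary rigid displacement", {
  set.seed(202)
  layout <- default_layout()
  canon <- apply_transform(build_observation_frame(nominal_landmarks(layout)),
                           nominal_landmarks(layout))
  for (i in 1:10) {
    tf <- rand_transform(tmax = 40)
    displaced <- apply_transform(tf, canon)
    rec <- build_observation_frame(displaced)
    # recovered transform is the inverse of the displacement
    ident <- compose_transform(rec, tf)
    expect_lt(max(abs(ident$rotation - diag(3))), 1e-9)
    expect_lt(max(abs(ident$translation)), 1e-9)
    # and observation-frame coordinates are pose-invariant
    obs <- apply_transform(rec, displaced)
    expect_equal(obs$points, canon$points, tolerance = 1e-9)
  }
})

test_that("observation frame rejects degenerate or incomplete input", {
  pts <- rbind("12" = c(0, 0, 0), "0" = c(1, 0, 0), "22" = c(2, 0, 0))
  expect_error(build_observation_frame(landmark_set(pts)), "collinear")
  pts2 <- rbind("12" = c(0, 0, 0), "0" = c(1, 1, 0))
  expect_error(build_observation_frame(landmark_set(pts2)), "missing")
})

test_that("jaw views contain only their jaw's labels", {
  lms <- nominal_landmarks(default_layout())
  up <- jaw_view(lms, "maxillary")
  expect_setequal(rownames(up$points), concave_labels("maxillary"))
  down <- jaw_view(lms, "mandibular")
  expect_setequal(rownames(down$points), concave_labels("mandibular"))
})
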