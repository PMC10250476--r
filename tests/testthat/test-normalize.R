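test_that("displacement, translation and middle neck follow the frame algebra", {
  fr <- random_frame()
  fr["body", ] <- c(3, 4)
  expect_equal(unname(displacement_vector(fr)), c(-3, -4))
  fr["body", ] <- c(0, 0)
  expect_equal(unname(displacement_vector(fr)), c(0, 0))
  fr["body", ] <- c(-2.5, 7)
  expect_equal(unname(displacement_vector(fr)), c(2.5, -7))
  expect_error(displacement_vector(fr[rownames(fr) != "body", ]), "body")

  fr2 <- translate_frame(fr, c(-3, -4))
  expect_equal(unname(fr2), unname(fr) + rep(c(-3, -4), each = nrow(fr)))
  expect_equal(translate_frame(fr, c(0, 0)), fr)
  # translation is an isometry
  d0 <- dist(fr); d1 <- dist(translate_frame(fr, rnorm(2, sd = 30)))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)

  fr["left_neck", ] <- c(2, 3); fr["right_neck", ] <- c(1, 1)
  expect_equal(unname(middle_neck(fr)), c(1, 2))
  fr["right_neck", ] <- c(2, 3)
  expect_equal(unname(middle_neck(fr)), c(0, 0))
  fr["left_neck", ] <- c(0, 1); fr["right_neck", ] <- c(0, -1)
  expect_equal(unname(middle_neck(fr)), c(0, 2))
  expect_equal(unname(middle_neck(fr, mode = "midpoint")), c(0, 0))
  expect_error(middle_neck(fr[rownames(fr) != "left_neck", ]), "left_neck")
})

test_that("rotation angle is measured from the positive y axis", {
  expect_equal(rotation_angle(c(0, 1)), 0)
  expect_equal(rotation_angle(c(1, 0)), 90)
  expect_equal(rotation_angle(c(1, 1)), 45)
  expect_equal(rotation_angle(c(-1, 0)), -90)
  expect_equal(rotation_angle(c(0, 0)), 0)   # degenerate convention
})

test_that("applying the rotation maps the reference vector onto +y", {
  fr <- matrix(c(1, 0), 1, 2, dimnames = list("p", c("x", "y")))
  expect_equal(unname(apply_rotation(fr, 90)), matrix(c(0, 1), 1),
               tolerance = 1e-12)
  expect_equal(apply_rotation(fr, 0), fr)
  # rotation preserves norms
  fr <- random_frame()
  rot <- apply_rotation(fr, runif(1, -180, 180))
  expect_equal(sqrt(rowSums(rot^2)), sqrt(rowSums(fr^2)), tolerance = 1e-9)
  # composed with the angle of any vector, that vector lands on +y
  for (i in 1:20) {
    v <- rnorm(2)
    out <- apply_rotation(matrix(v, 1, 2, dimnames = list("v", c("x", "y"))),
                          rotation_angle(v))
    expect_lt(abs(out[1, 1]), 1e-9)
    expect_gte(out[1, 2], 0)
  }
})

test_that("normalize_track meets its output contract on random tracks", {
  set.seed(42)
  tr <- random_track(50)
  nt <- normalize_track(tr)
  ib <- match("body", tr$parts)
  il <- match("left_neck", tr$parts); ir <- match("right_neck", tr$parts)
  expect_lt(max(abs(nt$track$x[, ib]), abs(nt$track$y[, ib])), 1e-6)
  vx <- nt$track$x[, il] - nt$track$x[, ir]
  vy <- nt$track$y[, il] - nt$track$y[, ir]
  expect_lt(max(abs(vx)), 1e-6)
  expect_true(all(vy >= -1e-6))
  expect_identical(nt$track$likelihood, tr$likelihood)
  expect_equal(nt$state$rot_norm,
               atan2(nt$state$v_x, nt$state$v_y) * 180 / pi)
  expect_true(all(nt$state$rot_norm > -180 & nt$state$rot_norm <= 180))
})

test_that("normalization is idempotent", {
  set.seed(1)
  tr <- random_track(30)
  once <- normalize_track(tr)
  twice <- normalize_track(once$track)
  expect_equal(twice$track$x, once$track$x, tolerance = 1e-6)
  expect_equal(twice$track$y, once$track$y, tolerance = 1e-6)
  expect_lt(max(abs(twice$state$rot_norm)), 1e-6)
})

test_that("normalization is invariant under global rigid motion", {
  set.seed(2)
  tr <- random_track(40)
  ref <- normalize_track(tr)
  for (case in 1:3) {
    ang <- runif(1, -180, 180)
    shift <- rnorm(2, sd = 100)
    a <- ang * pi / 180
    rx <- tr$x * cos(a) - tr$y * sin(a) + shift[1]
    ry <- tr$x * sin(a) + tr$y * cos(a) + shift[2]
    moved <- normalize_track(pose_track(rx, ry, tr$likelihood,
                                        parts = tr$parts))
    expect_equal(moved$track$x, ref$track$x, tolerance = 1e-6)
    expect_equal(moved$track$y, ref$track$y, tolerance = 1e-6)
  }
  # the fixed 37-degree + (50, -20) case
  a <- 37 * pi / 180
  moved <- normalize_track(pose_track(tr$x * cos(a) - tr$y * sin(a) + 50,
                                      tr$x * sin(a) + tr$y * cos(a) - 20,
                                      parts = tr$parts))
  expect_equal(moved$track$x, ref$track$x, tolerance = 1e-6)
})

test_that("the per-frame transform preserves pairwise inter-part distances", {
  set.seed(3)
  tr <- random_track(25)
  nt <- normalize_track(tr)
  for (f in c(0L, 12L, 24L)) {
    before <- dist(cbind(tr$x[f + 1, ], tr$y[f + 1, ]))
    after <- dist(cbind(nt$track$x[f + 1, ], nt$track$y[f + 1, ]))
    expect_equal(as.vector(after), as.vector(before), tolerance = 1e-9)
  }
})

test_that("degenerate middle-neck frames are flagged, not dropped", {
  tr <- random_track(3)
  tr$x[2, c("left_neck", "right_neck")] <- 10
  tr$y[2, c("left_neck", "right_neck")] <- 20
  expect_message(nt <- normalize_track(tr), "degenerate")
  expect_identical(nt$state$degenerate, c(FALSE, TRUE, FALSE))
  expect_equal(nt$state$rot_norm[2], 0)
  expect_equal(n_frames(nt$track), 3L)
})
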