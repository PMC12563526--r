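test_that("Hamilton product matches the 4x4 product-matrix oracle", {
  set.seed(1)
  for (rep in 1:50) {
    a <- q_normalize(quaternion(rnorm(1), rnorm(1), rnorm(1), rnorm(1)))
    b <- q_normalize(quaternion(rnorm(1), rnorm(1), rnorm(1), rnorm(1)))
    # left-multiplication matrix of a (Hamilton convention, i j = k)
    L <- matrix(c(a[1], -a[2], -a[3], -a[4],
                  a[2],  a[1], -a[4],  a[3],
                  a[3],  a[4],  a[1], -a[2],
                  a[4], -a[3],  a[2],  a[1]), 4, 4, byrow = TRUE)
    expect_equal(unname(unclass(q_multiply(a, b))),
                 unname(as.vector(L %*% unclass(b))), tolerance = 1e-12)
  }
})

test_that("identity and inverse behave as group elements", {
  a <- sample_rotation(40, seed = 5)
  expect_equal(unclass(q_multiply(a, q_identity())), unclass(a),
               tolerance = 1e-12)
  expect_equal(unname(unclass(q_multiply(a, q_inverse(a)))), c(1, 0, 0, 0),
               tolerance = 1e-12)
  expect_equal(sqrt(sum(unclass(q_multiply(a, a))^2)), 1, tolerance = 1e-9)
})

test_that("sampled rotations stay inside the per-axis angle bound", {
  expect_error(sample_rotation(0), "max_angle_deg")
  expect_error(sample_rotation(180), "max_angle_deg")
  # vanishing angle range gives the identity in the limit
  q <- sample_rotation(1e-6, seed = 1)
  expect_equal(unname(unclass(q)), c(1, 0, 0, 0), tolerance = 1e-6)
  # recovered intrinsic x-y-z Euler angles lie within +/- 15 degrees
  for (s in 1:2000) {
    q <- sample_rotation(15, seed = s)
    R <- quat_rotmat(unclass(q))
    ang <- c(atan2(-R[2, 3], R[3, 3]), asin(R[1, 3]),
             atan2(-R[1, 2], R[1, 1])) * 180 / pi
    expect_true(all(abs(ang) <= 15 + 1e-6))
  }
  expect_identical(unclass(sample_rotation(15, seed = 7)),
                   unclass(sample_rotation(15, seed = 7)))
})

test_that("vector conjugation matches the rotation-matrix oracle", {
  expect_equal(rotate_vector(q_identity(), c(1, 2, 3)), c(1, 2, 3))
  # 90 degrees about z under the inverse-on-left (passive) convention
  q <- quaternion(cos(pi / 4), 0, 0, sin(pi / 4))
  expect_equal(rotate_vector(q, c(1, 0, 0)), c(0, -1, 0), tolerance = 1e-12)
  set.seed(2)
  for (rep in 1:200) {
    q <- q_normalize(quaternion(rnorm(1), rnorm(1), rnorm(1), rnorm(1)))
    v <- rnorm(3)
    expect_equal(rotate_vector(q, v),
                 as.vector(t(quat_rotmat(unclass(q))) %*% v),
                 tolerance = 1e-9)
    expect_equal(sqrt(sum(rotate_vector(q, v)^2)), sqrt(sum(v^2)),
                 tolerance = 1e-9)
  }
})

test_that("segment rotation preserves norms and is invertible", {
  segs <- make_segments(2, "FM", wl = 190)
  q <- sample_rotation(15, seed = 3)
  rot <- rotate_segment(segs, q)
  expect_true(all(rot$provenance == "augmented"))
  expect_identical(rot$label, segs$label)
  # identity rotation only flips provenance
  rid <- rotate_segment(segs, q_identity())
  expect_equal(rid$samples, segs$samples, tolerance = 1e-12)
  # per-sample accelerometer and gyroscope norms are invariant
  for (i in 1:2) {
    expect_equal(sqrt(rowSums(rot$samples[i, , 1:3]^2)),
                 sqrt(rowSums(segs$samples[i, , 1:3]^2)), tolerance = 1e-9)
    expect_equal(sqrt(rowSums(rot$samples[i, , 4:6]^2)),
                 sqrt(rowSums(segs$samples[i, , 4:6]^2)), tolerance = 1e-9)
  }
  # rotating back with the inverse recovers the original samples
  back <- rotate_segment(rot, q_inverse(q))
  expect_equal(back$samples, segs$samples, tolerance = 1e-6)
})

test_that("reference-orientation update is right-multiplication", {
  q_ref <- sample_rotation(30, seed = 1)
  q <- sample_rotation(30, seed = 2)
  expect_equal(unclass(update_reference(q_ref, q_identity())),
               unclass(q_ref), tolerance = 1e-12)
  expect_equal(unclass(update_reference(q_identity(), q)), unclass(q),
               tolerance = 1e-12)
  expect_equal(unclass(update_reference(q_ref, q)),
               unclass(q_multiply(q_ref, q)), tolerance = 1e-12)
})

test_that("minority augmentation multiplies counts and keeps metadata", {
  segs <- make_segments(7, "FM", wl = 190)
  expect_identical(augment_minority(segs, 1), segs)
  aug <- augment_minority(segs, 3, seed = 4)
  expect_length(aug, 21)
  expect_equal(sum(aug$provenance == "original"), 7)
  expect_true(all(aug$label == "FM"))
  expect_equal(unique(aug$subject_id), "S1")
  # copies differ from originals but share per-sample norms
  expect_false(isTRUE(all.equal(aug$samples[8, , ], segs$samples[1, , ])))
  expect_equal(sqrt(rowSums(aug$samples[8, , 1:3]^2)),
               sqrt(rowSums(segs$samples[1, , 1:3]^2)), tolerance = 1e-9)
  # reproducible under the seed
  aug2 <- augment_minority(segs, 3, seed = 4)
  expect_identical(aug$samples, aug2$samples)
  # mixed labels are a contract error
  mixed <- make_segments(4, "N-FM", wl = 190)
  expect_error(augment_minority(mixed, 2), "minority")
})
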