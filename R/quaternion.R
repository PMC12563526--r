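#' Unit quaternions
#'
#' Hamilton-convention quaternions `(w, x, y, z)` with `i j = k`, used to
#' rotate six-axis IMU segments as if the sensor had been mounted in a
#' different orientation. Two coordinate frames are involved: the original
#' sensor frame S and the virtually rotated frame S'; a third, the inertial
#' frame I, appears when a reference orientation is tracked. The rotation
#' from S to S' is carried by a unit quaternion, and sensor vectors are
#' re-expressed in S' by the conjugation with the inverse on the left (the
#' passive convention): `v' = q^-1 (0, v) q`.
#'
#' @param w,x,y,z real components.
#' @return an object of class `fm_quaternion` (numeric length-4 vector).
#' @export
quaternion <- function(w, x = 0, y = 0, z = 0) {
  q <- c(w = unname(w), x = unname(x), y = unname(y), z = unname(z))
  if (!all(is.finite(q))) stop("quaternion components must be finite")
  structure(q, class = "fm_quaternion")
}

#' @export
print.fm_quaternion <- function(x, ...) {
  cat(sprintf("<quaternion> %.6f %+.6fi %+.6fj %+.6fk\n", x[1], x[2], x[3], x[4]))
  invisible(x)
}

q_norm <- function(q) sqrt(sum(unclass(q)^2))

#' @rdname quaternion
#' @param q a quaternion.
#' @export
q_normalize <- function(q) {
  n <- q_norm(q)
  if (n < 1e-12) stop("cannot normalize a near-zero quaternion")
  quaternion(q[1] / n, q[2] / n, q[3] / n, q[4] / n)
}

check_unit <- function(q, tol = 1e-6) {
  if (abs(q_norm(q) - 1) > tol)
    stop("quaternion is not unit within tolerance", call. = FALSE)
  invisible(q)
}

#' @rdname quaternion
#' @export
q_identity <- function() quaternion(1, 0, 0, 0)

#' @rdname quaternion
#' @export
q_inverse <- function(q) {
  check_unit(q)
  quaternion(q[1], -q[2], -q[3], -q[4])
}

#' Hamilton product of two unit quaternions
#'
#' @param a,b unit quaternions.
#' @return the renormalized Hamilton product `a %*% b` as an
#'   `fm_quaternion`.
#' @export
q_multiply <- function(a, b) {
  check_unit(a); check_unit(b)
  w <- a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4]
  x <- a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3]
  y <- a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2]
  z <- a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  q_normalize(quaternion(w, x, y, z))
}

axis_quaternion <- function(angle_rad, axis) {
  h <- angle_rad / 2
  v <- c(0, 0, 0)
  v[axis] <- sin(h)
  quaternion(cos(h), v[1], v[2], v[3])
}

#' Sample a small random rotation
#'
#' Draws independent per-axis angles uniformly on
#' `[-max_angle_deg, +max_angle_deg]` and composes the three axis rotations
#' intrinsically in the fixed order x then y then z (right-multiplication),
#' giving a unit quaternion suitable for virtual-rotation augmentation.
#'
#' @param max_angle_deg half-width of the per-axis angle range, in degrees;
#'   must lie in (0, 180).
#' @param seed optional seed for a reproducible draw.
#' @return a unit `fm_quaternion`.
#' @export
sample_rotation <- function(max_angle_deg = 15, seed = NULL) {
  if (!(max_angle_deg > 0 && max_angle_deg < 180))
    stop("max_angle_deg must lie in (0, 180)", call. = FALSE)
  with_seed(seed, {
    th <- stats::runif(3, -max_angle_deg, max_angle_deg) * pi / 180
    q <- q_multiply(q_multiply(axis_quaternion(th[1], 1),
                               axis_quaternion(th[2], 2)),
                    axis_quaternion(th[3], 3))
    q
  })
}

#' Rotate a 3-vector by quaternion conjugation
#'
#' Embeds `v` as a pure quaternion and applies the conjugation with the
#' inverse on the left, `v' = q^-1 (0, v) q`, returning the vector part.
#' This is the passive form: it re-expresses the same physical vector in
#' the rotated sensor frame. Norms are preserved.
#'
#' @param q a unit quaternion.
#' @param v numeric 3-vector.
#' @return rotated 3-vector.
#' @export
rotate_vector <- function(q, v) {
  check_unit(q)
  stopifnot(length(v) == 3L, all(is.finite(v)))
  qi <- q_inverse(q)
  # q^-1 * (0, v), computed without the unit check on the pure quaternion
  a <- unclass(qi); b <- c(0, v)
  p <- c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
         a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
         a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
         a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
  qq <- unname(unclass(q))
  p <- unname(p)
  c(p[1] * qq[2] + p[2] * qq[1] + p[3] * qq[4] - p[4] * qq[3],
    p[1] * qq[3] - p[2] * qq[4] + p[3] * qq[1] + p[4] * qq[2],
    p[1] * qq[4] + p[2] * qq[3] - p[3] * qq[2] + p[4] * qq[1])
}

# 3x3 matrix M with rotate_vector(q, v) == M %*% v; the transpose of the
# standard active rotation matrix of q
q_conjugation_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE) # active rotation matrix of q
  t(R)
}

#' Update a reference orientation
#'
#' Right-multiplies the reference orientation quaternion (sensor relative
#' to the inertial frame) by the virtual rotation, keeping orientation
#' labels consistent with the rotated signals.
#'
#' @param q_ref reference orientation quaternion (inertial to sensor).
#' @param q virtual rotation applied to the sensor frame.
#' @return updated reference quaternion `q_ref %*% q`.
#' @export
update_reference <- function(q_ref, q) q_multiply(q_ref, q)

#' Virtually rotate one segment
#'
#' Applies the frame rotation sample-wise to the accelerometer triple and,
#' with the same quaternion, to the gyroscope triple (both sensors sit on
#' the same rigid body). Labels and subject ids are unchanged; provenance
#' becomes `augmented`.
#'
#' @param seg an `fm_segments` object of length 1 (or a `window_len x 6`
#'   matrix).
#' @param q a unit quaternion.
#' @return object of the same type as `seg` with rotated samples.
#' @export
rotate_segment <- function(seg, q) {
  M <- q_conjugation_matrix(check_unit(q))
  rot <- function(m) cbind(m[, 1:3] %*% t(M), m[, 4:6] %*% t(M))
  if (is.matrix(seg)) {
    stopifnot(ncol(seg) == 6L)
    return(rot(seg))
  }
  stopifnot(inherits(seg, "fm_segments"))
  out <- seg
  for (i in seq_len(length(seg)))
    out$samples[i, , ] <- rot(seg$samples[i, , ])
  out$provenance <- factor(rep("augmented", length(seg)),
                           levels = c("original", "augmented"))
  out
}

#' Expand the minority class by virtual rotation
#'
#' Keeps the originals and appends `expansion_factor - 1` independently
#' rotated copies of each segment, each copy using a freshly sampled
#' quaternion, so the output has `expansion_factor` times the input count.
#' At the study scale this takes 686 FM training segments to 6860 with
#' `expansion_factor = 10`.
#'
#' @param segments an `fm_segments` object; all segments must share the
#'   minority label.
#' @param expansion_factor total expansion factor (originals included);
#'   `1` returns the input unchanged.
#' @param max_angle_deg per-axis rotation range passed to
#'   [sample_rotation()].
#' @param seed integer seed.
#' @param minority_label the label all inputs must carry.
#' @return an `fm_segments` object of length
#'   `expansion_factor * length(segments)`; originals first.
#' @export
augment_minority <- function(segments, expansion_factor, max_angle_deg = 15,
                             seed = 1L, minority_label = "FM") {
  stopifnot(inherits(segments, "fm_segments"), expansion_factor >= 1)
  expansion_factor <- as.integer(expansion_factor)
  if (!all(segments$label == minority_label))
    stop("augment_minority expects only minority-class ('", minority_label,
         "') segments", call. = FALSE)
  if (expansion_factor == 1L) return(segments)
  n <- length(segments)
  wl <- dim(segments$samples)[2]
  out <- array(0, c(n * expansion_factor, wl, 6L))
  out[seq_len(n), , ] <- segments$samples
  with_seed(seed, {
    at <- n
    for (r in seq_len(expansion_factor - 1L)) {
      for (i in seq_len(n)) {
        q <- sample_rotation(max_angle_deg)
        out[at + i, , ] <- rotate_segment(segments$samples[i, , ], q)
      }
      at <- at + n
    }
  })
  rep_f <- function(v) c(v, rep(v, expansion_factor - 1L))
  fm_segments(out,
              rep_f(as.character(segments$label)),
              rep_f(segments$subject_id),
              rep_f(segments$seg_index),
              c(rep("original", n), rep("augmented", n * (expansion_factor - 1L))),
              attr(segments, "sample_rate_hz"))
}
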