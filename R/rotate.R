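#' Estimate streamline rotation angles for one burst
#'
#' Computes the three misalignment-correction angles of the streamline
#' reference frame: first the x-y plane angle that zeroes the burst-mean
#' transverse velocity \eqn{\bar v}, then the x-z plane angle that zeroes the
#' burst-mean vertical velocity \eqn{\bar w} after the first rotation, and
#' finally a roll about the streamwise axis that zeroes the \eqn{v'w'}
#' covariance of the fluctuations,
#' \eqn{\theta = \tfrac12 \mathrm{atan2}(2\overline{v'w'},\,
#' \overline{v'^2} - \overline{w'^2})}. The rotations rest on the assumption
#' that well above the bed the flow is two-dimensional. Optionally
#' (`third_rotation = "xz"`) the third rotation is instead taken literally in
#' the x-z plane, zeroing \eqn{u'w'}.
#'
#' @param decomposed A `decomposed_burst` (see [decompose()]); the means come
#'   from the low-pass mean series, the covariance from the fluctuations.
#' @param min_speed Floor on \eqn{|\bar u|} (m s^-1) below which the
#'   streamline direction is indeterminate.
#' @param third_rotation `"roll"` (default, covariance-zeroing roll about x)
#'   or `"xz"`.
#' @return A `rotation_angles` object: `theta_xy`, `theta_xz`, `theta_cross`
#'   (degrees) and `source_elevations`.
#' @export
estimate_rotation_angles <- function(decomposed, min_speed = 1e-4,
                                     third_rotation = c("roll", "xz")) {
  third_rotation <- match.arg(third_rotation)
  d <- decomposed
  ub <- mean(d$u); vb <- mean(d$v); wb <- mean(d$w)
  if (!is.finite(ub) || abs(ub) <= min_speed)
    stop("indeterminate streamline direction: |u_mean| below floor")
  th1 <- atan2(vb, ub)
  r <- rot2(ub, vb, th1)
  th2 <- atan2(wb, r$a)
  # fluctuations after the first two rotations
  fu <- d$fluct_u; fv <- d$fluct_v; fw <- d$fluct_w
  r1 <- rot2(fu, fv, th1); fu <- r1$a; fv <- r1$b
  r2 <- rot2(fu, fw, th2); fu <- r2$a; fw <- r2$b
  # Small-angle solution of tan(2*theta) = 2 cov / (var_a - var_b): plain
  # atan keeps |theta| < 45 deg. (The atan2 form jumps to the principal-axis
  # solution ~90 deg away whenever var_a < var_b, which for turbulence --
  # where the vertical spectrum carries 4/3 the transverse density -- would
  # swap the axes instead of correcting a small misalignment.)
  half_atan <- function(cov_ab, dvar) {
    if (dvar == 0 && cov_ab == 0) return(0)
    if (dvar == 0) return(sign(cov_ab) * pi / 4)
    0.5 * atan(2 * cov_ab / dvar)
  }
  cvw <- mean(fv * fw) - mean(fv) * mean(fw)
  if (third_rotation == "roll") {
    th3 <- half_atan(cvw, (mean(fv^2) - mean(fv)^2) - (mean(fw^2) - mean(fw)^2))
  } else {
    cuw <- mean(fu * fw) - mean(fu) * mean(fw)
    th3 <- half_atan(cuw, (mean(fu^2) - mean(fu)^2) - (mean(fw^2) - mean(fw)^2))
  }
  ang <- c(th1, th2, th3) * 180 / pi
  if (any(!is.finite(ang)) || any(abs(ang) >= 90))
    stop("rotation angles not finite or >= 90 degrees; check burst orientation")
  structure(list(theta_xy = ang[1], theta_xz = ang[2], theta_cross = ang[3],
                 third_rotation = third_rotation,
                 source_elevations = d$elevation),
            class = "rotation_angles")
}

#' @export
print.rotation_angles <- function(x, ...) {
  cat(sprintf("<rotation_angles> xy %.4f deg, xz %.4f deg, cross %.4f deg (%s)\n",
              x$theta_xy, x$theta_xz, x$theta_cross, x$third_rotation))
  invisible(x)
}

#' Apply streamline rotation angles to a burst
#'
#' Composes the three plane rotations in the stated order (x-y, x-z, then the
#' cross-covariance rotation). The transform is orthogonal, so the per-sample
#' speed magnitude is preserved to machine precision. For a decomposed burst
#' the mean and fluctuating series are rotated separately (rotation is
#' linear), keeping the reconstruction identity intact.
#'
#' @param burst A `velocity_burst` or `decomposed_burst`.
#' @param angles A `rotation_angles` object.
#' @return Object of the same class, rotated.
#' @export
apply_rotation <- function(burst, angles) {
  stopifnot(inherits(angles, "rotation_angles"))
  a <- c(angles$theta_xy, angles$theta_xz, angles$theta_cross) * pi / 180
  if (any(!is.finite(a))) stop("angles must be finite")
  roll_xz <- identical(angles$third_rotation, "xz")
  rot_triplet <- function(u, v, w) {
    r <- rot2(u, v, a[1]); u <- r$a; v <- r$b
    r <- rot2(u, w, a[2]); u <- r$a; w <- r$b
    if (roll_xz) { r <- rot2(u, w, a[3]); u <- r$a; w <- r$b }
    else { r <- rot2(v, w, a[3]); v <- r$a; w <- r$b }
    list(u = u, v = v, w = w)
  }
  out <- burst
  r <- rot_triplet(burst$u, burst$v, burst$w)
  out$u <- r$u; out$v <- r$v; out$w <- r$w
  if (inherits(burst, "decomposed_burst")) {
    rm_ <- rot_triplet(burst$mean_u, burst$mean_v, burst$mean_w)
    rf <- rot_triplet(burst$fluct_u, burst$fluct_v, burst$fluct_w)
    out$mean_u <- rm_$u; out$mean_v <- rm_$v; out$mean_w <- rm_$w
    out$fluct_u <- rf$u; out$fluct_v <- rf$v; out$fluct_w <- rf$w
  }
  out$rotation <- angles
  out
}

#' Rotate a whole vertical profile with averaged upper-elevation angles
#'
#' The misalignment angles are estimated independently at the two highest
#' elevations of the profile (where the two-dimensional-flow assumption is
#' most defensible), arithmetically averaged per angle, and the averaged
#' angles applied to every burst in the profile.
#'
#' @param profile List of `decomposed_burst` objects with distinct
#'   `elevation` fields; at least two elevations required.
#' @param ... Passed to [estimate_rotation_angles()].
#' @return List with `bursts` (rotated profile) and `angles`
#'   (`rotation_angles` with `source_elevations` naming the two used).
#' @export
rotate_profile <- function(profile, ...) {
  if (length(profile) < 2) stop("profile needs >= 2 elevations")
  elev <- vapply(profile, function(b) as.numeric(b$elevation), numeric(1))
  if (anyNA(elev) || anyDuplicated(elev)) stop("profile elevations must be distinct")
  top2 <- order(elev, decreasing = TRUE)[1:2]
  angs <- lapply(profile[top2], estimate_rotation_angles, ...)
  avg <- structure(list(
    theta_xy = mean(vapply(angs, `[[`, 0, "theta_xy")),
    theta_xz = mean(vapply(angs, `[[`, 0, "theta_xz")),
    theta_cross = mean(vapply(angs, `[[`, 0, "theta_cross")),
    third_rotation = angs[[1]]$third_rotation,
    source_elevations = sort(elev[top2])), class = "rotation_angles")
  list(bursts = lapply(profile, apply_rotation, angles = avg), angles = avg)
}

#' Summarise one processed burst
#'
#' The per-burst row behind vertical mean-velocity and turbulence profiles:
#' burst-averaged mean velocities, fluctuation variances and the transverse-
#' vertical covariance, with positional metadata.
#'
#' @param decomposed A (typically despiked and rotated) `decomposed_burst`.
#' @param n_spikes Optional spike count to record.
#' @return One-row `data.frame`.
#' @export
burst_summary <- function(decomposed, n_spikes = NA_integer_) {
  d <- decomposed
  cv <- function(a, b) mean(a * b) - mean(a) * mean(b)
  data.frame(profile_id = d$profile_id %||% NA,
             location = d$location %||% NA,
             elevation_cmab = as.numeric(d$elevation %||% NA),
             u_mean = mean(d$mean_u), v_mean = mean(d$mean_v),
             w_mean = mean(d$mean_w),
             var_u = cv(d$fluct_u, d$fluct_u),
             var_v = cv(d$fluct_v, d$fluct_v),
             var_w = cv(d$fluct_w, d$fluct_w),
             cov_vw = cv(d$fluct_v, d$fluct_w),
             n_spikes = n_spikes, n = length(d$u),
             stringsAsFactors = FALSE)
}
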