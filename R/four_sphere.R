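#' Four-sphere volume-conductor head model
#'
#' Concentric-shell analytic head model mapping an intracranial current
#' dipole to scalp potential. The four shells represent gray matter,
#' cerebrospinal fluid, skull and scalp; the exterior is insulating. The
#' solution is a Legendre series whose per-order radial coefficients are
#' found by enforcing continuity of potential and radial current density at
#' the three interfaces and zero radial current at the scalp surface.
#'
#' @param radii Outer radii of the brain, CSF, skull and scalp shells, mm
#'   (strictly increasing).
#' @param conductivities Shell conductivities, S/m.
#' @param n_max Maximum series order; the series is truncated adaptively
#'   once terms fall below `tol` relative contribution.
#' @param tol Relative truncation tolerance.
#'
#' @return An object of class `four_sphere_model` with precomputed
#'   per-order surface gain coefficients.
#' @examples
#' mod <- four_sphere_model()
#' @export
four_sphere_model <- function(radii = c(79, 80, 85, 90),
                              conductivities = c(0.047, 1.71, 0.02, 0.41),
                              n_max = 400, tol = 1e-12) {
  stopifnot(length(radii) == 4, length(conductivities) == 4,
            all(diff(radii) > 0), all(conductivities > 0))
  m <- structure(list(radii = radii, sigma = conductivities,
                      n_max = n_max, tol = tol), class = "four_sphere_model")
  m$A <- four_sphere_gains(m)
  m
}

# Per-order surface gain A_n (dimensionless): scalp-surface potential per
# unit source, where the shell-1 source is the reference term
# s(r) = (r1/r)^(n+1). A dipole at radius rz contributes
# A_n * (rz/r1)^(n+1) * K_n with K_n the physical source coefficient.
# Numerically stable per-shell bases: in shell s (inner radius q_s, outer
# radius r_s), u(r) = (r/r_s)^n and v(r) = (q_s/r)^(n+1), both in [0, 1].
four_sphere_gains <- function(model) {
  r <- model$radii
  sg <- model$sigma
  q <- c(r[1], r[1], r[2], r[3]) # inner radius per shell (shell 1 unused v)
  vapply(seq_len(model$n_max), function(n) {
    u <- function(s, x) (x / r[s])^n
    v <- function(s, x) (q[s] / x)^(n + 1)
    du <- function(s, x) n / x * u(s, x)
    dv <- function(s, x) -(n + 1) / x * v(s, x)
    # unknowns: a1, a2, b2, a3, b3, a4, b4
    M <- matrix(0, 7, 7)
    rhs <- numeric(7)
    row <- 0
    for (i in 1:3) {
      ri <- r[i]
      # potential continuity at interface i / i+1
      row <- row + 1
      if (i == 1) M[row, 1] <- u(1, ri) else {
        M[row, 2 * i - 2] <- u(i, ri); M[row, 2 * i - 1] <- v(i, ri)
      }
      M[row, 2 * i] <- -u(i + 1, ri); M[row, 2 * i + 1] <- -v(i + 1, ri)
      rhs[row] <- if (i == 1) -(r[1] / ri)^(n + 1) else 0
      # radial current continuity
      row <- row + 1
      if (i == 1) M[row, 1] <- sg[i] * du(1, ri) else {
        M[row, 2 * i - 2] <- sg[i] * du(i, ri)
        M[row, 2 * i - 1] <- sg[i] * dv(i, ri)
      }
      M[row, 2 * i] <- -sg[i + 1] * du(i + 1, ri)
      M[row, 2 * i + 1] <- -sg[i + 1] * dv(i + 1, ri)
      rhs[row] <- if (i == 1) -sg[1] * (-(n + 1) / ri) * (r[1] / ri)^(n + 1)
                  else 0
    }
    # insulating exterior: zero radial current at the scalp surface
    row <- row + 1
    M[row, 6] <- du(4, r[4]); M[row, 7] <- dv(4, r[4])
    coef <- solve(M, rhs)
    coef[6] + coef[7] * (q[4] / r[4])^(n + 1)
  }, numeric(1))
}

# Legendre P_n(mu) and associated P_n^1(mu) (no Condon-Shortley phase),
# rows n = 1..n_max
legendre_table <- function(mu, n_max) {
  p <- numeric(n_max + 1)
  p1 <- numeric(n_max + 1) # index shifted: [n + 1] is order n
  p[1] <- 1; p[2] <- mu
  s <- sqrt(max(0, 1 - mu^2))
  p1[1] <- 0; p1[2] <- s
  for (n in 2:n_max) {
    p[n + 1] <- ((2 * n - 1) * mu * p[n] - (n - 1) * p[n - 1]) / n
    p1[n + 1] <- ((2 * n - 1) * mu * p1[n] - n * p1[n - 1]) / (n - 1)
  }
  list(p = p[-1], p1 = p1[-1])
}

#' Scalp potential of a current dipole in the four-sphere model
#'
#' Evaluates the Legendre-series solution for the radial and tangential
#' components of an arbitrary dipole. Units: positions mm, dipole moment
#' nA*um, output microvolts.
#'
#' @param model A [four_sphere_model()].
#' @param p Dipole moment vector, length 3, nA*um.
#' @param dipole_pos Dipole location, length 3, mm from the sphere center;
#'   must lie inside the brain shell.
#' @param electrode_pos Electrode location, length 3, mm; must lie on the
#'   scalp surface (radius equal to the outer radius within 0.1%).
#'
#' @return Scalp potential, microvolts.
#' @examples
#' mod <- four_sphere_model()
#' scalp_potential(mod, c(0, 0, 100), c(0, 0, 78), c(0, 0, 90))
#' @export
scalp_potential <- function(model, p, dipole_pos, electrode_pos) {
  stopifnot(inherits(model, "four_sphere_model"),
            length(p) == 3, length(dipole_pos) == 3,
            length(electrode_pos) == 3)
  rz <- sqrt(sum(dipole_pos^2))
  re <- sqrt(sum(electrode_pos^2))
  r4 <- model$radii[4]
  if (rz >= model$radii[1])
    stop("dipole must lie inside the brain shell (|pos| < ",
         model$radii[1], " mm)")
  if (abs(re - r4) > 1e-3 * r4)
    stop("electrode must lie on the scalp surface (|pos| = ", r4, " mm)")
  if (rz < 1e-9) stop("dipole at the sphere center is not supported")

  # local frame: z' radial through the dipole
  zhat <- dipole_pos / rz
  p_rad <- sum(p * zhat)
  p_tan_vec <- p - p_rad * zhat
  p_tan <- sqrt(sum(p_tan_vec^2))
  ehat <- electrode_pos / re
  mu <- min(1, max(-1, sum(ehat * zhat)))
  sin_theta <- sqrt(max(0, 1 - mu^2))
  cos_phi <- 0
  if (p_tan > 0 && sin_theta > 1e-12) {
    xhat <- p_tan_vec / p_tan
    cos_phi <- sum(ehat * xhat) / sin_theta
  }

  # SI conversion: mm -> m, nA*um -> A*m; K has units of volts
  rz_m <- rz * 1e-3
  k_rad <- (p_rad * 1e-15) / (4 * pi * model$sigma[1] * rz_m^2)
  k_tan <- (p_tan * 1e-15) / (4 * pi * model$sigma[1] * rz_m^2)

  leg <- legendre_table(mu, model$n_max)
  A <- model$A
  ratio <- rz / model$radii[1]
  phi <- 0
  total_scale <- 0
  for (n in seq_len(model$n_max)) {
    src <- ratio^(n + 1)
    term <- A[n] * src * (k_rad * n * leg$p[n] + k_tan * leg$p1[n] * cos_phi)
    phi <- phi + term
    scale_n <- abs(A[n]) * src * (abs(k_rad) * n + abs(k_tan)) # envelope
    total_scale <- max(total_scale, scale_n)
    if (n > 10 && scale_n < model$tol * max(total_scale, abs(phi), 1e-300))
      break
  }
  phi * 1e6 # V -> uV
}

#' Closed-form scalp potential for a homogeneous sphere (reference)
#'
#' Independent reference solution: a current dipole inside a homogeneous
#' conducting sphere with insulating exterior. The radial-dipole part uses
#' the closed-form sum of the image series; the tangential part sums its
#' analytically derived coefficient series directly. Useful as an oracle
#' for the four-sphere model with equal conductivities.
#'
#' @param sigma Conductivity, S/m.
#' @param radius Sphere radius, mm.
#' @param p Dipole moment vector, nA*um.
#' @param dipole_pos Dipole location, mm.
#' @param electrode_pos Electrode location on the surface, mm.
#' @param n_max Series order for the tangential part.
#' @return Surface potential, microvolts.
#' @export
homogeneous_sphere_potential <- function(sigma, radius, p, dipole_pos,
                                         electrode_pos, n_max = 3000) {
  rz <- sqrt(sum(dipole_pos^2))
  R <- radius
  zhat <- dipole_pos / rz
  p_rad <- sum(p * zhat)
  p_tan_vec <- p - p_rad * zhat
  p_tan <- sqrt(sum(p_tan_vec^2))
  ehat <- electrode_pos / sqrt(sum(electrode_pos^2))
  mu <- min(1, max(-1, sum(ehat * zhat)))
  sin_theta <- sqrt(max(0, 1 - mu^2))
  cos_phi <- 0
  if (p_tan > 0 && sin_theta > 1e-12) {
    xhat <- p_tan_vec / p_tan
    cos_phi <- sum(ehat * xhat) / sin_theta
  }

  R_m <- R * 1e-3
  x <- rz / R
  k_rad <- (p_rad * 1e-15) / (4 * pi * sigma)
  k_tan <- (p_tan * 1e-15) / (4 * pi * sigma)

  # radial: (k/R^2) * sum_{n>=1} (2n+1) x^(n-1) P_n(mu), closed form
  chi <- sqrt(1 - 2 * x * mu + x^2)
  s_rad <- (2 * x * (mu - x) / chi^3 + 1 / chi - 1) / x
  phi <- k_rad / R_m^2 * s_rad

  # tangential: (k cos(phi)/R^2) * sum_{n>=1} ((2n+1)/n) x^(n-1) P_n^1(mu)
  if (p_tan > 0 && sin_theta > 1e-12) {
    leg <- legendre_table(mu, n_max)
    n <- seq_len(n_max)
    s_tan <- sum((2 * n + 1) / n * x^(n - 1) * leg$p1)
    phi <- phi + k_tan * cos_phi / R_m^2 * s_tan
  }
  phi * 1e6
}

#' Project a dipole time series to a scalp EEG trace
#'
#' The four-sphere mapping is linear and time-invariant, so the EEG trace
#' is the dipole trace scaled by the static gain for the given geometry.
#' The dipole is oriented along the depth axis through its position
#' (radial), matching a cortical column under the electrode.
#'
#' @param trace A `dipole_trace` (moment along the depth axis, nA*um).
#' @param model A [four_sphere_model()].
#' @param dipole_pos Dipole location, mm (default radial at 78 mm, just
#'   under the brain-shell surface).
#' @param electrode_pos Electrode location, mm (default the vertex directly
#'   above the dipole).
#' @return An object of class `eeg_trace`: `x` (microvolts), `fs` (Hz),
#'   `gain` (microvolts per nA*um), positions.
#' @export
project_dipole <- function(trace, model = four_sphere_model(),
                           dipole_pos = c(0, 0, 78),
                           electrode_pos = c(0, 0, 90)) {
  stopifnot(inherits(trace, "dipole_trace"))
  if (!all(is.finite(trace$x))) stop("dipole trace contains non-finite values")
  axis <- dipole_pos / sqrt(sum(dipole_pos^2))
  gain <- scalp_potential(model, axis, dipole_pos, electrode_pos)
  structure(list(x = trace$x * gain, fs = trace$fs, gain = gain,
                 dipole_pos = dipole_pos, electrode_pos = electrode_pos,
                 units = "uV"), class = "eeg_trace")
}
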