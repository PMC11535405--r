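## Electron source on a micron-scale spherical target: sampling energy and
## direction from a binned joint fluence distribution, then entry positions
## on the sphere by uniform sampling of the perpendicular disk (chord
## construction).

#' Construct a binned joint energy-direction distribution
#'
#' Fluence density per unit dose, binned in electron kinetic energy and in
#' the direction cosine relative to the beam axis (+z). Weights carry units
#' of um^-2 Gy^-1 per bin; their sum is the total fluence per gray.
#'
#' @param energy_edges Strictly increasing bin edges, MeV.
#' @param cos_edges Strictly increasing bin edges in [-1, 1].
#' @param weights Matrix (energy bins x cos-theta bins) of non-negative
#'   fluence densities, um^-2 Gy^-1.
#' @return Object of class `joint_distribution`.
#' @seealso [synth_joint_distribution()] to generate a realistic fixture,
#'   [read_joint_distribution()] / [write_joint_distribution()] for file
#'   round-tripping.
#' @export
joint_distribution <- function(energy_edges, cos_edges, weights) {
  energy_edges <- as.numeric(energy_edges)
  cos_edges <- as.numeric(cos_edges)
  weights <- as.matrix(weights)
  stopifnot(
    all(diff(energy_edges) > 0), all(diff(cos_edges) > 0),
    min(cos_edges) >= -1, max(cos_edges) <= 1,
    nrow(weights) == length(energy_edges) - 1,
    ncol(weights) == length(cos_edges) - 1,
    all(weights >= 0)
  )
  structure(
    list(energy_edges = energy_edges, cos_edges = cos_edges,
         weights = weights),
    class = "joint_distribution"
  )
}

#' @export
print.joint_distribution <- function(x, ...) {
  cat(sprintf(
    "<joint_distribution> %d energy bins [%.3g, %.3g] MeV x %d cos-theta bins; total %.4g um^-2 Gy^-1\n",
    nrow(x$weights), min(x$energy_edges), max(x$energy_edges),
    ncol(x$weights), sum(x$weights)))
  invisible(x)
}

#' Total fluence per gray of a joint distribution
#'
#' @param dist A `joint_distribution`.
#' @return Sum of bin weights, um^-2 Gy^-1.
#' @export
total_fluence_per_gray <- function(dist) sum(dist$weights)

#' Sample energies and directions from a joint distribution
#'
#' Draws (E, cos-theta) pairs proportionally to bin weights, uniformly within
#' the selected bin, and azimuthal angles phi uniformly on [0, 2*pi) (the
#' geometry is axially symmetric). Uses the session RNG.
#'
#' @param dist A `joint_distribution` with positive total weight.
#' @param n Number of draws.
#' @return data.frame with columns `energy_MeV`, `cos_theta`, `phi`.
#' @examples
#' set.seed(1)
#' d <- synth_joint_distribution()
#' s <- sample_energy_direction(d, 1000)
#' @export
sample_energy_direction <- function(dist, n) {
  stopifnot(inherits(dist, "joint_distribution"), n >= 0)
  w <- as.vector(dist$weights)
  if (sum(w) <= 0) stop("joint distribution has zero total weight")
  if (n == 0) {
    return(data.frame(energy_MeV = numeric(0), cos_theta = numeric(0),
                      phi = numeric(0)))
  }
  bins <- sample.int(length(w), n, replace = TRUE, prob = w)
  ne <- nrow(dist$weights)
  ei <- (bins - 1) %% ne + 1
  ci <- (bins - 1) %/% ne + 1
  e_lo <- dist$energy_edges[ei]
  e_hi <- dist$energy_edges[ei + 1]
  c_lo <- dist$cos_edges[ci]
  c_hi <- dist$cos_edges[ci + 1]
  data.frame(
    energy_MeV = stats::runif(n, e_lo, e_hi),
    cos_theta = stats::runif(n, c_lo, c_hi),
    phi = stats::runif(n, 0, 2 * pi)
  )
}

# Orthonormal basis (u, v) perpendicular to unit vector d (3-vector).
.perp_basis <- function(d) {
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- c(a[2] * d[3] - a[3] * d[2],
         a[3] * d[1] - a[1] * d[3],
         a[1] * d[2] - a[2] * d[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

#' Entry point of an electron on the sphere surface (chord construction)
#'
#' Samples a position uniformly on the disk of radius `R` perpendicular to
#' the propagation direction, then takes the upstream intersection of the
#' line through that position along the direction with the sphere surface —
#' the intersection from which the electron propagates toward the sphere
#' interior. Rim points (chord length 0, a measure-zero event) are resampled.
#'
#' @param direction Unit 3-vector of propagation.
#' @param R Sphere radius, um.
#' @return Entry position 3-vector, um; satisfies |position| = R and
#'   position . direction <= 0.
#' @examples
#' p <- chord_entry_point(c(0, 0, 1), 2)
#' sqrt(sum(p^2))  # 2
#' @export
chord_entry_point <- function(direction, R) {
  stopifnot(R > 0, abs(sqrt(sum(direction^2)) - 1) < 1e-9)
  b <- .perp_basis(direction)
  repeat {
    r <- R * sqrt(stats::runif(1))
    if (r < R) break  # rim guard (measure zero)
  }
  a <- stats::runif(1, 0, 2 * pi)
  p <- r * (cos(a) * b$u + sin(a) * b$v)
  p - sqrt(max(R^2 - r^2, 0)) * direction
}

#' Vectorized parallel-beam entry sampling
#'
#' Samples `n` entry points for a common direction; used for the
#' chord-length statistics of a parallel beam. The chord length of each
#' entry is 2*sqrt(R^2 - r^2) with r the sampled disk radius; its analytic
#' mean over the uniform disk is 4R/3 and its density is l/(2 R^2) on
#' [0, 2R].
#'
#' @param n Number of samples.
#' @param direction Unit 3-vector.
#' @param R Sphere radius, um.
#' @return List with `position` (n x 3 matrix) and `chord` (lengths, um).
#' @export
sample_entry_points <- function(n, direction = c(0, 0, 1), R = 2) {
  stopifnot(R > 0, abs(sqrt(sum(direction^2)) - 1) < 1e-9, n >= 0)
  b <- .perp_basis(direction)
  r <- R * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  half <- sqrt(pmax(R^2 - r^2, 0))
  pos <- outer(r * cos(a), b$u) + outer(r * sin(a), b$v) -
    outer(half, direction)
  list(position = pos, chord = 2 * half)
}

#' Generate the electron source-point list for a bunch schedule
#'
#' One source point per electron: energy and direction sampled from the
#' joint distribution, entry position from the chord construction, emission
#' time shared within a bunch. The beam axis is +z; a sampled (cos-theta,
#' phi) maps to direction (sin-theta cos-phi, sin-theta sin-phi, cos-theta).
#'
#' @param dist A `joint_distribution`.
#' @param schedule A `bunch_schedule` from [sample_emission_times()].
#' @param R Sphere radius, um (default 2).
#' @return data.frame with columns `x`, `y`, `z` (um), `dx`, `dy`, `dz`,
#'   `energy_MeV`, `emission_time_s`, `bunch`.
#' @examples
#' set.seed(1)
#' sched <- sample_emission_times(100, 10, make_pulse_train(5, 1.8e-6))
#' src <- generate_source(synth_joint_distribution(), sched, R = 2)
#' nrow(src)  # 100
#' @export
generate_source <- function(dist, schedule, R = 2) {
  stopifnot(inherits(schedule, "bunch_schedule"))
  n <- schedule$n_electrons
  ed <- sample_energy_direction(dist, n)
  st <- sqrt(pmax(1 - ed$cos_theta^2, 0))
  dirs <- cbind(st * cos(ed$phi), st * sin(ed$phi), ed$cos_theta)
  pos <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    pos[i, ] <- chord_entry_point(dirs[i, ], R)
  }
  bunch <- rep(seq_along(schedule$emission_times),
               schedule$electrons_per_bunch)
  data.frame(
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
    energy_MeV = ed$energy_MeV,
    emission_time_s = schedule$emission_times[bunch],
    bunch = bunch
  )
}

#' Energy needed to deposit a dose in a water sphere
#'
#' E = dose * rho * (4/3) pi R^3 with rho = 1 g/cm^3, converted to eV. This
#' is the dose-threshold bookkeeping that defines how many electrons form a
#' pulse when a per-electron mean energy deposit is known.
#'
#' @param dose Dose, Gy.
#' @param R Sphere radius, um.
#' @return Energy, eV.
#' @examples
#' sphere_dose_to_energy(10, 2)  # ~2.09e6 eV
#' @export
sphere_dose_to_energy <- function(dose, R) {
  stopifnot(dose >= 0, R > 0)
  volume_m3 <- (4 / 3) * pi * (R * 1e-6)^3
  mass_kg <- 1000 * volume_m3  # water density 1000 kg/m^3
  dose * mass_kg / .EV_J
}

#' Electron count to reach a dose threshold
#'
#' @param dose Target dose in the sphere, Gy.
#' @param R Sphere radius, um.
#' @param mean_deposit_eV Mean energy deposited in the sphere per electron,
#'   eV (caller-supplied; the package implements no track physics).
#' @return Integer electron count (ceiling).
#' @export
electrons_for_dose <- function(dose, R, mean_deposit_eV) {
  stopifnot(mean_deposit_eV > 0)
  as.integer(ceiling(sphere_dose_to_energy(dose, R) / mean_deposit_eV))
}
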