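# Thermodynamic scans: temperature-dependent contact-energy scale and heat
# capacity from the partition function.

#' Temperature-dependent contact-energy scale
#'
#' \deqn{\epsilon(T) = \epsilon_f + p(1 - T/T_f) -
#'   q[(1 - T/T_f) + (T/T_f)\ln(T/T_f)]}
#' By construction \eqn{\epsilon(T_f) = \epsilon_f} exactly; `p` and `q`
#' shape the enthalpic/heat-capacity contributions of solvation.
#'
#' @param temperature Temperature(s), K (> 0).
#' @param eps_f Scale at the reference temperature.
#' @param p,q Linear and curvature coefficients.
#' @param T_f Reference temperature, K.
#' @return epsilon(T), dimensionless scale (vectorized).
#' @export
epsilon_of_T <- function(temperature, eps_f, p, q, T_f) {
  stopifnot(all(temperature > 0))
  x <- temperature / T_f
  eps_f + p * (1 - x) - q * ((1 - x) + x * log(x))
}

#' Heat capacity from a log-partition-function builder
#'
#' \eqn{C(T) = \frac{d}{dT}\left(k_B T^2 \frac{d \ln Z}{dT}\right)}
#' evaluated with second-order central differences on a uniform temperature
#' grid: \eqn{C = k_B (2 T \ln Z' + T^2 \ln Z'')} at interior grid points
#' (a 5-point grid yields 3 interior values). Re-evaluate epsilon(T) inside
#' `log_z` when the contact scale is temperature dependent.
#'
#' @param log_z Function `T -> ln Z` (total partition function).
#' @param T_grid Uniform temperature grid, K (>= 5 points).
#' @param baseline Constant added to C, kcal/(mol K) (default 0).
#' @return Data frame with columns `T` and `C` (kcal/(mol K)), interior
#'   points only; class `wsme_thermo_scan`.
#' @export
heat_capacity <- function(log_z, T_grid, baseline = 0) {
  if (length(T_grid) < 5) stop("need at least 5 temperature grid points")
  h <- diff(T_grid)
  if (max(abs(h - h[1])) > 1e-9 * h[1]) stop("temperature grid must be uniform")
  h <- h[1]
  lz <- vapply(T_grid, log_z, 0)
  m <- length(T_grid)
  interior <- 2:(m - 1)
  d1 <- (lz[interior + 1] - lz[interior - 1]) / (2 * h)
  d2 <- (lz[interior + 1] - 2 * lz[interior] + lz[interior - 1]) / h^2
  Tm <- T_grid[interior]
  C <- .wsme$R_kcal * (2 * Tm * d1 + Tm^2 * d2) + baseline
  structure(data.frame(T = Tm, C = C),
            class = c("wsme_thermo_scan", "data.frame"))
}
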