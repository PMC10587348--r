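# Theoretical Phi-value analysis and degree of disulfide-bond formation.
#
# A pseudo-mutation perturbs all native contacts of one residue at once by
# eta_{i,j} = 0.1 |eps_{i,j}| (attractive contacts only); the normalized
# free-energy response along the folding pathway is the theoretical Phi
# value, 0 for an unfolded residue and 1 for a natively packed one. A
# perturbation on a single Cys-Cys contact instead yields a finite-difference
# estimate of the probability that the disulfide contact is formed.

#' Pseudo-mutation perturbation matrix for one residue
#'
#' `eta[i,l] = scale * |eps[i,l]|` for attractive contacts of residue l
#' (`eps < 0`), 0 otherwise and everywhere off the residue's row/column.
#'
#' @param model A `wsme_energy_model`.
#' @param l Residue index.
#' @param scale Perturbation scale (default 0.1).
#' @return N x N symmetric matrix, kcal/mol.
#' @export
phi_perturbation <- function(model, l, scale = 0.1) {
  E <- contact_energies(model)
  n <- model$n
  eta <- matrix(0, n, n)
  att <- E[, l] < 0
  eta[att, l] <- scale * abs(E[att, l])
  eta[l, att] <- eta[att, l]
  eta
}

#' Single-contact perturbation matrix (disulfide formation probe)
#'
#' @param model A `wsme_energy_model`.
#' @param i,j Contact pair with attractive energy (`eps[i,j] < 0`).
#' @param scale Perturbation scale.
#' @return N x N matrix with `eta[i,j] = eta[j,i] = scale * |eps[i,j]|`.
#' @export
ss_perturbation <- function(model, i, j, scale = 0.1) {
  E <- contact_energies(model)
  if (E[i, j] >= 0)
    stop("contact (", i, ",", j, ") is not attractive; eta would be 0")
  eta <- matrix(0, model$n, model$n)
  eta[i, j] <- scale * abs(E[i, j])
  eta[j, i] <- eta[i, j]
  eta
}

# free-energy difference profile -k_B T ln(Z^Mu/Z) per bin (vector over bins)
perturbation_free_energy <- function(zmu, z) {
  RT <- .wsme$R_kcal * z$temperature
  -RT * (zmu$lm - z$lm)
}

#' Theoretical Phi values of one residue along a pathway
#'
#' Evaluates, for each pathway bin n, the normalized free-energy response
#' \deqn{\Phi_{th,l}(n) = \frac{\Delta F_l(n) - \Delta F_l(0)}
#'   {\Delta F_l(1) - \Delta F_l(0)}}
#' where \eqn{\Delta F_l(n) = -k_B T \ln[Z^{Mu}_{L,l}(n)/Z_L(n)]} compares the
#' linker ensembles with and without the residue-l pseudo-mutation. Negative
#' values are clamped to 0; a vanishing denominator (residue without
#' attractive contacts) yields NA ("missing", not 0).
#'
#' @param model A `wsme_energy_model`.
#' @param entropy A `wsme_entropy_model`.
#' @param temperature K.
#' @param spec A `wsme_order_spec`.
#' @param l Residue index.
#' @param path Data frame with bin indices i1, i2 (e.g. from
#'   [dominant_pathway()]); default the full 1D grid.
#' @param linkers Linker pairs (default [linker_set()]).
#' @param z_l Optional precomputed unperturbed ensemble (reused across
#'   residues).
#' @param scale Perturbation scale.
#' @param method `"tm"` or `"enumerate"`.
#' @param denom_tol Denominator magnitude below which Phi is reported NA.
#' @return List with `phi` (clamped values per path bin), `raw` (unclamped),
#'   `denominator` (kcal/mol).
#' @export
phi_theory <- function(model, entropy, temperature, spec, l,
                       path = NULL, linkers = linker_set(model),
                       z_l = NULL, scale = 0.1,
                       method = c("tm", "enumerate"), denom_tol = 1e-8) {
  method <- match.arg(method)
  if (is.null(z_l))
    z_l <- wsme_l_partition(model, entropy, temperature, spec,
                            linkers = linkers, method = method)
  eta <- phi_perturbation(model, l, scale)
  zmu <- wsme_l_partition(model, entropy, temperature, spec,
                          linkers = linkers, eta = eta, method = method)
  dF <- perturbation_free_energy(zmu, z_l)
  dF <- dF - dF[1, 1]
  denom <- dF[nrow(dF), ncol(dF)]
  if (is.null(path)) {
    stopifnot(!spec$two_d)
    path <- data.frame(i1 = seq_len(nrow(dF)), i2 = 1L)
  }
  vals <- dF[cbind(path$i1, path$i2)]
  if (abs(denom) < denom_tol) {
    return(list(phi = rep(NA_real_, nrow(path)),
                raw = rep(NA_real_, nrow(path)), denominator = denom))
  }
  raw <- vals / denom
  list(phi = pmax(raw, 0), raw = raw, denominator = denom)
}

#' Phi profile over all residues
#'
#' @inheritParams phi_theory
#' @return Matrix residues x path bins of clamped Phi values (NA rows for
#'   residues without attractive contacts).
#' @export
phi_profile <- function(model, entropy, temperature, spec,
                        path = NULL, linkers = linker_set(model),
                        scale = 0.1, method = c("tm", "enumerate")) {
  method <- match.arg(method)
  z_l <- wsme_l_partition(model, entropy, temperature, spec,
                          linkers = linkers, method = method)
  if (is.null(path)) {
    stopifnot(!spec$two_d)
    path <- data.frame(i1 = seq_len(nrow(z_l$lm)), i2 = 1L)
  }
  out <- matrix(NA_real_, model$n, nrow(path))
  for (l in seq_len(model$n)) {
    out[l, ] <- phi_theory(model, entropy, temperature, spec, l,
                           path = path, linkers = linkers, z_l = z_l,
                           scale = scale, method = method)$phi
  }
  out
}

#' Degree of disulfide-bond formation
#'
#' Finite-difference estimate of the probability that the Cys-Cys contact
#' (i, j) is formed at each order-parameter bin:
#' \deqn{\Phi^{SS}_{i,j}(n) = \frac{-k_B T \ln Z^{Mu}_{L,i,j}(n) +
#'   k_B T \ln Z_L(n)}{\eta_{i,j}}}
#' with the single-contact perturbation
#' \eqn{\eta_{i,j} = 0.1 |\epsilon_{i,j}|}.
#'
#' @inheritParams phi_theory
#' @param i,j Disulfide contact pair (attractive).
#' @return List with `phi_ss` (vector over bins of the 1D grid, or matrix for
#'   2D), `eta` (kcal/mol).
#' @export
phi_ss <- function(model, entropy, temperature, spec, i, j,
                   linkers = linker_set(model), z_l = NULL, scale = 0.1,
                   method = c("tm", "enumerate")) {
  method <- match.arg(method)
  eta <- ss_perturbation(model, i, j, scale)
  eta_ij <- eta[i, j]
  if (is.null(z_l))
    z_l <- wsme_l_partition(model, entropy, temperature, spec,
                            linkers = linkers, method = method)
  zmu <- wsme_l_partition(model, entropy, temperature, spec,
                          linkers = linkers, eta = eta, method = method)
  dF <- perturbation_free_energy(zmu, z_l)
  list(phi_ss = dF / eta_ij, eta = eta_ij)
}

#' Domain-averaged Phi value
#'
#' Arithmetic mean of the Phi values of a residue set at one state's bin,
#' used to translate state populations into domain-level structure formation.
#'
#' @param profile Residues x bins matrix (e.g. from [phi_profile()]).
#' @param residues Non-empty residue index set.
#' @param bin Column index of the state's bin within the profile.
#' @return Scalar mean (NA values dropped with a warning).
#' @export
domain_phi_average <- function(profile, residues, bin) {
  stopifnot(length(residues) >= 1)
  vals <- profile[residues, bin]
  if (anyNA(vals)) {
    warning("dropping ", sum(is.na(vals)), " residues with undefined Phi")
    vals <- vals[!is.na(vals)]
  }
  mean(vals)
}
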