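# Transfer-matrix wrappers. The C++ engine evaluates the generating-function
# product over stretch transfer matrices as a polynomial in the order
# parameter indeterminant(s); these wrappers attach the model/entropy objects,
# apply linker masks and state-independent energy offsets, and return
# partition tables in the shared (log-magnitude, sign) representation.

# shared low-level: partition table from an explicit energy matrix
run_partition <- function(E, entropy, temperature, spec,
                          linkers = NULL, energy_offset = 0,
                          method = c("tm", "enumerate")) {
  method <- match.arg(method)
  n <- nrow(E)
  if (is.null(linkers)) linkers <- matrix(integer(), 0, 2)
  linkers <- matrix(as.integer(linkers), ncol = 2)
  if (method == "tm") {
    lm <- tm_engine_cpp(E, entropy$S, temperature, spec$axis, linkers,
                        .wsme$R_cal, .wsme$R_kcal)
    lm <- lm - energy_offset / (.wsme$R_kcal * temperature)
    new_partition_table(lm, sg = (lm > -Inf) * 1, spec, temperature)
  } else {
    tmp <- new_energy_model(n, E, eps = 1)
    enumerate_partition(tmp, entropy, temperature, spec,
                        linkers = if (nrow(linkers)) linkers else NULL,
                        energy_offset = energy_offset)
  }
}

#' Restricted partition function (no linker)
#'
#' Exact evaluation of the partition function restricted by the order
#' parameter(s), by the polynomial transfer-matrix route (default) or by the
#' exhaustive-enumeration oracle.
#'
#' @param model A `wsme_energy_model`.
#' @param entropy A `wsme_entropy_model`.
#' @param temperature Temperature, K.
#' @param spec A `wsme_order_spec`.
#' @param method `"tm"` (polynomial in N) or `"enumerate"` (2^N oracle,
#'   N <= 22).
#' @return A `wsme_partition_table`.
#' @export
restricted_partition <- function(model, entropy, temperature, spec,
                                 method = c("tm", "enumerate")) {
  stopifnot(model$n == entropy$n, model$n == spec$n)
  run_partition(contact_energies(model), entropy, temperature, spec,
                method = match.arg(method))
}

#' Restricted partition function with one virtual linker
#'
#' The linked partition function: the Hamiltonian counts a contact when its
#' residues are joined through the main chain or through the linker (u, v);
#' the five weights around (u, v) are zeroed to avoid double counting and the
#' state-independent linker gain eps'(u,v) enters the exponent of every
#' microstate, as printed.
#'
#' @inheritParams restricted_partition
#' @param u,v Linker endpoints, `u < v`.
#' @param eta Optional symmetric perturbation matrix (kcal/mol) added to the
#'   contact energies without masking; its five values around (u, v) are
#'   added to the energy offset (the Delta-eps' correction).
#' @return A `wsme_partition_table`.
#' @export
linked_partition <- function(model, entropy, temperature, spec, u, v,
                             eta = NULL, method = c("tm", "enumerate")) {
  stopifnot(u >= 1, v <= model$n, u < v)
  lg <- linker_gain(model, u, v)
  E <- contact_energies(mask_linker_pairs(model, u, v))
  offset <- lg$eps_prime
  if (!is.null(eta)) {
    # eta follows the same convention as eps inside a linked component:
    # masked in the Hamiltonian, carried by the Delta-eps' constant
    offset <- offset + sum(eta[lg$mask])
    eta[lg$mask] <- 0
    eta[lg$mask[, 2:1, drop = FALSE]] <- 0
    E <- E + eta
  }
  run_partition(E, entropy, temperature, spec,
                linkers = matrix(c(u, v), 1), energy_offset = offset,
                method = match.arg(method))
}

#' Restricted partition function with two linkers
#'
#' The double-linker partition function: contacts count when joined through
#' the main chain or through either linker. Only the first linker's
#' double-counting mask and gain eps'(u1,v1) are applied (the convention of
#' the disulfide-intact ensemble, where the second linker is a disulfide
#' whose contact weights have already been removed from the model).
#'
#' @inheritParams linked_partition
#' @param linker1,linker2 Length-2 vectors (u, v), `u < v`, distinct.
#' @return A `wsme_partition_table`.
#' @export
double_linked_partition <- function(model, entropy, temperature, spec,
                                    linker1, linker2, eta = NULL,
                                    method = c("tm", "enumerate")) {
  if (identical(as.integer(linker1), as.integer(linker2)))
    stop("identical linkers: use the single-linker path")
  u1 <- linker1[1]; v1 <- linker1[2]
  stopifnot(u1 < v1, linker2[1] < linker2[2])
  lg <- linker_gain(model, u1, v1)
  E <- contact_energies(mask_linker_pairs(model, u1, v1))
  offset <- lg$eps_prime
  if (!is.null(eta)) {
    offset <- offset + sum(eta[lg$mask])
    eta[lg$mask] <- 0
    eta[lg$mask[, 2:1, drop = FALSE]] <- 0
    E <- E + eta
  }
  run_partition(E, entropy, temperature, spec,
                linkers = rbind(linker1, linker2), energy_offset = offset,
                method = match.arg(method))
}
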