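# Exhaustive-enumeration oracle. Brute-force 2^N evaluation of every
# Hamiltonian and restricted partition function; defines the microstate
# semantics the transfer-matrix route must reproduce. Deliberately simple and
# loop-heavy; guarded at N <= 22.

ENUM_GUARD <- 22L

#' All microstates of an N-residue chain
#' @param n Residue count (N <= 22).
#' @return 2^N x N binary matrix; row order is the binary counting order.
#' @export
microstates <- function(n) {
  if (n > ENUM_GUARD)
    stop("enumeration guarded at N <= ", ENUM_GUARD,
         "; use the transfer-matrix route")
  states <- 0:(2^n - 1)
  m <- matrix(0L, length(states), n)
  for (k in seq_len(n)) m[, k] <- bitwAnd(bitwShiftR(states, k - 1L), 1L)
  m
}

# m_{i,j} for one state vector, with the empty-product convention m_{i+1,i}=1
m_run <- function(m, i, j) {
  if (i > j) return(1L)
  as.integer(all(m[i:j] == 1L))
}

#' WSME Hamiltonian of one microstate
#'
#' \eqn{H(\{m\}) = \sum_{i<j} \epsilon_{i,j} m_{i,j}} with
#' \eqn{m_{i,j} = \prod_{k=i}^{j} m_k}.
#'
#' @param state Binary vector of residue states.
#' @param model A `wsme_energy_model`.
#' @return Energy in kcal/mol.
#' @export
hamiltonian <- function(state, model) {
  n <- model$n
  if (length(state) != n) stop("state length does not match model")
  E <- contact_energies(model)
  h <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (E[i, j] != 0) h <- h + E[i, j] * m_run(state, i, j)
  }
  h
}

#' Linker connectivity indicator
#'
#' \eqn{m^{(u,v)}_{i,j}}: 1 when residues i and j are joined in a native
#' stretch through the linker shortcut (i connected to u and v connected to j
#' along the main chain), else 0.
#'
#' @param state Binary vector.
#' @param i,j Contact pair, `i < j`.
#' @param u,v Linker endpoints, `u < v`.
#' @return 0 or 1.
#' @export
linked_indicator <- function(state, i, j, u, v) {
  m_run(state, min(i, u), max(u, i)) * m_run(state, min(v, j), max(j, v))
}

#' Linked Hamiltonian (OR of main-chain and linker connectivity)
#'
#' Each contact contributes its energy when the main-chain indicator or any
#' linker indicator is 1; the ceiling of the averaged indicator sum in the
#' printed Hamiltonians is exactly this logical OR. Weights are used as
#' supplied (apply the double-counting mask first when composing linked
#' partition functions).
#'
#' @param state Binary vector.
#' @param model A `wsme_energy_model` (weights already masked if desired).
#' @param linkers Two-column matrix of linker pairs (one or more rows).
#' @return Energy in kcal/mol.
#' @export
hamiltonian_linked <- function(state, model, linkers) {
  linkers <- matrix(as.integer(linkers), ncol = 2)
  if (nrow(linkers) < 1L) stop("at least one linker required")
  n <- model$n
  E <- contact_energies(model)
  h <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (E[i, j] == 0) next
    on <- m_run(state, i, j)
    if (!on) for (k in seq_len(nrow(linkers))) {
      if (linked_indicator(state, i, j, linkers[k, 1], linkers[k, 2])) {
        on <- 1L; break
      }
    }
    if (on) h <- h + E[i, j]
  }
  h
}

# vectorized over all states: matrix M (2^N x N) -> indicator column
m_run_all <- function(M, i, j) {
  if (i > j) return(rep(1L, nrow(M)))
  if (i == j) return(M[, i])
  as.integer(rowSums(M[, i:j, drop = FALSE]) == (j - i + 1L))
}

linked_indicator_all <- function(M, i, j, u, v) {
  m_run_all(M, min(i, u), max(u, i)) * m_run_all(M, min(v, j), max(j, v))
}

# per-state Hamiltonian (and optionally a single contact's OR indicator)
hamiltonian_all <- function(M, E, linkers = NULL, track_pair = NULL) {
  n <- ncol(M)
  h <- numeric(nrow(M))
  tracked <- NULL
  pairs <- which(E != 0 & upper.tri(E), arr.ind = TRUE)
  if (!is.null(track_pair))
    pairs <- unique(rbind(pairs, matrix(track_pair, 1)))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    on <- m_run_all(M, i, j)
    if (!is.null(linkers) && nrow(linkers) > 0) {
      for (k in seq_len(nrow(linkers))) {
        off <- on == 0L
        if (!any(off)) break
        on[off] <- linked_indicator_all(M[off, , drop = FALSE], i, j,
                                        linkers[k, 1], linkers[k, 2])
      }
    }
    h <- h + E[i, j] * on
    if (!is.null(track_pair) && i == track_pair[1] && j == track_pair[2])
      tracked <- on
  }
  if (is.null(track_pair)) h else list(h = h, tracked = tracked)
}

#' Restricted partition function by exhaustive enumeration
#'
#' Sums \eqn{\exp[-(H + \mathrm{offset} - T \sum_i S_i m_i)/k_B T]} over all
#' 2^N microstates into bins indexed by the native count(s) of the order
#' parameter spec. With linkers, H is the linked (OR) Hamiltonian; the
#' state-independent linker gain eps' is passed via `energy_offset` by the
#' ensemble builders.
#'
#' @param model A `wsme_energy_model` (weights already masked for linked use).
#' @param entropy A `wsme_entropy_model`.
#' @param temperature Temperature in K.
#' @param spec A `wsme_order_spec`.
#' @param linkers Optional two-column matrix of linker pairs.
#' @param energy_offset Constant added inside the exponent, kcal/mol.
#' @return A `wsme_partition_table` (log-magnitude + sign representation).
#' @export
enumerate_partition <- function(model, entropy, temperature, spec,
                                linkers = NULL, energy_offset = 0) {
  n <- model$n
  stopifnot(entropy$n == n, spec$n == n, temperature > 0)
  if (n > ENUM_GUARD)
    stop("enumeration guarded at N <= ", ENUM_GUARD,
         "; use the transfer-matrix route")
  M <- microstates(n)
  E <- contact_energies(model)
  if (!is.null(linkers)) linkers <- matrix(as.integer(linkers), ncol = 2)
  h <- hamiltonian_all(M, E, linkers)
  lw <- -(h + energy_offset) / (.wsme$R_kcal * temperature) +
    as.vector(M %*% entropy$S) / .wsme$R_cal
  k1 <- as.vector(M %*% (spec$axis == 1L))
  k2 <- as.vector(M %*% (spec$axis == 2L))
  lm <- matrix(-Inf, spec$n1 + 1L, spec$n2 + 1L)
  bin <- k1 * (spec$n2 + 1L) + k2
  for (b in unique(bin)) {
    lm[b %/% (spec$n2 + 1L) + 1L, b %% (spec$n2 + 1L) + 1L] <-
      logsumexp(lw[bin == b])
  }
  new_partition_table(lm, sg = (lm > -Inf) * 1, spec, temperature)
}

#' Thermal contact occupancy in the linker ensemble (oracle)
#'
#' Enumeration-based first-order response of the linker-ensemble free energy
#' to a perturbation on one contact: the ensemble-weighted expectation of the
#' contact's connectivity indicator, where the component with linker (u, v)
#' uses the OR indicator and additionally counts 1 when (i, j) lies in the
#' (u, v) double-counting neighbourhood (the linker itself carries the
#' contact). This is the quantity the degree-of-disulfide-formation statistic
#' estimates by finite differences.
#'
#' @param model Unmasked `wsme_energy_model`.
#' @param entropy A `wsme_entropy_model` with distances.
#' @param temperature K.
#' @param spec A `wsme_order_spec` (1D).
#' @param pair Length-2 contact (i, j), i < j.
#' @param linkers Linker list as from [linker_set()].
#' @return Vector over bins of the expected indicator (0..1-ish).
#' @export
contact_occupancy_oracle <- function(model, entropy, temperature, spec, pair,
                                     linkers) {
  n <- model$n
  M <- microstates(n)
  i <- pair[1]; j <- pair[2]
  beta <- 1 / (.wsme$R_kcal * temperature)
  k1 <- as.vector(M %*% (spec$axis == 1L))
  k2 <- as.vector(M %*% (spec$axis == 2L))
  bin <- k1 * (spec$n2 + 1L) + k2
  bins <- sort(unique(bin))
  lsw <- as.vector(M %*% entropy$S) / .wsme$R_cal

  comp <- function(E, linkmat, offset, track_extra) {
    ht <- hamiltonian_all(M, E, linkmat, track_pair = pair)
    lw <- -beta * (ht$h + offset) + lsw
    ind <- pmin(ht$tracked + track_extra, 1)
    lz <- vapply(bins, function(b) logsumexp(lw[bin == b]), 0)
    num <- vapply(bins, function(b) {
      sel <- bin == b & ind > 0
      if (!any(sel)) -Inf else logsumexp(lw[sel])
    }, 0)
    list(lz = lz, lnum = num)
  }

  base <- comp(contact_energies(model), NULL, 0, 0L)
  # signed accumulation of Z_L and of the indicator-weighted sum
  accZ <- list(l = base$lz, s = rep(1, length(base$lz)))
  accI <- list(l = base$lnum, s = (base$lnum > -Inf) * 1)
  for (r in seq_len(nrow(linkers))) {
    u <- linkers[r, 1]; v <- linkers[r, 2]
    lg <- linker_gain(model, u, v)
    masked <- mask_linker_pairs(model, u, v)
    in_mask <- any(lg$mask[, 1] == i & lg$mask[, 2] == j)
    lc <- comp(contact_energies(masked), matrix(c(u, v), 1), lg$eps_prime,
               as.integer(in_mask))
    sp <- sprime_profile(entropy, u, v)
    ktot <- bins %/% (spec$n2 + 1L) + bins %% (spec$n2 + 1L)
    pen <- sp[ktot + 1L] / .wsme$R_cal
    dZ <- ls_add(lc$lz, 1, base$lz, -1)
    accZ <- ls_add(accZ$l, accZ$s, dZ$l + pen, dZ$s)
    dI <- ls_add(lc$lnum, (lc$lnum > -Inf) * 1, base$lnum,
                 -(base$lnum > -Inf) * 1)
    accI <- ls_add(accI$l, accI$s, dI$l + pen, dI$s)
  }
  if (any(accZ$s < 0)) stop("negative ensemble bin")
  out <- rep(0, length(bins))
  pos <- accI$s != 0
  out[pos] <- accI$s[pos] * exp(accI$l[pos] - accZ$l[pos])
  out
}
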