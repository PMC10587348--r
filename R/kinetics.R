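# Folding kinetics: 1D master equation over the order parameter, stability,
# parameter fitting, and the named multi-state scheme with its population
# dynamics.

#' Macroscopic folding rate from a 1D landscape
#'
#' Microscopic hopping rates between adjacent bins,
#' `k = A exp(-(F(n +/- 1/N) - F(n)) / 2 k_B T)`, assembled into the
#' tridiagonal master-equation generator; the macroscopic rate is the
#' eigenvalue of smallest nonzero magnitude (computed on the detailed-balance
#' symmetrized matrix for stability).
#'
#' @param ls 1D `wsme_landscape` with finite F everywhere.
#' @param A Attempt frequency, 1/s (default 1e7).
#' @return List with `k_f` (1/s), `rate_matrix` (generator; columns sum to
#'   0), `eigenvalues` (ascending magnitudes), `stationary` (detailed-balance
#'   stationary distribution).
#' @export
folding_rate_1d <- function(ls, A = 1e7) {
  stopifnot(is_1d(ls))
  f <- ls$F[, 1]
  if (any(!is.finite(f))) stop("landscape has non-finite bins")
  RT <- .wsme$R_kcal * ls$temperature
  m <- length(f)
  up <- A * exp(-(f[-1] - f[-m]) / (2 * RT))   # k_{i -> i+1}
  dn <- A * exp(-(f[-m] - f[-1]) / (2 * RT))   # k_{i+1 -> i}
  M <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    M[i + 1, i] <- M[i + 1, i] + up[i]
    M[i, i] <- M[i, i] - up[i]
    M[i, i + 1] <- M[i, i + 1] + dn[i]
    M[i + 1, i + 1] <- M[i + 1, i + 1] - dn[i]
  }
  pi_st <- exp(-(f - min(f)) / RT)
  pi_st <- pi_st / sum(pi_st)
  s <- sqrt(pi_st)
  Msym <- diag(1 / s) %*% M %*% diag(s)
  ev <- eigen((Msym + t(Msym)) / 2, symmetric = TRUE, only.values = TRUE)$values
  mags <- sort(abs(ev))
  k_f <- mags[2] # smallest nonzero |eigenvalue| (mags[1] ~ 0 is stationary)
  list(k_f = k_f, rate_matrix = M, eigenvalues = mags, stationary = pi_st)
}

#' Two-state stability from a 1D landscape
#'
#' `dG_NU = F_min(native basin) - F_min(unfolded basin)`, taking the
#' lowest-n basin as unfolded and the highest-n basin as native. Requires at
#' least two basins.
#'
#' @param ls 1D `wsme_landscape`.
#' @return Stability in kcal/mol (negative favours the native state).
#' @export
stability <- function(ls) {
  ann <- find_basins_and_saddles(ls)
  if (nrow(ann$basins) < 2)
    stop("two-state stability undefined: landscape has ",
         nrow(ann$basins), " basin(s)")
  b <- ann$basins[order(ann$basins$i1), ]
  b$F[nrow(b)] - b$F[1]
}

#' Fit the energy scale and ring-entropy scale against targets
#'
#' For each value of the ring-entropy scale `h_S'` on the grid, finds the
#' contact-energy scale epsilon minimizing the loss
#' `((dG - dG_exp)/k_B T)^2 + ln(k_f/k_f_exp)^2` (the rate term is omitted
#' when no rate target is given). Returns the full per-grid-point table and
#' the minimum-loss pair; the caller chooses among near-minimal pairs.
#'
#' @param build Function `(eps, h)` returning a 1D `wsme_landscape`.
#' @param dG_target Target stability, kcal/mol.
#' @param kf_target Optional target folding rate, 1/s.
#' @param temperature K (for the k_B T scaling of the loss).
#' @param h_grid Grid of `h_S'` values (default 0.5..2.0 by 0.1).
#' @param eps_interval Bracketing interval for epsilon.
#' @param A Attempt frequency for the rate.
#' @param tol Scalar-minimization tolerance.
#' @return List with `table` (data frame h, eps, loss), `best` (row of the
#'   minimal loss).
#' @export
fit_parameters <- function(build, dG_target, kf_target = NULL, temperature,
                           h_grid = seq(0.5, 2.0, by = 0.1),
                           eps_interval = c(0.05, 10), A = 1e7, tol = 1e-4) {
  RT <- .wsme$R_kcal * temperature
  loss_fn <- function(eps, h) {
    ls <- build(eps, h)
    ann <- try(stability(ls), silent = TRUE)
    if (inherits(ann, "try-error")) return(1e6)
    loss <- ((ann - dG_target) / RT)^2
    if (!is.null(kf_target)) {
      kf <- folding_rate_1d(ls, A = A)$k_f
      loss <- loss + log(kf / kf_target)^2
    }
    loss
  }
  rows <- lapply(h_grid, function(h) {
    # coarse scan to check the bracket before refining
    grid <- exp(seq(log(eps_interval[1]), log(eps_interval[2]), length.out = 8))
    coarse <- vapply(grid, loss_fn, 0, h = h)
    if (which.min(coarse) %in% c(1L, length(coarse)))
      stop("loss not bracketed for h = ", h, "; coarse scan: ",
           paste(sprintf("eps=%.3g loss=%.3g", grid, coarse), collapse = ", "))
    opt <- optimize(loss_fn, interval = eps_interval, h = h, tol = tol)
    data.frame(h = h, eps = opt$minimum, loss = opt$objective)
  })
  table <- do.call(rbind, rows)
  list(table = table, best = table[which.min(table$loss), ])
}

#' Prefactor with internal friction
#'
#' `A(n) = A0 / (1 + 5 Q(n))` with `Q(n) = n^2`: the attempt frequency for
#' crossing a transition state at pathway order parameter n.
#'
#' @param n Order parameter in [0, 1].
#' @param A0 Base prefactor, 1/s.
#' @return Prefactor, 1/s.
#' @export
scheme_prefactor <- function(n, A0 = 1e7) {
  A0 / (1 + 5 * n^2)
}

#' Microscopic rates of a named multi-state scheme
#'
#' For each listed transition X -> Y, `k_XY = A(n_saddle) exp(-dF/k_B T)`
#' with `dF = F(saddle) - F_min(basin X)`; the saddle between X and Y comes
#' from the landscape annotations and `n_saddle` is the saddle bin's pathway
#' order parameter.
#'
#' @param ls 2D `wsme_landscape`.
#' @param states Named list of basin bins, e.g.
#'   `list(U = c(1, 1), I1 = ..., I2 = ..., N = ...)`.
#' @param transitions List of length-2 character vectors c(from, to); both
#'   directions of each listed pair are produced.
#' @param A0 Base prefactor, 1/s.
#' @param annotations Optional precomputed [find_basins_and_saddles()]
#'   output.
#' @return Object of class `wsme_scheme`: data frame of rates plus metadata.
#' @export
scheme_rates <- function(ls, states, transitions, A0 = 1e7,
                         annotations = NULL) {
  RT <- .wsme$R_kcal * ls$temperature
  rows <- list()
  for (tr in transitions) {
    from <- tr[1]; to <- tr[2]
    bf <- states[[from]]; bt <- states[[to]]
    if (is.null(bf) || is.null(bt)) stop("unknown state in transition ",
                                         from, "->", to)
    barrier <- minimax_barrier(ls, bf, bt)
    if (!is.finite(barrier))
      stop("no saddle between states ", from, " and ", to)
    # locate a saddle bin achieving the minimax value for n_pathway
    n_s <- saddle_n_pathway(ls, bf, bt, barrier)
    for (dir in list(c(from, to), c(to, from))) {
      src <- states[[dir[1]]]
      dF <- barrier - ls$F[src[1], src[2]]
      rows[[length(rows) + 1]] <- data.frame(
        from = dir[1], to = dir[2], barrier = dF, n_saddle = n_s,
        prefactor = scheme_prefactor(n_s, A0),
        rate = scheme_prefactor(n_s, A0) * exp(-dF / RT))
    }
  }
  structure(list(rates = do.call(rbind, rows), states = states,
                 temperature = ls$temperature, A0 = A0),
            class = "wsme_scheme")
}

# pathway order parameter of the highest cell on the best minimax path
saddle_n_pathway <- function(ls, from, to, barrier) {
  f <- ls$F
  # cells reachable from both ends through F <= barrier; the saddle is a
  # bottleneck cell with F equal to the barrier
  reach <- function(start) {
    n1 <- nrow(f); n2 <- ncol(f)
    ok <- matrix(FALSE, n1, n2)
    ok[start[1], start[2]] <- TRUE
    repeat {
      grew <- FALSE
      idx <- which(ok, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          ii <- i + d[1]; jj <- j + d[2]
          if (ii < 1 || ii > nrow(f) || jj < 1 || jj > ncol(f)) next
          if (!ok[ii, jj] && f[ii, jj] <= barrier + 1e-12) {
            ok[ii, jj] <- TRUE; grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    ok
  }
  both <- reach(from) & reach(to)
  cand <- which(both & abs(f - barrier) <= 1e-9, arr.ind = TRUE)
  if (nrow(cand) == 0) cand <- which(both, arr.ind = TRUE)
  i <- cand[1, 1]; j <- cand[1, 2]
  ((i - 1) + (j - 1)) / ls$spec$n
}

#' Generator matrix of the four-state conservative scheme
#'
#' States (U, I1, I2, N) with transitions U<->I1, I1<->I2, I1<->N, I2<->N;
#' returns the generator G with dC/dt = G C (columns sum to zero).
#'
#' @param scheme A `wsme_scheme` containing the listed transitions.
#' @return 4 x 4 generator matrix with dimnames.
#' @export
scheme_matrix_conservative <- function(scheme) {
  k <- function(a, b) {
    r <- scheme$rates
    hit <- r$rate[r$from == a & r$to == b]
    if (length(hit) == 0) 0 else hit[1]
  }
  st <- c("U", "I1", "I2", "N")
  G <- matrix(0, 4, 4, dimnames = list(st, st))
  pairs <- list(c("U", "I1"), c("I1", "I2"), c("I1", "N"), c("I2", "N"))
  for (p in pairs) {
    G[p[2], p[1]] <- G[p[2], p[1]] + k(p[1], p[2])
    G[p[1], p[1]] <- G[p[1], p[1]] - k(p[1], p[2])
    G[p[1], p[2]] <- G[p[1], p[2]] + k(p[2], p[1])
    G[p[2], p[2]] <- G[p[2], p[2]] - k(p[2], p[1])
  }
  G
}

#' Generator matrix of the five-state irreversible scheme
#'
#' Under native conditions unfolding of N is negligible; the native state is
#' split by the pathway of arrival (N_p1 via I2, N_p2 directly from I1) and
#' the N -> I transitions are dropped. dC/dt = G C over
#' (U, I1, I2, N_p1, N_p2).
#'
#' @param scheme A `wsme_scheme`.
#' @return 5 x 5 generator matrix with dimnames.
#' @export
scheme_matrix_irreversible <- function(scheme) {
  k <- function(a, b) {
    r <- scheme$rates
    hit <- r$rate[r$from == a & r$to == b]
    if (length(hit) == 0) 0 else hit[1]
  }
  st <- c("U", "I1", "I2", "Np1", "Np2")
  G <- matrix(0, 5, 5, dimnames = list(st, st))
  kUI1 <- k("U", "I1"); kI1U <- k("I1", "U")
  kI1I2 <- k("I1", "I2"); kI2I1 <- k("I2", "I1")
  kI1N <- k("I1", "N"); kI2N <- k("I2", "N")
  G["U", "U"] <- -kUI1; G["U", "I1"] <- kI1U
  G["I1", "U"] <- kUI1
  G["I1", "I1"] <- -(kI1U + kI1I2 + kI1N)
  G["I1", "I2"] <- kI2I1
  G["I2", "I1"] <- kI1I2
  G["I2", "I2"] <- -(kI2I1 + kI2N)
  G["Np1", "I2"] <- kI2N
  G["Np2", "I1"] <- kI1N
  G
}

#' Solve a kinetic scheme analytically
#'
#' Populations C(t) from the eigendecomposition of the generator; falls back
#' to fourth-order Runge-Kutta integration when the generator is defective
#' (logged). Also reports the t -> Inf limit (for irreversible schemes, the
#' terminal pathway split).
#'
#' @param G Generator matrix (dC/dt = G C).
#' @param t_grid Times, s.
#' @param C0 Initial populations (default all mass in state 1).
#' @return List with `populations` (time x states data frame) and
#'   `terminal` (named limit vector).
#' @export
solve_scheme <- function(G, t_grid, C0 = NULL) {
  m <- nrow(G)
  if (is.null(C0)) C0 <- c(1, rep(0, m - 1))
  dec <- eigen(G)
  sv <- svd(dec$vectors)$d
  ok <- all(is.finite(sv)) && min(sv) / max(sv) > 1e-12
  if (ok) {
    coef <- solve(dec$vectors, C0)
    pop <- t(vapply(t_grid, function(t)
      Re(dec$vectors %*% (coef * exp(dec$values * t)))[, 1], numeric(m)))
    lim <- Mod(dec$values) < 1e-9 * max(Mod(dec$values), 1e-12)
    terminal <- Re(dec$vectors[, lim, drop = FALSE] %*%
                     coef[lim])[, 1]
  } else {
    message("defective generator: integrating numerically")
    pop <- matrix(NA_real_, length(t_grid), m)
    h_steps <- 2000L
    y <- C0
    tprev <- 0
    for (r in seq_along(t_grid)) {
      tt <- t_grid[r]
      h <- (tt - tprev) / h_steps
      if (h > 0) for (s in seq_len(h_steps)) {
        k1 <- G %*% y
        k2 <- G %*% (y + h / 2 * k1)
        k3 <- G %*% (y + h / 2 * k2)
        k4 <- G %*% (y + h * k3)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      pop[r, ] <- y
      tprev <- tt
    }
    terminal <- pop[nrow(pop), ]
  }
  colnames(pop) <- rownames(G)
  names(terminal) <- rownames(G)
  list(populations = data.frame(t = t_grid, pop, check.names = FALSE),
       terminal = terminal)
}

#' Time evolution of domain-specific structure formation
#'
#' `p_domain(t) = sum_X Phi_domain(n_X) C_X(t)`: populations weighted by the
#' per-state domain-averaged Phi values.
#'
#' @param populations Data frame from [solve_scheme()] (`t` plus one column
#'   per state).
#' @param phi_states Named vector of domain-averaged Phi values per state;
#'   names must match population columns (pathway-split native states may be
#'   given a single "N" value applied to all `N*` columns).
#' @return Data frame with `t` and `p`.
#' @export
domain_time_evolution <- function(populations, phi_states) {
  cols <- setdiff(colnames(populations), "t")
  phi <- vapply(cols, function(cn) {
    if (cn %in% names(phi_states)) phi_states[[cn]]
    else if (grepl("^N", cn) && "N" %in% names(phi_states)) phi_states[["N"]]
    else stop("no Phi value for state ", cn)
  }, 0)
  data.frame(t = populations$t,
             p = as.matrix(populations[, cols, drop = FALSE]) %*% phi)
}
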