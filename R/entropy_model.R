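# Conformational entropy costs: the per-residue cost of fixing a residue in
# its native conformation, and the Gaussian-chain ring-closure penalty paid by
# a virtual linker.

#' Build an entropy model
#'
#' @param n Residue count.
#' @param S Per-residue entropy cost in cal/(mol K); scalar (recycled) or
#'   length-n vector; every entry must be negative. Defaults to the linker
#'   ensemble value -3.5.
#' @param h_sprime Dimensionless scaling of the ring-closure entropy (fit per
#'   protein over 0.5..2.0; default 1).
#' @param a Calpha-Calpha virtual bond length, Angstrom.
#' @param persistence Persistence length, Angstrom.
#' @param r N x N matrix of native Calpha-Calpha distances (Angstrom), used as
#'   the end-to-end distance of the loop closed by a linker; may be NULL when
#'   no linkers are used.
#' @return Object of class `wsme_entropy_model`.
#' @export
entropy_model <- function(n, S = -3.5, h_sprime = 1,
                          a = 3.8, persistence = 20, r = NULL) {
  S <- rep_len(S, n)
  if (any(S >= 0)) stop("entropy costs S_i must be negative")
  if (a <= 0 || persistence <= 0) stop("a and persistence must be positive")
  if (!is.null(r)) {
    stopifnot(is.matrix(r), nrow(r) == n, ncol(r) == n, all(r >= 0))
  }
  structure(list(n = n, S = S, h_sprime = h_sprime, a = a,
                 persistence = persistence, r = r),
            class = "wsme_entropy_model")
}

#' @export
print.wsme_entropy_model <- function(x, ...) {
  cat("<wsme_entropy_model> N=", x$n, " S=[",
      format(min(x$S)), ",", format(max(x$S)), "] h=", x$h_sprime,
      "\n", sep = "")
  invisible(x)
}

#' Ring-closure entropy of a Gaussian loop
#'
#' Entropy cost of closing a loop of `L` virtual bonds whose ends sit `r`
#' apart: \eqn{s'(L) = -(3/2) k_B [\ln L + (r^2 - a^2) / (2 A a L)]} with
#' \eqn{k_B} the gas constant 1.987 cal/(mol K), `a` the Calpha step (3.8 A)
#' and `A` the persistence length (20 A). `L < 1` is clamped to 1 (one virtual
#' bond is the physical minimum loop).
#'
#' @param L Loop length in residues (vectorized; clamped to >= 1).
#' @param r End-to-end distance, Angstrom.
#' @param a Step length, Angstrom.
#' @param persistence Persistence length, Angstrom.
#' @return Entropy in cal/(mol K) (<= 0 for r >= a at L = 1).
#' @export
ring_closure_entropy <- function(L, r, a = 3.8, persistence = 20) {
  L <- pmax(L, 1)
  -1.5 * .wsme$R_cal * (log(L) + (r^2 - a^2) / (2 * persistence * a * L))
}

#' Linker entropy penalty at a given order parameter
#'
#' The expected ring-closure cost of the loop spanned by a linker (u, v) when
#' `nN` of the N residues are native, averaged over the hypergeometric number
#' of native residues falling inside the span: with `N' = v - u + 1`,
#' \deqn{S'^{(u,v)}(n) = h_{S'} \sum_{i=0}^{nN}
#'   \frac{\binom{N'}{i}\binom{N-N'}{nN-i}}{\binom{N}{nN}} s'(N'-i),}
#' impossible terms contributing 0 and the `s'` argument clamped to >= 1.
#'
#' @param entropy A `wsme_entropy_model` with the `r` distance matrix set.
#' @param u,v Linker endpoints, `1 <= u < v <= N`.
#' @param n Order parameter on the grid {0, 1/N, ..., 1} (equivalently pass
#'   the integer native count via `k`).
#' @param k Integer native count nN; overrides `n` when given.
#' @return Entropy penalty in cal/(mol K).
#' @export
linker_entropy_penalty <- function(entropy, u, v, n = NULL, k = NULL) {
  N <- entropy$n
  stopifnot(u >= 1, v <= N, u < v)
  if (is.null(k)) {
    k <- n * N
    if (abs(k - round(k)) > 1e-9)
      stop("n must lie on the grid {0, 1/N, ..., 1}; nN = ", k,
           " is not an integer")
    k <- as.integer(round(k))
  }
  if (is.null(entropy$r)) stop("entropy model has no distance matrix r")
  Np <- v - u + 1L
  i <- 0:k
  wts <- dhyper(i, Np, N - Np, k)
  if (abs(sum(wts) - 1) > 1e-12)
    stop("hypergeometric weights do not sum to 1")
  s <- ring_closure_entropy(Np - i, r = entropy$r[u, v],
                            a = entropy$a, persistence = entropy$persistence)
  entropy$h_sprime * sum(wts * s)
}

# S'(n) for every native count k = 0..N at once (used by ensemble builders)
sprime_profile <- function(entropy, u, v) {
  vapply(0:entropy$n, function(k)
    linker_entropy_penalty(entropy, u, v, k = k), 0)
}
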