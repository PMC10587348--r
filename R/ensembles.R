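# Linker-ensemble partition functions. The full model is an ensemble over
# partition functions with a virtual linker at each eligible contact,
#   Z_L(n) = Z(n) + sum_{(u,v)} (Z^{(u,v)}(n) - Z(n)) exp(S'^{(u,v)}(n)/k_B),
# and the disulfide-intact variant nests the same combination inside a sum
# over mandatory disulfide linkers. Differences of partition functions can be
# negative term by term, so the combination runs in signed log arithmetic and
# a negative resulting bin is a hard error (model misconfiguration), never
# silently clamped.

# total-native-count index (k1 + k2) for every bin of a spec, as a matrix
bin_total_counts <- function(spec) {
  outer(0:spec$n1, 0:spec$n2, "+")
}

#' Combine a base table and linked tables into the linker ensemble
#'
#' The ensemble combination applied bin by bin:
#' `Z_L = Z + sum_l (Z_l - Z) * exp(S'_l(n)/k_B)` where `S'_l(n)` is the
#' linker entropy penalty evaluated at the bin's total native count.
#'
#' @param base `wsme_partition_table` without linker.
#' @param linked List of `wsme_partition_table`s, one per linker.
#' @param penalties List (same length) of numeric vectors of `S'(n)` in
#'   cal/(mol K), indexed by total native count 0..N of the axes.
#' @return A `wsme_partition_table`; errors on any negative resulting bin.
#' @export
combine_linker_ensemble <- function(base, linked, penalties) {
  stopifnot(length(linked) == length(penalties))
  ktot <- bin_total_counts(base$spec)
  acc_l <- as.vector(base$lm)
  acc_s <- as.vector(base$sg)
  for (i in seq_along(linked)) {
    tab <- linked[[i]]
    if (!same_spec(tab$spec, base$spec) ||
        tab$temperature != base$temperature)
      stop("linked table ", i, " has a different axis spec or temperature")
    pen <- penalties[[i]][as.vector(ktot) + 1L] / .wsme$R_cal
    d <- ls_add(as.vector(tab$lm), as.vector(tab$sg),
                as.vector(base$lm), -as.vector(base$sg))
    acc <- ls_add(acc_l, acc_s, d$l + pen, d$s)
    acc_l <- acc$l; acc_s <- acc$s
  }
  if (any(acc_s < 0))
    stop("linker ensemble produced a negative bin: ",
         "model misconfiguration (check energies and entropy penalties)")
  lm <- matrix(acc_l, nrow(base$lm), ncol(base$lm))
  sg <- matrix(acc_s, nrow(base$lm), ncol(base$lm))
  new_partition_table(lm, sg, base$spec, base$temperature)
}

#' Linker-ensemble (WSME-L) partition function
#'
#' Builds the base and per-linker restricted partition functions and combines
#' them with the ring-closure entropy penalties. With `eta`, the same
#' combination is evaluated for the perturbed Hamiltonians (the
#' pseudo-mutation ensemble used by the theoretical Phi-value analysis).
#'
#' @inheritParams restricted_partition
#' @param linkers Two-column matrix of linker pairs; default
#'   [linker_set()] of the model.
#' @param eta Optional symmetric perturbation matrix, kcal/mol.
#' @return A `wsme_partition_table`.
#' @export
wsme_l_partition <- function(model, entropy, temperature, spec,
                             linkers = linker_set(model), eta = NULL,
                             method = c("tm", "enumerate")) {
  method <- match.arg(method)
  linkers <- matrix(as.integer(linkers), ncol = 2)
  E <- contact_energies(model)
  if (!is.null(eta)) E <- E + eta
  base <- run_partition(E, entropy, temperature, spec, method = method)
  if (nrow(linkers) == 0L) return(base)
  linked <- vector("list", nrow(linkers))
  pens <- vector("list", nrow(linkers))
  for (i in seq_len(nrow(linkers))) {
    u <- linkers[i, 1]; v <- linkers[i, 2]
    linked[[i]] <- linked_partition(model, entropy, temperature, spec,
                                    u, v, eta = eta, method = method)
    pens[[i]] <- sprime_profile(entropy, u, v)
  }
  combine_linker_ensemble(base, linked, pens)
}

#' Disulfide-intact ensemble partition function
#'
#' For each mandatory disulfide linker (u2, v2), combines its single-linker
#' partition function with the double-linker partitions over the virtual
#' linkers (u1, v1) using the virtual linkers' entropy penalties, then sums
#' the per-disulfide ensembles. The model must already have the contact
#' weights around each disulfide pair zeroed
#' (see [zero_disulfide_neighborhood()]); the covalent bond is carried by the
#' mandatory linker, which pays no entropy penalty.
#'
#' @inheritParams wsme_l_partition
#' @param ss_pairs Two-column matrix of disulfide pairs (>= 1 row).
#' @param virtual_linkers Two-column matrix of virtual linker pairs.
#' @return A `wsme_partition_table`.
#' @export
ss_intact_partition <- function(model, entropy, temperature, spec,
                                ss_pairs = model$ss_pairs,
                                virtual_linkers = linker_set(model),
                                eta = NULL,
                                method = c("tm", "enumerate")) {
  method <- match.arg(method)
  ss_pairs <- matrix(as.integer(ss_pairs), ncol = 2)
  if (nrow(ss_pairs) < 1L) stop("at least one disulfide pair required")
  virtual_linkers <- matrix(as.integer(virtual_linkers), ncol = 2)
  for (k in seq_len(nrow(ss_pairs))) {
    nb <- neighborhood5(ss_pairs[k, 1], ss_pairs[k, 2], model$n)
    if (any(model$weights[nb] != 0))
      warning("contact weights around disulfide pair (", ss_pairs[k, 1], ",",
              ss_pairs[k, 2], ") are nonzero; expected a model prepared ",
              "with zero_disulfide_neighborhood()")
  }
  total <- NULL
  for (k in seq_len(nrow(ss_pairs))) {
    s <- ss_pairs[k, ]
    zs <- linked_partition(model, entropy, temperature, spec, s[1], s[2],
                           eta = eta, method = method)
    linked <- list(); pens <- list()
    for (i in seq_len(nrow(virtual_linkers))) {
      l <- virtual_linkers[i, ]
      linked[[i]] <- double_linked_partition(model, entropy, temperature,
                                             spec, l, s, eta = eta,
                                             method = method)
      pens[[i]] <- sprime_profile(entropy, l[1], l[2])
    }
    zk <- if (length(linked)) combine_linker_ensemble(zs, linked, pens)
          else zs
    if (is.null(total)) total <- zk
    else {
      acc <- ls_add(as.vector(total$lm), as.vector(total$sg),
                    as.vector(zk$lm), as.vector(zk$sg))
      total$lm <- matrix(acc$l, nrow(total$lm), ncol(total$lm))
      total$sg <- matrix(acc$s, nrow(total$lm), ncol(total$lm))
    }
  }
  total
}
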