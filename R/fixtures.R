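# Synthetic fixtures: toy chains with designed topology, random-but-seeded
# contact energies, and fixture PDB files, so that every other module can be
# exercised without external data.
#
# The "discontinuous" topology is the headline scenario: attractive contacts
# bridge an N-terminal and a C-terminal block across an inert middle block,
# so the terminal blocks can only fold together early if a linker shortcut
# carries their contacts.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

new_chain_from_ca <- function(ca) {
  n <- nrow(ca)
  atoms <- lapply(seq_len(n), function(i) {
    m <- ca[i, , drop = FALSE]
    rownames(m) <- "CA"
    m
  })
  structure(list(n = n, ca = ca, atoms = atoms,
                 resnames = rep("ALA", n),
                 author_numbering = data.frame(index = seq_len(n),
                                               chain = "A",
                                               resseq = as.character(seq_len(n)),
                                               icode = " ")),
            class = "wsme_chain")
}

#' Render a chain as PDB-format text
#'
#' Standard ATOM records, single chain A, alanine residues, occupancy 1.00
#' and B-factor 0.00; Calpha atoms only.
#'
#' @param chain A `wsme_chain`.
#' @return Character vector of PDB lines (including END).
#' @export
fixture_pdb <- function(chain) {
  lines <- vapply(seq_len(chain$n), function(i) {
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, i, chain$ca[i, 1], chain$ca[i, 2], chain$ca[i, 3], 1, 0)
  }, "")
  c(lines, "END")
}

toy_geometry <- function(n, topology) {
  a <- 3.8
  if (topology == "hairpin") {
    if (n < 6) stop("hairpin needs at least 6 residues")
    m <- ceiling(n / 2)
    ca <- matrix(0, n, 3)
    for (i in 1:m) ca[i, ] <- c(0, (i - 1) * a, 0)
    for (j in (m + 1):n) ca[j, ] <- c(4.8, (n - j) * a, 0)
    pairs <- do.call(rbind, lapply(1:m, function(i) c(i, n + 1 - i)))
    pairs <- pairs[pairs[, 2] - pairs[, 1] > 2 & pairs[, 2] <= n, ,
                   drop = FALSE]
    list(ca = ca, pairs = pairs, blocks = NULL)
  } else if (topology == "discontinuous") {
    b <- max(3L, n %/% 3L)
    if (n < 3 * b - 1) stop("discontinuous topology infeasible for N = ", n)
    mid <- (b + 1):(n - b)
    ca <- matrix(0, n, 3)
    for (i in 1:b) ca[i, ] <- c(0, (i - 1) * 4.0, 0)
    for (k in seq_along(mid)) ca[mid[k], ] <- c(25, (k - 1) * 4.0, 0)
    for (k in 1:b) ca[n - b + k, ] <- c(4.8, (k - 1) * 4.0, 0)
    pairs <- do.call(rbind, lapply(1:b, function(i) c(i, n - b + i)))
    pairs <- pairs[pairs[, 2] - pairs[, 1] > 2, , drop = FALSE]
    list(ca = ca, pairs = pairs,
         blocks = list(block1 = 1:b, mid = mid, block3 = (n - b + 1):n))
  } else if (topology == "compact") {
    # seeded self-avoiding walk on a cubic lattice (step = Calpha bond)
    dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
    ca <- NULL; pairs <- NULL
    for (attempt in 1:500) {
      pos <- matrix(0, n, 3)
      seen <- new.env(hash = TRUE)
      assign("0/0/0", TRUE, envir = seen)
      dead <- FALSE
      for (i in 2:n) {
        ord <- sample.int(6)
        placed <- FALSE
        for (d in ord) {
          cand <- pos[i - 1, ] + dirs[d, ]
          key <- paste(cand, collapse = "/")
          if (!exists(key, envir = seen, inherits = FALSE)) {
            pos[i, ] <- cand
            assign(key, TRUE, envir = seen)
            placed <- TRUE
            break
          }
        }
        if (!placed) { dead <- TRUE; break }
      }
      if (dead) next
      cand_ca <- pos * a
      dmat <- as.matrix(stats::dist(cand_ca))
      idx <- which(dmat <= 5.5 & upper.tri(dmat), arr.ind = TRUE)
      cand_pairs <- idx[idx[, 2] - idx[, 1] > 2, , drop = FALSE]
      if (nrow(cand_pairs) >= 2) { ca <- cand_ca; pairs <- cand_pairs; break }
    }
    if (is.null(ca))
      stop("could not place a compact self-avoiding walk for N = ", n)
    list(ca = ca, pairs = pairs, blocks = NULL)
  } else stop("unknown topology: ", topology)
}

#' Generate a toy chain, energy model and entropy model
#'
#' Deterministic for a given seed. Topologies: `"hairpin"` (two paired
#' strands), `"discontinuous"` (terminal blocks in contact across an inert
#' middle block), `"compact"` (seeded self-avoiding lattice walk). Designed
#' contact pairs receive raw energies drawn uniformly from `energy_range`
#' (kcal/mol) and are normalized into weights; Calpha coordinates are laid
#' out so that geometric distances agree with the designed contacts.
#'
#' @param n Residue count (<= 30 for oracle-compatible fixtures).
#' @param topology One of `"hairpin"`, `"discontinuous"`, `"compact"`.
#' @param seed Integer seed.
#' @param energy_range Range of raw contact energies, kcal/mol (negative).
#' @param S Per-residue entropy cost, cal/(mol K).
#' @param h_sprime Ring-entropy scale.
#' @param eps Contact-energy scale epsilon.
#' @return List with `chain`, `model` (`wsme_energy_model`), `entropy`
#'   (`wsme_entropy_model` with the Calpha distance matrix), `spec` (1D),
#'   `designed_pairs`, `blocks` (for the discontinuous topology), `pdb`
#'   (fixture PDB text), and the generation parameters.
#' @export
make_toy_model <- function(n, topology = c("hairpin", "discontinuous",
                                           "compact"),
                           seed = 1, energy_range = c(-3, -0.5),
                           S = -3.5, h_sprime = 1, eps = 1) {
  topology <- match.arg(topology)
  if (n > 30) stop("toy fixtures are capped at N = 30 (oracle compatibility)")
  geo <- with_seed(seed, toy_geometry(n, topology))
  pairs <- geo$pairs
  if (nrow(pairs) == 0) stop("topology produced no designed contacts")
  raw <- matrix(0, n, n)
  en <- with_seed(seed + 1L,
                  runif(nrow(pairs), min(energy_range), max(energy_range)))
  for (r in seq_len(nrow(pairs))) {
    raw[pairs[r, 1], pairs[r, 2]] <- en[r]
    raw[pairs[r, 2], pairs[r, 1]] <- en[r]
  }
  model <- weighted_energy_model(raw)
  model$eps <- eps
  chain <- new_chain_from_ca(geo$ca)
  entropy <- entropy_model(n, S = S, h_sprime = h_sprime,
                           r = ca_distances(chain))
  list(chain = chain, model = model, entropy = entropy,
       spec = order_spec(n), designed_pairs = pairs, blocks = geo$blocks,
       pdb = fixture_pdb(chain),
       params = list(n = n, topology = topology, seed = seed,
                     energy_range = energy_range, S = S,
                     h_sprime = h_sprime, eps = eps))
}

#' Disulfide fixture: oxidative and disulfide-intact variants
#'
#' Builds a toy model and returns both the oxidative variant (disulfide
#' raw-energy bonus applied) and the disulfide-intact variant (contact
#' weights around each pair zeroed) of the same base model.
#'
#' @inheritParams make_toy_model
#' @param ss_pairs Two-column matrix of disulfide pairs (`|i-j| > 2`);
#'   default: the designed contact pair with the largest sequence separation.
#' @param bonus Disulfide raw-energy bonus, kcal/mol.
#' @return List with `base` (the [make_toy_model()] output), `ss_pairs`,
#'   `model_ss` (bonus applied) and `model_ss_intact` (neighbourhood zeroed).
#' @export
make_disulfide_fixture <- function(n = 14, topology = "hairpin", seed = 1,
                                   ss_pairs = NULL, bonus = -40, ...) {
  base <- make_toy_model(n, topology, seed, ...)
  if (is.null(ss_pairs)) {
    sep <- base$designed_pairs[, 2] - base$designed_pairs[, 1]
    ss_pairs <- base$designed_pairs[which.max(sep), , drop = FALSE]
  }
  ss_pairs <- matrix(as.integer(ss_pairs), ncol = 2)
  if (nrow(ss_pairs) == 0) stop("at least one disulfide pair required")
  if (any(abs(ss_pairs[, 1] - ss_pairs[, 2]) <= 2))
    stop("disulfide pair too local (|i-j| <= 2)")
  model_ss <- apply_disulfide_bonus(base$model, ss_pairs, bonus = bonus)
  model_int <- base$model
  model_int$ss_pairs <- ss_pairs
  model_int <- zero_disulfide_neighborhood(model_int, ss_pairs)
  list(base = base, ss_pairs = ss_pairs, model_ss = model_ss,
       model_ss_intact = model_int)
}
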