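# Native contact maps and contact energies.
#
# An energy model holds the dimensionless symmetric weight matrix e_{i,j}
# (zero on and near the diagonal, |e| <= 1 for non-disulfide pairs after
# normalization), the global scale epsilon so that eps_{i,j} = epsilon * e_{i,j}
# in kcal/mol, the raw pairwise energies when they were supplied, and the
# disulfide pair list.

#' Parse a protein chain from PDB-format text
#'
#' Reads ATOM/HETATM records of the first chain (or a selected chain ID),
#' resolves altlocs (first wins), uses model 1 of multi-model files (with a
#' message), drops hydrogens, and renumbers residues 1..N in file order. Every
#' residue must have a Calpha atom.
#'
#' @param pdb_text Character scalar or vector of lines in PDB format.
#' @param chain_id Optional one-letter chain identifier; default: first chain.
#' @return An object of class `wsme_chain`: list with `n` (residue count),
#'   `ca` (N x 3 Calpha coordinates, Angstrom), `atoms` (list of per-residue
#'   heavy-atom coordinate matrices, including the Calpha), `resnames`,
#'   `author_numbering` (data frame mapping new 1..N indices to the author
#'   chain/resseq/icode).
#' @export
read_structure <- function(pdb_text, chain_id = NULL) {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE))
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text
  rec <- substr(lines, 1, 6)
  if (any(grepl("^MODEL", rec))) {
    first_model <- which(grepl("^MODEL", rec))[1]
    endmdl <- which(grepl("^ENDMDL", rec))
    if (length(endmdl) > 0) {
      message("multi-model PDB input: using model 1 only")
      lines <- lines[seq_len(endmdl[1] - 1L)]
      rec <- substr(lines, 1, 6)
    }
  }
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no ATOM/HETATM records found")
  atom_name <- trimws(substr(lines, 13, 16))
  altloc    <- substr(lines, 17, 17)
  resname   <- trimws(substr(lines, 18, 20))
  chain     <- substr(lines, 22, 22)
  resseq    <- trimws(substr(lines, 23, 26))
  icode     <- substr(lines, 27, 27)
  x <- as.numeric(substr(lines, 31, 38))
  y <- as.numeric(substr(lines, 39, 46))
  z <- as.numeric(substr(lines, 47, 54))
  element <- trimws(substr(lines, 77, 78))

  if (is.null(chain_id)) chain_id <- chain[1]
  sel <- chain == chain_id
  if (!any(sel)) stop("chain '", chain_id, "' not found")
  atom_name <- atom_name[sel]; altloc <- altloc[sel]; resname <- resname[sel]
  resseq <- resseq[sel]; icode <- icode[sel]
  x <- x[sel]; y <- y[sel]; z <- z[sel]; element <- element[sel]

  # heavy atoms only; infer element from the name when the column is blank
  elem <- ifelse(element == "", gsub("[0-9']", "", atom_name), element)
  heavy <- !(substr(elem, 1, 1) %in% c("H", "D"))
  # first altloc wins per (residue, atom name)
  res_key <- paste(resseq, icode, sep = "|")
  dup <- duplicated(paste(res_key, atom_name, sep = "@"))
  keep2 <- heavy & !dup
  atom_name <- atom_name[keep2]; resname <- resname[keep2]
  res_key <- res_key[keep2]; resseq <- resseq[keep2]; icode <- icode[keep2]
  x <- x[keep2]; y <- y[keep2]; z <- z[keep2]

  keys <- unique(res_key)
  n <- length(keys)
  if (n < 3L) stop("chain must contain at least 3 residues (found ", n, ")")
  ca <- matrix(NA_real_, n, 3)
  atoms <- vector("list", n)
  resnames <- character(n)
  for (r in seq_len(n)) {
    idx <- which(res_key == keys[r])
    resnames[r] <- resname[idx[1]]
    coords <- cbind(x[idx], y[idx], z[idx])
    rownames(coords) <- atom_name[idx]
    atoms[[r]] <- coords
    ca_i <- which(atom_name[idx] == "CA")
    if (length(ca_i) == 0L)
      stop("residue ", resname[idx[1]], " ", keys[r],
           " (renumbered ", r, ") has no CA atom")
    ca[r, ] <- coords[ca_i[1], ]
  }
  numbering <- data.frame(
    index = seq_len(n), chain = chain_id,
    resseq = vapply(strsplit(keys, "|", fixed = TRUE), `[`, "", 1),
    icode = vapply(strsplit(keys, "|", fixed = TRUE),
                   function(v) if (length(v) > 1) v[2] else " ", ""),
    stringsAsFactors = FALSE
  )
  structure(list(n = n, ca = ca, atoms = atoms, resnames = resnames,
                 author_numbering = numbering),
            class = "wsme_chain")
}

#' @export
print.wsme_chain <- function(x, ...) {
  cat("<wsme_chain> ", x$n, " residues\n", sep = "")
  invisible(x)
}

#' Calpha-Calpha distance matrix of a chain
#' @param chain A `wsme_chain`.
#' @return N x N matrix of distances in Angstrom.
#' @export
ca_distances <- function(chain) {
  as.matrix(stats::dist(chain$ca))
}

new_energy_model <- function(n, weights, eps = 1, raw = NULL,
                             normalizer = NA_real_, ss_pairs = NULL,
                             dropped = NULL) {
  dimnames(weights) <- NULL
  structure(list(n = n, weights = weights, eps = eps, raw = raw,
                 normalizer = normalizer,
                 ss_pairs = if (is.null(ss_pairs))
                   matrix(integer(), 0, 2) else ss_pairs,
                 dropped = dropped),
            class = "wsme_energy_model")
}

#' @export
print.wsme_energy_model <- function(x, ...) {
  cat("<wsme_energy_model> N=", x$n,
      " contacts=", sum(x$weights[upper.tri(x$weights)] != 0),
      " eps=", format(x$eps),
      " disulfides=", nrow(x$ss_pairs), "\n", sep = "")
  invisible(x)
}

#' Effective contact-energy matrix eps_{i,j} = epsilon * e_{i,j} (kcal/mol)
#' @param model A `wsme_energy_model`.
#' @return N x N symmetric matrix in kcal/mol.
#' @export
contact_energies <- function(model) model$eps * model$weights

# internal invariant checks shared by constructors and tests
validate_energy_model <- function(model, allow_ss_excess = TRUE) {
  w <- model$weights
  n <- model$n
  stopifnot(is.matrix(w), nrow(w) == n, ncol(w) == n)
  if (max(abs(w - t(w))) > 0) stop("weight matrix is not symmetric")
  near <- abs(row(w) - col(w)) <= 2
  if (any(w[near] != 0)) stop("nonzero weight at |i-j| <= 2")
  excess <- abs(w) > 1 + 1e-12
  if (any(excess)) {
    ok <- matrix(FALSE, n, n)
    if (allow_ss_excess && nrow(model$ss_pairs) > 0) {
      for (k in seq_len(nrow(model$ss_pairs))) {
        i <- model$ss_pairs[k, 1]; j <- model$ss_pairs[k, 2]
        ok[i, j] <- ok[j, i] <- TRUE
      }
    }
    if (any(excess & !ok)) stop("|e| > 1 on a non-disulfide pair")
  }
  if (nrow(model$ss_pairs) > 0 &&
      any(abs(model$ss_pairs[, 1] - model$ss_pairs[, 2]) <= 2))
    stop("disulfide pair with |i-j| <= 2")
  invisible(model)
}

#' Geometric native contact map (uniform weights)
#'
#' Builds the uniform-contact energy model: `e[i,j] = -1` when any heavy-atom
#' pair of residues i and j is within `cutoff` (default 4 A, boundary
#' inclusive) and `|i-j| > 2`, else 0.
#'
#' @param chain A `wsme_chain`.
#' @param cutoff Distance cutoff in Angstrom.
#' @param ca_fallback When the chain carries only Calpha coordinates, set TRUE
#'   to use Calpha-Calpha distances with your own cutoff (logged; this is a
#'   convenience, not the standard all-atom rule).
#' @return A `wsme_energy_model` with weights in {-1, 0} and `eps = 1`.
#' @export
geometric_contact_map <- function(chain, cutoff = 4.0, ca_fallback = FALSE) {
  n <- chain$n
  only_ca <- all(vapply(chain$atoms, nrow, 0L) == 1L)
  if (only_ca && !ca_fallback)
    stop("chain has Calpha atoms only; re-run with ca_fallback = TRUE ",
         "and a Calpha-appropriate cutoff")
  if (only_ca && ca_fallback)
    message("using Calpha-Calpha distances for the contact map ",
            "(all-atom rule unavailable)")
  w <- matrix(0, n, n)
  if (only_ca) {
    d <- ca_distances(chain)
    w[d <= cutoff] <- -1
  } else {
    for (i in seq_len(n - 1L)) {
      ai <- chain$atoms[[i]]
      for (j in (i + 1L):n) {
        aj <- chain$atoms[[j]]
        dmin <- sqrt(min(outer(rowSums(ai^2), rowSums(aj^2), "+") -
                           2 * tcrossprod(ai, aj)))
        if (dmin <= cutoff) { w[i, j] <- -1; w[j, i] <- -1 }
      }
    }
  }
  w[abs(row(w) - col(w)) <= 2] <- 0
  validate_energy_model(new_energy_model(n, w))
}

#' Weighted energy model from a raw pairwise energy table
#'
#' Converts raw residue-pair energies (kcal/mol, e.g. force-field derived) to
#' normalized weights: pairs with `|i-j| <= 2` are dropped first, then
#' `e[i,j] = raw[i,j] / max(|raw|)` over the retained pairs. The raw energies
#' are kept for later linker-eligibility thresholding.
#'
#' @param raw Either an N x N matrix or a data frame/matrix with columns
#'   (i, j, energy) in kcal/mol, 1-based indices.
#' @param n Residue count (required for the 3-column form; inferred from a
#'   square matrix or a `wsme_chain` passed here).
#' @return A `wsme_energy_model` with `max |e| = 1` over retained pairs.
#' @export
weighted_energy_model <- function(raw, n = NULL) {
  if (inherits(n, "wsme_chain")) n <- n$n
  if (is.matrix(raw) && nrow(raw) == ncol(raw) &&
      (is.null(n) || nrow(raw) == n)) {
    n <- nrow(raw)
    m <- raw
  } else {
    tab <- as.data.frame(raw)
    if (ncol(tab) < 3) stop("raw table must have columns i, j, energy")
    if (is.null(n)) n <- max(tab[[1]], tab[[2]])
    m <- matrix(0, n, n)
    for (r in seq_len(nrow(tab))) {
      i <- tab[[1]][r]; j <- tab[[2]][r]
      if (i < 1 || j < 1 || i > n || j > n)
        stop("raw energy index (", i, ",", j, ") outside 1..", n)
      m[i, j] <- m[i, j] + tab[[3]][r]
    }
    # entries given once are mirrored; entries given twice are averaged below
    m[lower.tri(m)][t(m)[lower.tri(m)] != 0 & m[lower.tri(m)] == 0] <- 0
    m <- ifelse(m != 0 & t(m) != 0, (m + t(m)) / 2, m + t(m))
  }
  if (max(abs(m - t(m))) > 1e-9) {
    warning("raw energy table is asymmetric; symmetrizing by averaging")
  }
  m <- (m + t(m)) / 2
  dropped <- which(m != 0 & abs(row(m) - col(m)) <= 2, arr.ind = TRUE)
  m[abs(row(m) - col(m)) <= 2] <- 0
  normalizer <- max(abs(m))
  if (normalizer == 0) stop("all retained raw energies are zero; ",
                            "normalization undefined")
  w <- m / normalizer
  validate_energy_model(new_energy_model(n, w, raw = m,
                                         normalizer = normalizer,
                                         dropped = dropped))
}

#' Add the disulfide stabilization bonus to Cys-Cys pairs
#'
#' For models built from raw energies, adds `bonus` (default -40 kcal/mol) to
#' the raw energy of each disulfide pair before conversion to weights; the
#' normalizing maximum is not recomputed, so disulfide weights may exceed 1 in
#' magnitude (a documented exception to the |e| <= 1 invariant). For
#' uniform-contact models without raw energies, a weight increment is used
#' instead (default -10, logged), mirroring the same relative change.
#'
#' @param model A `wsme_energy_model`.
#' @param pairs Two-column matrix of Cys-Cys residue pairs, `|i-j| > 2`.
#' @param bonus Raw-energy increment, kcal/mol.
#' @param weight_increment Weight-space increment used when no raw energies
#'   exist.
#' @return Updated model with `ss_pairs` recorded.
#' @export
apply_disulfide_bonus <- function(model, pairs, bonus = -40,
                                  weight_increment = -10) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) == 0L) return(model)
  if (any(pairs < 1 | pairs > model$n))
    stop("disulfide pair outside 1..", model$n)
  if (any(abs(pairs[, 1] - pairs[, 2]) <= 2))
    stop("disulfide pair with |i-j| <= 2")
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!is.null(model$raw)) {
      model$raw[i, j] <- model$raw[i, j] + bonus
      model$raw[j, i] <- model$raw[i, j]
      model$weights[i, j] <- model$raw[i, j] / model$normalizer
      model$weights[j, i] <- model$weights[i, j]
    } else if (bonus != 0) {
      message("no raw energies: applying weight increment ", weight_increment,
              " to disulfide pair (", i, ",", j, ")")
      model$weights[i, j] <- model$weights[i, j] + weight_increment
      model$weights[j, i] <- model$weights[i, j]
    }
  }
  model$ss_pairs <- unique(rbind(model$ss_pairs, pairs))
  validate_energy_model(model)
}

# the five pairs (i,j), (i+/-1,j), (i,j+/-1) clipped to 1..n, as a k x 2 matrix
neighborhood5 <- function(i, j, n) {
  p <- rbind(c(i, j), c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
  p[p[, 1] >= 1 & p[, 1] <= n & p[, 2] >= 1 & p[, 2] <= n, , drop = FALSE]
}

#' Zero contact weights around disulfide pairs (disulfide-intact preparation)
#'
#' Sets `e[i,j] = e[i+/-1,j] = e[i,j+/-1] = 0` for every disulfide pair, the
#' preparation step of the disulfide-intact model in which the covalent bond
#' is carried by a mandatory linker rather than by the contact Hamiltonian.
#' Out-of-range neighbours are skipped.
#'
#' @inheritParams apply_disulfide_bonus
#' @return Updated model (raw energies zeroed alongside the weights).
#' @export
zero_disulfide_neighborhood <- function(model, pairs = model$ss_pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (any(pairs < 1 | pairs > model$n))
    stop("disulfide pair outside 1..", model$n)
  for (k in seq_len(nrow(pairs))) {
    nb <- neighborhood5(pairs[k, 1], pairs[k, 2], model$n)
    for (r in seq_len(nrow(nb))) {
      i <- nb[r, 1]; j <- nb[r, 2]
      model$weights[i, j] <- 0; model$weights[j, i] <- 0
      if (!is.null(model$raw)) { model$raw[i, j] <- 0; model$raw[j, i] <- 0 }
    }
  }
  model$ss_pairs <- unique(rbind(model$ss_pairs, pairs))
  model
}

#' Virtual-linker eligible pairs
#'
#' Pairs whose raw energy is below `threshold` (default -0.6 kcal/mol), with
#' `u < v` and `|u-v| > 2`, sorted by (u, v). When the model has no raw
#' energies (uniform-contact inputs), all pairs with negative weight are
#' returned with a message.
#'
#' @param model A `wsme_energy_model`.
#' @param threshold Raw-energy threshold in kcal/mol (strictly less than).
#' @return Two-column integer matrix of (u, v) pairs.
#' @export
linker_set <- function(model, threshold = -0.6) {
  src <- model$raw
  if (is.null(src)) {
    message("no raw energies: linker set taken from all negative-weight pairs")
    idx <- which(model$weights < 0 & upper.tri(model$weights), arr.ind = TRUE)
  } else {
    idx <- which(src < threshold & upper.tri(src), arr.ind = TRUE)
  }
  idx <- idx[abs(idx[, 1] - idx[, 2]) > 2, , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("u", "v")
  unname(idx)
}

#' Linker contact-energy gain and double-counting mask
#'
#' The contact energy acquired when a virtual linker forms between residues u
#' and v: `eps' = epsilon * (e[u,v] + e[u+1,v] + e[u-1,v] + e[u,v+1] +
#' e[u,v-1])` (out-of-range terms 0), together with the set of pairs that must
#' be zeroed inside the linked Hamiltonian to avoid double counting.
#'
#' @param model A `wsme_energy_model`.
#' @param u,v Linker endpoints, `u < v`.
#' @return List with `eps_prime` (kcal/mol) and `mask` (k x 2 matrix of pairs).
#' @export
linker_gain <- function(model, u, v) {
  stopifnot(u >= 1, v <= model$n, u < v)
  nb <- neighborhood5(u, v, model$n)
  list(eps_prime = model$eps * sum(model$weights[nb]),
       mask = nb)
}

# model with the linker double-counting mask applied (weights only)
mask_linker_pairs <- function(model, u, v) {
  nb <- neighborhood5(u, v, model$n)
  for (r in seq_len(nrow(nb))) {
    model$weights[nb[r, 1], nb[r, 2]] <- 0
    model$weights[nb[r, 2], nb[r, 1]] <- 0
  }
  model
}

#' Zero all contacts touching a residue set
#'
#' General-purpose mask for regions that do not form stable native structure
#' (e.g. a disordered helix): every weight in the listed rows/columns is set
#' to zero.
#'
#' @param model A `wsme_energy_model`.
#' @param residues Integer vector within 1..N (may be empty).
#' @return Updated model.
#' @export
mask_region <- function(model, residues) {
  if (length(residues) == 0L) return(model)
  residues <- as.integer(residues)
  if (any(residues < 1 | residues > model$n))
    stop("residue index outside 1..", model$n)
  model$weights[residues, ] <- 0
  model$weights[, residues] <- 0
  if (!is.null(model$raw)) {
    model$raw[residues, ] <- 0
    model$raw[, residues] <- 0
  }
  model
}

#' Read a 3-column pairwise energy table (TSV)
#'
#' Format: `i<TAB>j<TAB>energy_kcal_mol`, 1-based residue indices, optional
#' header line, `#` comments.
#'
#' @param path File path.
#' @return Data frame with columns i, j, energy.
#' @export
read_energy_table <- function(path) {
  first <- readLines(path, n = 50)
  first <- first[!grepl("^\\s*#", first) & nzchar(trimws(first))]
  has_header <- length(first) > 0 &&
    is.na(suppressWarnings(as.numeric(strsplit(first[1], "\t")[[1]][1])))
  tab <- read.table(path, sep = "\t", header = has_header,
                    comment.char = "#", col.names = c("i", "j", "energy"))
  tab
}

#' Write a contact map as TSV with a JSON sidecar
#'
#' @param model A `wsme_energy_model`.
#' @param path Output TSV path (`<path>.json` records the normalization
#'   constant, dropped pairs and disulfide list).
#' @return Invisibly, the TSV path.
#' @export
write_contact_map <- function(model, path) {
  idx <- which(model$weights != 0 & upper.tri(model$weights), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   e = model$weights[idx])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    n = model$n, eps = model$eps, normalizer = model$normalizer,
    dropped_pairs = if (is.null(model$dropped)) list() else
      apply(model$dropped, 1, as.list),
    disulfides = if (nrow(model$ss_pairs)) apply(model$ss_pairs, 1, as.list)
    else list()
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
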