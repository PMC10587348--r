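# Free-energy landscapes over the order-parameter grid, with basin, saddle
# and dominant-pathway annotations.

#' Free-energy landscape from a partition table
#'
#' `F(n) = -k_B T ln Z(n)` per bin, gauged so that the all-unfolded bin has
#' `F = 0`. Zero bins become `+Inf` with a warning; negative bins are an
#' upstream error.
#'
#' @param table A `wsme_partition_table` with non-negative bins.
#' @return Object of class `wsme_landscape`: `F` matrix (kcal/mol) over bins,
#'   `spec`, `temperature`, and grid vectors `n1`, `n2`.
#' @export
free_energy <- function(table) {
  if (any(table$sg < 0)) stop("partition table has negative bins")
  RT <- .wsme$R_kcal * table$temperature
  f <- -RT * table$lm
  if (any(table$sg == 0)) {
    warning("zero partition bins reported as F = +Inf")
    f[table$sg == 0] <- Inf
  }
  f <- f - f[1, 1]
  structure(list(F = f, spec = table$spec, temperature = table$temperature,
                 n1 = if (table$spec$n1 > 0)
                   (0:table$spec$n1) / table$spec$n1 else 0,
                 n2 = if (table$spec$n2 > 0)
                   (0:table$spec$n2) / table$spec$n2 else 0),
            class = "wsme_landscape")
}

#' @export
print.wsme_landscape <- function(x, ...) {
  cat("<wsme_landscape> ", nrow(x$F), "x", ncol(x$F), " bins, T=",
      x$temperature, "K, F range [", format(min(x$F)), ", ",
      format(max(x$F[is.finite(x$F)])), "] kcal/mol\n", sep = "")
  invisible(x)
}

is_1d <- function(ls) ncol(ls$F) == 1L

# union-find for watershed saddle detection
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Locate basins and saddles of a landscape
#'
#' 1D: basins are local minima and the transition states are the maxima
#' between adjacent basins. 2D: basins are 4-neighbourhood local minima;
#' saddles between basins are the minimax points over all 4-connected paths,
#' found by flooding the landscape in order of increasing F and recording the
#' first cell at which two basins' catchments merge. A monotone landscape
#' yields a single basin and no saddle (a valid downhill case).
#'
#' @param ls A `wsme_landscape`.
#' @return List with `basins` (data frame: i1, i2 1-based bin indices, F) and
#'   `saddles` (data frame: basin1, basin2, i1, i2, F), both ordered.
#' @export
find_basins_and_saddles <- function(ls) {
  f <- ls$F
  n1 <- nrow(f); n2 <- ncol(f)
  if (is_1d(ls)) {
    v <- f[, 1]
    k <- length(v)
    is_min <- vapply(seq_len(k), function(i) {
      left <- if (i > 1) v[i] < v[i - 1] else TRUE
      right <- if (i < k) v[i] < v[i + 1] else TRUE
      left && right && is.finite(v[i])
    }, TRUE)
    b <- which(is_min)
    basins <- data.frame(i1 = b, i2 = 1L, F = v[b])
    saddles <- NULL
    if (length(b) > 1) {
      saddles <- do.call(rbind, lapply(seq_len(length(b) - 1L), function(s) {
        seg <- b[s]:b[s + 1]
        ts <- seg[which.max(v[seg])]
        data.frame(basin1 = s, basin2 = s + 1L, i1 = ts, i2 = 1L, F = v[ts])
      }))
    } else saddles <- data.frame(basin1 = integer(), basin2 = integer(),
                                 i1 = integer(), i2 = integer(), F = numeric())
    return(list(basins = basins, saddles = saddles))
  }
  # 2D local minima (strict against finite neighbours)
  idx <- which(is.finite(f), arr.ind = TRUE)
  is_min <- apply(idx, 1, function(p) {
    i <- p[1]; j <- p[2]
    nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= n1 & nb[, 2] >= 1 & nb[, 2] <= n2, ,
             drop = FALSE]
    all(f[i, j] < f[nb] + 1e-15)
  })
  bmat <- idx[is_min, , drop = FALSE]
  basins <- data.frame(i1 = bmat[, 1], i2 = bmat[, 2],
                       F = f[bmat])
  basins <- basins[order(basins$F), ]
  rownames(basins) <- NULL
  # watershed flooding for minimax saddles
  cellid <- function(i, j) (j - 1L) * n1 + i
  basin_of_cell <- rep(NA_integer_, n1 * n2)
  for (b in seq_len(nrow(basins)))
    basin_of_cell[cellid(basins$i1[b], basins$i2[b])] <- b
  ord <- order(as.vector(f))
  parent <- uf_new(n1 * n2)
  comp_basin <- rep(NA_integer_, n1 * n2) # representative -> basin label
  added <- rep(FALSE, n1 * n2)
  saddles <- data.frame(basin1 = integer(), basin2 = integer(),
                        i1 = integer(), i2 = integer(), F = numeric())
  seen_pairs <- character()
  for (c0 in ord) {
    if (!is.finite(f[c0])) next
    added[c0] <- TRUE
    comp_basin[c0] <- basin_of_cell[c0]
    i <- (c0 - 1L) %% n1 + 1L; j <- (c0 - 1L) %/% n1 + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > n1 || jj < 1 || jj > n2) next
      c1 <- cellid(ii, jj)
      if (!added[c1]) next
      r0 <- uf_find(parent, c0); r1 <- uf_find(parent, c1)
      if (r0 == r1) next
      b0 <- comp_basin[r0]; b1 <- comp_basin[r1]
      if (!is.na(b0) && !is.na(b1) && b0 != b1) {
        key <- paste(min(b0, b1), max(b0, b1))
        if (!(key %in% seen_pairs)) {
          seen_pairs <- c(seen_pairs, key)
          saddles <- rbind(saddles,
                           data.frame(basin1 = min(b0, b1),
                                      basin2 = max(b0, b1),
                                      i1 = i, i2 = j, F = f[i, j]))
        }
      }
      parent[r1] <- r0
      comp_basin[r0] <- if (!is.na(b0)) b0 else b1
    }
  }
  list(basins = basins, saddles = saddles)
}

#' Minimax barrier between two basins over arbitrary 4-connected paths
#'
#' @param ls A `wsme_landscape` (2D).
#' @param from,to 1-based bin index pairs c(i1, i2).
#' @return The minimal over paths of the maximal F encountered.
#' @export
minimax_barrier <- function(ls, from, to) {
  f <- ls$F
  n1 <- nrow(f); n2 <- ncol(f)
  # Dijkstra-like on max-cost
  best <- matrix(Inf, n1, n2)
  best[from[1], from[2]] <- f[from[1], from[2]]
  active <- matrix(FALSE, n1, n2)
  active[from[1], from[2]] <- TRUE
  while (any(active)) {
    idx <- which(active, arr.ind = TRUE)
    sel <- idx[which.min(best[idx]), ]
    i <- sel[1]; j <- sel[2]
    active[i, j] <- FALSE
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > n1 || jj < 1 || jj > n2) next
      cand <- max(best[i, j], f[ii, jj])
      if (cand < best[ii, jj]) {
        best[ii, jj] <- cand
        active[ii, jj] <- TRUE
      }
    }
  }
  best[to[1], to[2]]
}

#' Dominant folding pathway across a 2D landscape
#'
#' The unfolded-to-native staircase path (steps increase one native count at
#' a time, so the pathway order parameter
#' `n_pathway = (N1 n1 + N2 n2)/N` never decreases) minimizing the maximum F
#' along the path; ties are broken by the lower path integral of F, then
#' lexicographically (axis-1 step preferred).
#'
#' @param ls A `wsme_landscape` (2D, finite corridor from bin (1,1) to the
#'   all-native bin).
#' @return Data frame with columns i1, i2 (1-based bin indices), n1, n2,
#'   n_pathway, F.
#' @export
dominant_pathway <- function(ls) {
  f <- ls$F
  if (is_1d(ls)) stop("dominant_pathway requires a 2D landscape")
  n1 <- nrow(f); n2 <- ncol(f)
  mm <- matrix(Inf, n1, n2)    # minimax value to reach cell
  ss <- matrix(Inf, n1, n2)    # tie-break path integral
  pre <- matrix(NA_integer_, n1, n2) # 1 = from left (i1-1), 2 = from below
  mm[1, 1] <- f[1, 1]; ss[1, 1] <- f[1, 1]
  for (t in 1:(n1 + n2 - 2)) {
    for (i in max(1, t - n2 + 2):min(n1, t + 1)) {
      j <- t - i + 2
      if (j < 1 || j > n2) next
      cands <- list()
      if (i > 1 && is.finite(mm[i - 1, j]))
        cands[[length(cands) + 1]] <- c(1, mm[i - 1, j], ss[i - 1, j])
      if (j > 1 && is.finite(mm[i, j - 1]))
        cands[[length(cands) + 1]] <- c(2, mm[i, j - 1], ss[i, j - 1])
      if (length(cands) == 0 || !is.finite(f[i, j])) next
      sc <- vapply(cands, function(cc)
        c(max(cc[2], f[i, j]), cc[3] + f[i, j], cc[1]), numeric(3))
      o <- order(sc[1, ], sc[2, ], sc[3, ])[1]
      mm[i, j] <- sc[1, o]; ss[i, j] <- sc[2, o]
      pre[i, j] <- as.integer(sc[3, o])
    }
  }
  if (!is.finite(mm[n1, n2]))
    stop("no finite-F staircase path from the unfolded to the native bin")
  path <- matrix(NA_integer_, n1 + n2 - 1, 2)
  i <- n1; j <- n2
  for (s in (n1 + n2 - 1):1) {
    path[s, ] <- c(i, j)
    if (s > 1) {
      if (pre[i, j] == 1L) i <- i - 1L else j <- j - 1L
    }
  }
  spec <- ls$spec
  data.frame(
    i1 = path[, 1], i2 = path[, 2],
    n1 = (path[, 1] - 1) / max(spec$n1, 1),
    n2 = (path[, 2] - 1) / max(spec$n2, 1),
    n_pathway = ((path[, 1] - 1) + (path[, 2] - 1)) / spec$n,
    F = f[path]
  )
}
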