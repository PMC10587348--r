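test_that("free_energy gauges at the unfolded bin and flags zero bins", {
  inst <- random_instance(31, n = 9)
  pt <- restricted_partition(inst$model, inst$entropy, 300, inst$spec,
                             method = "enumerate")
  ls <- free_energy(pt)
  expect_equal(ls$F[1, 1], 0)
  RT <- wsme_constants()$R_kcal * 300
  expect_equal(ls$F[, 1], -RT * (pt$lm[, 1] - pt$lm[1, 1]))
  # uniform Z -> flat F
  flat <- wsmel:::new_partition_table(matrix(2, 5, 1), matrix(1, 5, 1),
                                      order_spec(4), 300)
  expect_true(all(free_energy(flat)$F == 0))
  # zero bin -> +Inf with warning
  z <- pt; z$sg[3, 1] <- 0; z$lm[3, 1] <- -Inf
  expect_warning(lz <- free_energy(z), "Inf")
  expect_true(is.infinite(lz$F[3, 1]))
})

test_that("1D basins and transition states follow the double-well shape", {
  ls <- structure(list(F = matrix(c(0, 3, -5), 3, 1), temperature = 300,
                       spec = order_spec(2), n1 = c(0, .5, 1), n2 = 0),
                  class = "wsme_landscape")
  ann <- find_basins_and_saddles(ls)
  expect_equal(ann$basins$i1, c(1, 3))
  expect_equal(ann$saddles$i1, 2)
  # strictly decreasing F: single basin, no transition state (downhill)
  ls2 <- ls; ls2$F <- matrix(c(0, -1, -2), 3, 1)
  ann2 <- find_basins_and_saddles(ls2)
  expect_equal(nrow(ann2$basins), 1)
  expect_equal(nrow(ann2$saddles), 0)
})

test_that("2D saddles equal brute-force minimax over all grid paths", {
  # brute-force oracle: connectivity under a sweeping threshold
  brute_minimax <- function(f, from, to) {
    vals <- sort(unique(as.vector(f)))
    for (v in vals) {
      ok <- f <= v
      # flood fill from 'from'
      reach <- matrix(FALSE, nrow(f), ncol(f))
      reach[from[1], from[2]] <- ok[from[1], from[2]]
      repeat {
        grew <- FALSE
        for (i in seq_len(nrow(f))) for (j in seq_len(ncol(f))) {
          if (!reach[i, j]) next
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            ii <- i + d[1]; jj <- j + d[2]
            if (ii >= 1 && ii <= nrow(f) && jj >= 1 && jj <= ncol(f) &&
                ok[ii, jj] && !reach[ii, jj]) {
              reach[ii, jj] <- TRUE; grew <- TRUE
            }
          }
        }
        if (!grew) break
      }
      if (reach[to[1], to[2]]) return(v)
    }
    Inf
  }
  local_seed(32, for (rep in 1:3) {
    f <- matrix(rnorm(49), 7, 7)
    ls <- structure(list(F = f, temperature = 300,
                         spec = order_spec(12, 1:6, 7:12),
                         n1 = (0:6) / 6, n2 = (0:6) / 6),
                    class = "wsme_landscape")
    from <- c(1, 1); to <- c(7, 7)
    expect_equal(minimax_barrier(ls, from, to), brute_minimax(f, from, to))
    # watershed saddle between the two deepest basins is consistent
    ann <- find_basins_and_saddles(ls)
    if (nrow(ann$basins) >= 2 && nrow(ann$saddles) >= 1) {
      b1 <- unlist(ann$basins[1, c("i1", "i2")])
      b2 <- unlist(ann$basins[2, c("i1", "i2")])
      mm <- brute_minimax(f, b1, b2)
      sd12 <- ann$saddles$F[ann$saddles$basin1 == 1 & ann$saddles$basin2 == 2]
      if (length(sd12) == 1) expect_equal(sd12, mm)
    }
  })
})

test_that("dominant pathway equals exhaustive monotone-path enumeration", {
  enumerate_paths <- function(f) {
    n1 <- nrow(f); n2 <- ncol(f)
    best <- NULL
    recurse <- function(i, j, mx, sm, path) {
      mx <- max(mx, f[i, j]); sm <- sm + f[i, j]
      path <- rbind(path, c(i, j))
      if (i == n1 && j == n2) {
        if (is.null(best) || mx < best$mx - 1e-12 ||
            (abs(mx - best$mx) < 1e-12 && sm < best$sm - 1e-12))
          best <<- list(mx = mx, sm = sm, path = path)
        return()
      }
      if (i < n1) recurse(i + 1, j, mx, sm, path)
      if (j < n2) recurse(i, j + 1, mx, sm, path)
    }
    recurse(1, 1, -Inf, 0, NULL)
    best
  }
  local_seed(33, for (rep in 1:3) {
    f <- matrix(rnorm(48), 8, 6)
    f[1, 1] <- min(f) - 1
    ls <- structure(list(F = f, temperature = 300,
                         spec = order_spec(12, 1:7, 8:12),
                         n1 = (0:7) / 7, n2 = (0:5) / 5),
                    class = "wsme_landscape")
    got <- dominant_pathway(ls)
    oracle <- enumerate_paths(f)
    expect_equal(max(got$F), oracle$mx)
    expect_equal(sum(got$F), oracle$sm)
    # n_pathway is non-decreasing along the path
    expect_true(all(diff(got$n_pathway) >= 0))
  })
  # unique finite corridor -> exactly that corridor
  f <- matrix(Inf, 3, 3)
  f[, 1] <- c(0, 1, 2); f[3, ] <- c(2, 3, 4)
  ls <- structure(list(F = f, temperature = 300,
                       spec = order_spec(4, 1:2, 3:4),
                       n1 = (0:2) / 2, n2 = (0:2) / 2),
                  class = "wsme_landscape")
  got <- dominant_pathway(ls)
  expect_equal(got$i1, c(1, 2, 3, 3, 3))
  expect_equal(got$i2, c(1, 1, 1, 2, 3))
})

test_that("landscape gauge removes state-independent energy offsets", {
  inst <- random_instance(34, n = 9)
  m <- inst$model; ent <- inst$entropy; spec <- inst$spec
  E <- contact_energies(m)
  a <- wsmel:::run_partition(E, ent, 300, spec)
  b <- wsmel:::run_partition(E, ent, 300, spec, energy_offset = 0.7)
  # a constant in the exponent shifts every bin uniformly, so barriers,
  # pathways and Phi values built from the gauged F are unchanged
  expect_equal(free_energy(a)$F, free_energy(b)$F, tolerance = 1e-10)
})
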