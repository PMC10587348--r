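test_that("read_structure parses fixture PDBs and applies selection rules", {
  fx <- make_toy_model(6, "hairpin", seed = 1)
  chain <- read_structure(fx$pdb)
  expect_s3_class(chain, "wsme_chain")
  expect_equal(chain$n, 6)
  expect_equal(chain$ca, fx$chain$ca, tolerance = 1e-3)

  # residue lacking CA -> error naming it
  bad <- sub("CA ", "CB ", fx$pdb[3], fixed = TRUE)
  pdb_bad <- fx$pdb; pdb_bad[3] <- bad
  expect_error(read_structure(pdb_bad), "no CA atom")

  # two chains -> first chain only
  second <- gsub(" A", " B", fx$pdb[1:6])
  chain1 <- read_structure(c(fx$pdb[1:6], second, "END"))
  expect_equal(chain1$n, 6)
  # explicit selection of the second chain works too
  chainB <- read_structure(c(fx$pdb[1:6], second, "END"), chain_id = "B")
  expect_equal(chainB$n, 6)

  # multi-model file: model 1 used, with a message
  mm <- c("MODEL     1", fx$pdb[1:6], "ENDMDL",
          "MODEL     2", fx$pdb[1:6], "ENDMDL", "END")
  expect_message(chain_m <- read_structure(mm), "model 1")
  expect_equal(chain_m$n, 6)
})

test_that("geometric_contact_map applies the distance and locality rules", {
  # three residues near, far apart in sequence
  ca <- matrix(c(0, 0, 0,
                 50, 0, 0,
                 100, 0, 0,
                 3.5, 0, 0,   # close to residue 1, |i-j| = 3
                 100, 3.0, 0, # close to residue 3, |i-j| = 2 -> excluded
                 200, 0, 0), ncol = 3, byrow = TRUE)
  chain <- wsmel:::new_chain_from_ca(ca)
  m <- geometric_contact_map(chain, cutoff = 4.0, ca_fallback = TRUE)
  expect_equal(m$weights[1, 4], -1)   # 3.5 A, |i-j| > 2
  expect_equal(m$weights[3, 5], 0)    # |i-j| = 2 excluded
  expect_equal(sum(m$weights != 0), 2)

  # all residues far apart -> all-zero matrix
  far <- wsmel:::new_chain_from_ca(matrix(seq(0, 100, length.out = 18),
                                          6, 3) * 10)
  m0 <- geometric_contact_map(far, cutoff = 4.0, ca_fallback = TRUE)
  expect_true(all(m0$weights == 0))

  # Calpha-only chains require the explicit fallback flag
  expect_error(geometric_contact_map(chain, 4.0), "ca_fallback")

  # monotone in cutoff: contacts(c1) subset of contacts(c2) for c1 <= c2
  fx <- make_toy_model(12, "compact", seed = 3)
  cuts <- c(4, 5.5, 8)
  maps <- lapply(cuts, function(ct)
    geometric_contact_map(fx$chain, ct, ca_fallback = TRUE)$weights != 0)
  expect_true(all(maps[[1]] <= maps[[2]]))
  expect_true(all(maps[[2]] <= maps[[3]]))
})

test_that("weighted_energy_model normalizes and drops local pairs", {
  raw <- data.frame(i = c(1, 2), j = c(5, 9), energy = c(-2, -4))
  m <- weighted_energy_model(raw, n = 9)
  expect_equal(m$weights[1, 5], -0.5)
  expect_equal(m$weights[2, 9], -1)
  expect_equal(m$normalizer, 4)

  # local pair excluded from both output and the normalizing max
  raw2 <- data.frame(i = c(3, 1), j = c(5, 9), energy = c(-10, -2))
  m2 <- weighted_energy_model(raw2, n = 9)
  expect_equal(m2$weights[3, 5], 0)
  expect_equal(m2$weights[1, 9], -1)
  expect_equal(m2$normalizer, 2)

  # all-zero retained energies -> error
  raw3 <- data.frame(i = 3, j = 5, energy = -10)
  expect_error(weighted_energy_model(raw3, n = 9), "normalization undefined")

  # asymmetric matrix symmetrized by averaging, with a warning
  a <- matrix(0, 8, 8); a[1, 5] <- -2; a[5, 1] <- -4
  expect_warning(m3 <- weighted_energy_model(a), "symmetrizing")
  expect_equal(m3$raw[1, 5], -3)

  # invariants: symmetry, locality, normalization to exactly 1
  for (seed in 1:5) {
    inst <- random_instance(seed)
    w <- inst$model$weights
    expect_identical(w, t(w))
    expect_true(all(w[abs(row(w) - col(w)) <= 2] == 0))
    expect_equal(max(abs(w)), 1)
  }
})

test_that("disulfide bonus modifies raw energies without renormalizing", {
  raw <- matrix(0, 10, 10)
  raw[1, 5] <- raw[5, 1] <- -3
  raw[2, 9] <- raw[9, 2] <- -4
  m <- weighted_energy_model(raw)
  m2 <- apply_disulfide_bonus(m, rbind(c(1, 5)), bonus = -40)
  expect_equal(m2$raw[1, 5], -43)
  expect_equal(m2$weights[1, 5], -43 / 4)  # normalizer unchanged
  expect_equal(m2$weights[2, 9], -1)
  expect_silent(wsmel:::validate_energy_model(m2)) # SS excess allowed
  # identity cases
  expect_equal(apply_disulfide_bonus(m, matrix(integer(), 0, 2))$weights,
               m$weights)
  expect_equal(apply_disulfide_bonus(m, rbind(c(1, 5)), bonus = 0)$weights,
               m$weights)
  expect_error(apply_disulfide_bonus(m, rbind(c(1, 11))), "outside")
  # weight-increment path for models without raw energies
  g <- wsmel:::new_energy_model(10, m$weights)
  expect_message(g2 <- apply_disulfide_bonus(g, rbind(c(1, 5))),
                 "weight increment")
  expect_equal(g2$weights[1, 5], m$weights[1, 5] - 10)
})

test_that("zero_disulfide_neighborhood zeroes the five-pair neighbourhood", {
  fx <- make_toy_model(14, "hairpin", seed = 2)
  m <- fx$model
  pair <- fx$designed_pairs[which.max(fx$designed_pairs[, 2] -
                                        fx$designed_pairs[, 1]), ]
  i <- pair[1]; j <- pair[2]
  z <- zero_disulfide_neighborhood(m, rbind(pair))
  for (p in list(c(i, j), c(i - 1, j), c(i + 1, j), c(i, j - 1),
                 c(i, j + 1))) {
    if (all(p >= 1 & p <= 14)) expect_equal(z$weights[p[1], p[2]], 0)
  }
  # boundary clipping: pair at (1, N)
  m2 <- m; m2$weights[1, 14] <- m2$weights[14, 1] <- -0.5
  z2 <- zero_disulfide_neighborhood(m2, rbind(c(1, 14)))
  expect_equal(z2$weights[1, 14], 0)
  # idempotent
  expect_equal(zero_disulfide_neighborhood(z, rbind(pair))$weights, z$weights)
})

test_that("linker_set thresholds raw energies", {
  raw <- matrix(0, 9, 9)
  raw[1, 9] <- raw[9, 1] <- -0.7
  raw[2, 8] <- raw[8, 2] <- -0.5
  m <- weighted_energy_model(raw)
  expect_equal(linker_set(m, -0.6), matrix(c(1L, 9L), 1))
  expect_equal(nrow(linker_set(m, -Inf)), 0)
  expect_equal(nrow(linker_set(m, 0)), 2)   # all negative pairs
  # no raw energies: fall back to negative weights, with a message
  g <- wsmel:::new_energy_model(9, m$weights)
  expect_message(ls0 <- linker_set(g), "negative-weight")
  expect_equal(nrow(ls0), 2)
})

test_that("linker_gain sums the five-weight neighbourhood", {
  w <- matrix(0, 12, 12)
  for (p in list(c(4, 9), c(3, 9), c(5, 9), c(4, 8), c(4, 10)))
    w[p[1], p[2]] <- w[p[2], p[1]] <- -0.2
  m <- wsmel:::new_energy_model(12, w, eps = 1)
  lg <- linker_gain(m, 4, 9)
  expect_equal(lg$eps_prime, -1.0)
  expect_equal(nrow(lg$mask), 5)
  # boundary: u = 1 has no u-1 term
  w2 <- matrix(0, 12, 12)
  for (p in list(c(1, 9), c(2, 9), c(1, 8), c(1, 10)))
    w2[p[1], p[2]] <- w2[p[2], p[1]] <- -0.2
  m2 <- wsmel:::new_energy_model(12, w2, eps = 1)
  expect_equal(linker_gain(m2, 1, 9)$eps_prime, -0.8)
  expect_equal(linker_gain(wsmel:::new_energy_model(12, matrix(0, 12, 12)),
                           4, 9)$eps_prime, 0)
})

test_that("mask_region zeroes rows and columns only for listed residues", {
  inst <- random_instance(4)
  m <- inst$model
  expect_equal(mask_region(m, integer())$weights, m$weights)
  expect_true(all(mask_region(m, 1:m$n)$weights == 0))
  k <- 4
  mk <- mask_region(m, k)
  expect_true(all(mk$weights[k, ] == 0) && all(mk$weights[, k] == 0))
  untouched <- m$weights[-k, -k]
  expect_equal(mk$weights[-k, -k], untouched)
})

test_that("energy tables and contact maps round-trip through files", {
  dir <- withr::local_tempdir()
  raw <- data.frame(i = c(1, 2, 3), j = c(6, 9, 8),
                    energy = c(-1.25, -2.5, -0.75))
  path <- file.path(dir, "e.tsv")
  write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_energy_table(path)
  expect_equal(tab$energy, raw$energy)
  m <- weighted_energy_model(tab, n = 9)
  out <- file.path(dir, "map.tsv")
  write_contact_map(m, out)
  expect_true(file.exists(out) && file.exists(paste0(out, ".json")))
  back <- read.table(out, header = TRUE, sep = "\t")
  expect_equal(back$e[back$i == 2 & back$j == 9], -1)
})
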