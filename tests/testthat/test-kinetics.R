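R <- wsme_constants()

make_landscape_1d <- function(f, temperature = 300) {
  structure(list(F = matrix(f, ncol = 1), temperature = temperature,
                 spec = order_spec(length(f) - 1),
                 n1 = seq(0, 1, length.out = length(f)), n2 = 0),
            class = "wsme_landscape")
}

test_that("two-bin system gives the analytic two-state relaxation", {
  ls <- make_landscape_1d(c(0, -1))
  out <- folding_rate_1d(ls, A = 1e7)
  RT <- R$R_kcal * 300
  k01 <- 1e7 * exp(1 / (2 * RT)); k10 <- 1e7 * exp(-1 / (2 * RT))
  expect_equal(out$k_f, k01 + k10, tolerance = 1e-10)
  # flat landscape: uniform stationary distribution
  flat <- folding_rate_1d(make_landscape_1d(rep(0, 6)))
  expect_equal(flat$stationary, rep(1 / 6, 6))
  expect_error(folding_rate_1d(make_landscape_1d(c(0, Inf, 1))), "finite")
})

test_that("rate matrix satisfies detailed balance and the ODE oracle", {
  local_seed(51, for (rep in 1:3) {
    f <- cumsum(rnorm(10, sd = 0.8))
    ls <- make_landscape_1d(f)
    out <- folding_rate_1d(ls)
    M <- out$rate_matrix
    expect_equal(colSums(M), rep(0, 10), tolerance = 1e-8)
    pi <- out$stationary
    for (i in 1:9)
      expect_lt(abs(M[i + 1, i] * pi[i] - M[i, i + 1] * pi[i + 1]), 1e-8)
    # relaxation rate from explicit numerical integration
    tg <- seq(0, 3 / out$k_f, length.out = 60)
    sol <- solve_scheme(M, tg, C0 = c(1, rep(0, 9)))
    dist <- rowSums(abs(as.matrix(sol$populations[, -1]) -
                          matrix(pi, length(tg), 10, byrow = TRUE)))
    sel <- tg > 1.2 / out$k_f & dist > 1e-12
    fit <- lm(log(dist[sel]) ~ tg[sel])
    expect_equal(-unname(coef(fit)[2]), out$k_f, tolerance = 0.02)
  })
})

test_that("stability reads basin minima and rejects single wells", {
  ls <- make_landscape_1d(c(0, 2, -5, -4, -3))
  expect_equal(stability(ls), -5)
  sym <- make_landscape_1d(c(-1, 2, -1))
  expect_equal(stability(sym), 0)
  expect_error(stability(make_landscape_1d(c(0, -1, -2))), "undefined")
})

test_that("oracle-backed stability matches the partition route", {
  fx <- make_toy_model(12, "compact", seed = 2, S = -2.5)
  m <- fx$model; m$eps <- 1.4
  pt_tm <- wsme_l_partition(m, fx$entropy, 298, fx$spec)
  pt_en <- wsme_l_partition(m, fx$entropy, 298, fx$spec,
                            method = "enumerate")
  expect_equal(stability(free_energy(pt_tm)), stability(free_energy(pt_en)),
               tolerance = 1e-9)
})

test_that("self-target parameter recovery works on one instance", {
  fx <- make_toy_model(12, "compact", seed = 2, S = -2.5)
  lk <- linker_set(fx$model)
  build <- function(eps, h) {
    m <- fx$model; m$eps <- eps
    ent <- fx$entropy; ent$h_sprime <- h
    free_energy(wsme_l_partition(m, ent, 300, fx$spec, linkers = lk))
  }
  ls0 <- build(1.4, 1.3)
  fit <- fit_parameters(build, dG_target = stability(ls0),
                        kf_target = folding_rate_1d(ls0)$k_f,
                        temperature = 300, h_grid = seq(1.1, 1.5, 0.1),
                        eps_interval = c(0.5, 4))
  expect_equal(fit$best$h, 1.3)
  expect_lt(abs(fit$best$eps - 1.4), 0.01)
  expect_lt(fit$best$loss, 1e-6)
  # rate-free variant uses the stability loss only
  fit2 <- fit_parameters(build, dG_target = stability(ls0),
                         temperature = 300, h_grid = c(1.3),
                         eps_interval = c(0.5, 4))
  expect_lt(fit2$best$loss, 1e-7)
})

test_that("scheme prefactor and rates follow the internal-friction form", {
  expect_equal(scheme_prefactor(0, 1e7), 1e7)
  expect_equal(scheme_prefactor(1, 1e7), 1e7 / 6)
  expect_equal(scheme_prefactor(0.5, 2e6), 2e6 / (1 + 5 * 0.25))
  # barrierless limit: k = A(n_saddle)
  f <- matrix(c(0, 0, 0, 0), 2, 2)
  ls <- structure(list(F = f, temperature = 300,
                       spec = order_spec(2, 1, 2), n1 = 0:1, n2 = 0:1),
                  class = "wsme_landscape")
  sch <- scheme_rates(ls, states = list(U = c(1, 1), N = c(2, 2)),
                      transitions = list(c("U", "N")), A0 = 1e7)
  r <- sch$rates
  expect_equal(r$rate[r$from == "U"],
               scheme_prefactor(r$n_saddle[r$from == "U"], 1e7))
})

test_that("scheme solutions conserve mass and match brute-force checks", {
  # conservative four-state scheme with random rates
  local_seed(52, {
    rates <- data.frame(
      from = c("U", "I1", "I1", "I2", "I1", "N", "I2", "N"),
      to   = c("I1", "U", "I2", "I1", "N", "I1", "N", "I2"),
      rate = runif(8, 0.1, 5))
    sch <- structure(list(rates = rates), class = "wsme_scheme")
    G <- scheme_matrix_conservative(sch)
    expect_equal(colSums(G), rep(0, 4), tolerance = 1e-12,
                 ignore_attr = TRUE)
    tg <- seq(0, 5, length.out = 40)
    sol <- solve_scheme(G, tg)
    expect_true(all(abs(rowSums(sol$populations[, -1]) - 1) < 1e-9))
    # all-zero rates freeze the system
    sol0 <- solve_scheme(matrix(0, 3, 3,
                                dimnames = list(letters[1:3], letters[1:3])),
                         tg, C0 = c(0.2, 0.5, 0.3))
    expect_true(all(abs(as.matrix(sol0$populations[, -1]) -
                          matrix(c(0.2, 0.5, 0.3), 40, 3, byrow = TRUE))
                    < 1e-12))
    # eigen solution matches explicit RK4 integration
    y <- c(1, 0, 0, 0)
    h <- tg[2] / 50
    for (s in 1:50) {
      k1 <- G %*% y; k2 <- G %*% (y + h / 2 * k1)
      k3 <- G %*% (y + h / 2 * k2); k4 <- G %*% (y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    expect_equal(unlist(sol$populations[2, -1]), y[, 1],
                 tolerance = 1e-7, ignore_attr = TRUE)
  })
})

test_that("irreversible scheme terminal split matches stochastic simulation", {
  local_seed(53, {
    rates <- data.frame(
      from = c("U", "I1", "I1", "I2", "I1", "I2"),
      to   = c("I1", "U", "I2", "I1", "N", "N"),
      rate = c(4, 1, 2.5, 0.7, 1.2, 3))
    sch <- structure(list(rates = rates), class = "wsme_scheme")
    G <- scheme_matrix_irreversible(sch)
    expect_equal(colSums(G), rep(0, 5), tolerance = 1e-12,
                 ignore_attr = TRUE)
    sol <- solve_scheme(G, seq(0, 50, length.out = 20))
    split <- sol$terminal["Np1"] / (sol$terminal["Np1"] +
                                      sol$terminal["Np2"])
    # embedded-jump-chain simulation of 1e6 molecules
    nsim <- 1e6
    state <- rep(1L, nsim) # 1=U 2=I1 3=I2 4=Np1 5=Np2
    k <- function(a, b) rates$rate[rates$from == a & rates$to == b]
    for (step in 1:200) {
      active <- state <= 3L
      if (!any(active)) break
      u <- runif(sum(active))
      s <- state[active]
      new <- s
      # U -> I1 always
      new[s == 1L] <- 2L
      pI1 <- c(k("I1", "U"), k("I1", "I2"), k("I1", "N"))
      pI1 <- cumsum(pI1) / sum(pI1)
      i1 <- s == 2L
      new[i1] <- ifelse(u[i1] < pI1[1], 1L, ifelse(u[i1] < pI1[2], 3L, 5L))
      pI2 <- c(k("I2", "I1"), k("I2", "N"))
      pI2 <- cumsum(pI2) / sum(pI2)
      i2 <- s == 3L
      new[i2] <- ifelse(u[i2] < pI2[1], 2L, 4L)
      state[active] <- new
    }
    sim_split <- mean(state == 4L)
    se <- sqrt(sim_split * (1 - sim_split) / nsim)
    expect_lt(abs(split - sim_split), 3 * se + 1e-6)
  })
})

test_that("domain time evolution is the population-weighted Phi sum", {
  pops <- data.frame(t = c(0, 1, 2),
                     U = c(1, 0.5, 0.2), I1 = c(0, 0.3, 0.3),
                     Np1 = c(0, 0.1, 0.3), Np2 = c(0, 0.1, 0.2))
  phi <- c(U = 0.05, I1 = 0.6, N = 0.95)
  p <- domain_time_evolution(pops, phi)
  expect_equal(p$p[1], 0.05)
  expect_equal(p$p[2], 0.5 * 0.05 + 0.3 * 0.6 + 0.2 * 0.95)
  expect_equal(p$p[3], 0.2 * 0.05 + 0.3 * 0.6 + 0.5 * 0.95)
})
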