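# Shared generators for randomized test instances. All randomness is wrapped
# in local seeds so the suite is deterministic.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

# random energy model + entropy + spec; guarantees at least one contact
random_instance <- function(seed, n = NULL, two_d = FALSE, density = 0.4) {
  local_seed(seed, {
    if (is.null(n)) n <- sample(6:12, 1)
    raw <- matrix(0, n, n)
    for (i in 1:(n - 3)) for (j in (i + 3):n) if (runif(1) < density) {
      raw[i, j] <- raw[j, i] <- -runif(1, 0.2, 3)
    }
    if (all(raw == 0)) raw[1, n] <- raw[n, 1] <- -1.5
    model <- weighted_energy_model(raw)
    model$eps <- runif(1, 0.5, 2)
    ca <- matrix(rnorm(3 * n, sd = 6), n, 3)
    entropy <- entropy_model(n, S = -runif(1, 1.5, 4),
                             h_sprime = runif(1, 0.5, 2),
                             r = as.matrix(dist(ca)))
    spec <- if (two_d) {
      r1 <- sort(sample(1:n, n %/% 2))
      order_spec(n, r1, setdiff(1:n, r1))
    } else order_spec(n)
    list(model = model, entropy = entropy, spec = spec,
         temperature = runif(1, 280, 360), n = n)
  })
}

# max relative deviation between two partition tables (bin-wise)
table_rel_dev <- function(a, b) {
  stopifnot(all(dim(a$lm) == dim(b$lm)))
  both_zero <- a$sg == 0 & b$sg == 0
  d <- abs(exp(a$lm - b$lm) - 1)
  d[both_zero] <- 0
  max(d)
}
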