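test_that("cumulative results honour the boundary and monotonicity contract", {
  cfg <- italy_fixture()
  for (engine in c("exact", "bahadur", "independent")) {
    res <- at_least(cfg, "NITp", 6, engine = engine)
    expect_equal(res$p_at_least[1], 1, tolerance = 1e-12)       # k = 0
    expect_true(all(diff(res$p_at_least) <= 1e-12))             # non-increasing
    expect_equal(at_least_value(res, 7), 0)                     # k = M + 1
    expect_equal(at_least_value(res, -1), 1)
  }
})

test_that("at M = 1 the cumulative model reduces to the first model", {
  cfg <- italy_fixture()
  p1 <- nth_probability(cfg, 1)$prob[1, ]
  for (c in names(p1)) {
    expect_equal(at_least_exact(cfg, c, 1)$p_at_least[2], unname(p1[c]),
                 tolerance = 1e-12)
  }
})

test_that("strict alternation: two certain centres split two organs", {
  cfg <- two_slot_config(1, 1)
  for (c in c("A", "B")) {
    res <- at_least_exact(cfg, c, 2)
    expect_equal(res$p_at_least, c(1, 1, 0), tolerance = 1e-12)
  }
})

test_that("a single-centre nation reproduces the binomial tail", {
  M <- 20
  for (p in c(0.26, 0.9, 1.0)) {
    cfg <- single_center_config(p)
    ex <- at_least_exact(cfg, "A", M)
    expect_equal(ex$p_at_least, pbinom(0:M - 1, M, p, lower.tail = FALSE),
                 tolerance = 1e-12)
    law <- law_from_chain(cfg, "A", M)
    expect_equal(at_least_independent(law)$p_at_least,
                 pbinom(0:M - 1, M, p, lower.tail = FALSE), tolerance = 1e-12)
  }
})

test_that("the independence engine matches 2^M enumeration", {
  p <- c(0.2, 0.5, 0.9)
  law <- acceptance_law(p)
  # full enumeration of the 8 outcomes
  grid <- as.matrix(expand.grid(rep(list(0:1), 3)))
  mass <- apply(grid, 1, function(x) prod(p^x * (1 - p)^(1 - x)))
  for (k in 0:3) {
    expect_equal(at_least_independent(law, k),
                 sum(mass[rowSums(grid) >= k]), tolerance = 1e-12)
  }
  expect_equal(at_least_independent(law, 0), 1)
})

test_that("zero-correlation Bahadur is bitwise the independence engine", {
  cfg <- italy_fixture()
  law <- law_from_chain(cfg, "Toscana", 8)
  law$R <- diag(1, 8)
  expect_identical(at_least_bahadur(law)$p_at_least,
                   at_least_independent(law)$p_at_least)
  expect_equal(at_least_bahadur(law)$clipped_mass, 0)
})

test_that("two correlated indicators match the closed-form joint law", {
  p <- c(0.5, 0.5); r <- 0.5
  law <- acceptance_law(p, matrix(c(1, r, r, 1), 2))
  # exact two-variable Bernoulli law with correlation r:
  p11 <- p[1] * p[2] + r * sqrt(prod(p * (1 - p)))
  expect_equal(at_least_bahadur(law, 2), p11, tolerance = 1e-12)
  p10 <- p[1] - p11; p01 <- p[2] - p11
  expect_equal(at_least_bahadur(law, 1), p11 + p10 + p01, tolerance = 1e-12)
})

test_that("the exchangeable Bahadur case matches full enumeration of the density", {
  M <- 4; p <- rep(0.3, M); r <- 0.2
  R <- matrix(r, M, M); diag(R) <- 1
  law <- acceptance_law(p, R)
  got <- at_least_bahadur(law)
  expect_equal(got$p_at_least, oracle_bahadur_atleast(p, R), tolerance = 1e-12)
})

test_that("clipping activates only when the truncated density goes negative", {
  M <- 4; p <- rep(0.1, M)
  R <- matrix(0.9, M, M); diag(R) <- 1  # strong correlation forces negativity
  law <- acceptance_law(p, R)
  res <- at_least_bahadur(law)
  expect_gt(res$clipped_mass, 0)
  expect_true(all(res$p_at_least >= 0))
  expect_equal(res$p_at_least[1], 1, tolerance = 1e-12)
  expect_equal(res$p_at_least, oracle_bahadur_atleast(p, R), tolerance = 1e-12)
})

test_that("the chain-derived law matches brute-force enumeration", {
  cfg <- random_config(12, n_centers = c(1, 2), max_slots = 1,
                       n_extra_regions = c(0, 1), n_producers = 2)
  target <- names(cfg$centers)[1]
  M <- 3
  law <- law_from_chain(cfg, target, M)
  orc <- oracle_enumerate(cfg, M, target = target)
  expect_equal(law$p, unname(orc$prob[, target]), tolerance = 1e-12)
  ex <- at_least_exact(cfg, target, M)
  expect_equal(ex$p_at_least, orc$atleast, tolerance = 1e-12)
})

test_that("rotation-forced alternation makes successive organs anti-correlated", {
  # deterministic round-robin: marginals are degenerate (1, 0, 1, 0) and the
  # correlations take the degenerate-indicator convention, 0
  cfg <- two_slot_config(1, 1)
  law <- law_from_chain(cfg, "A", 4)
  expect_equal(law$p, c(1, 0, 1, 0))
  expect_equal(law$R[1, 2], 0)
  # all rates 0: marginals all 0, correlations 0 by the same convention
  cfg0 <- two_slot_config(0, 0)
  law0 <- law_from_chain(cfg0, "A", 3)
  expect_equal(law0$p, c(0, 0, 0))
  expect_true(all(law0$R[upper.tri(law0$R)] == 0))
  # randomising the first donor: if A obtains organ 1 it can never obtain
  # organ 2. Hand enumeration: p = (1/2, 1/4), P(both) = 0, r = -1/sqrt(3);
  # cross-checked against the path-enumeration oracle.
  cfg2 <- two_slot_config(1, 1)
  cfg2$macroareas$MA1$regions$production <- c(1L, 0L, 1L)  # RA and RX produce
  law2 <- law_from_chain(cfg2, "A", 2)
  orc <- oracle_enumerate(cfg2, 2, target = "A")
  expect_equal(law2$p, unname(orc$prob[, "A"]), tolerance = 1e-12)
  expect_equal(orc$count_pmf[3], 0)  # both organs to A: impossible
  expect_equal(law2$p, c(0.5, 0.25), tolerance = 1e-12)
  expect_equal(law2$R[1, 2], -1 / sqrt(3), tolerance = 1e-12)
})

test_that("certain acceptance extinguishes the tail at the routable maximum", {
  # two certain centres, M = 6 organs from an outside donor: strict
  # alternation routes exactly 3 to each, so P(at least 4) = 0
  cfg <- two_slot_config(1, 1)
  res <- at_least_exact(cfg, "A", 6)
  expect_equal(res$p_at_least[1:4], c(1, 1, 1, 1), tolerance = 1e-12)
  expect_equal(res$p_at_least[5:7], c(0, 0, 0), tolerance = 1e-12)
})

test_that("the Monte Carlo law reports marginals with standard errors", {
  cfg <- italy_fixture()
  law <- law_from_chain(cfg, "NITp", 4, engine = "montecarlo",
                        n_reps = 20000, seed = 5)
  exact <- law_from_chain(cfg, "NITp", 4)
  expect_true(all(abs(law$p - exact$p) <= 4 * pmax(law$se, 1e-4)))
  expect_length(law$se, 4)
})
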