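test_that("position-conditional probabilities follow the cascade product", {
  cfg <- italy_fixture()
  st <- initial_state(cfg)
  # head of the donor-MA strip, no-centre donor: the acceptance rate itself
  expect_equal(position_conditional_probability(cfg, st, "Piemonte", 1,
                                                donor_region = "Valle d'Aosta"),
               0.26)
  # position 2: one predecessor refusal
  expect_equal(position_conditional_probability(cfg, st, "Emilia Romagna", 2,
                                                donor_region = "Valle d'Aosta"),
               (1 - 0.26) * 0.26)
  # donor inside the centre's own (macro)region: producer exclusion
  expect_equal(position_conditional_probability(cfg, st, "NITp", 4,
                                                donor_region = "Lombardia"),
               0)
  # hand-set rates: predecessor 0.5, own 0.26 -> 0.13
  cfg2 <- two_slot_config(p = 0.5, q = 0.26)
  expect_equal(position_conditional_probability(cfg2, initial_state(cfg2),
                                                "B", 2, donor_region = "RX"),
               0.5 * 0.26)
  expect_error(position_conditional_probability(cfg, st, "Piemonte", 3,
                                                donor_region = "Valle d'Aosta"),
               "does not occupy")
})

test_that("the marginal variant multiplies by the non-production probability", {
  cfg <- italy_fixture()
  st <- initial_state(cfg)
  S <- donor_distribution(cfg)
  got <- position_conditional_probability(cfg, st, "Toscana", 3,
                                          variant = "marginal")
  expect_equal(got, 0.26 * (1 - S[["Toscana"]]) * (1 - 0.26)^2, tolerance = 1e-14)
  # NITp's marginal excludes all its member regions' production
  s_nitp <- sum(S[c("Lombardia", "Veneto", "Friuli Venezia Giulia",
                    "Trentino-Alto Adige", "Liguria", "Marche")])
  got <- position_conditional_probability(cfg, st, "NITp", 4,
                                          variant = "marginal")
  expect_equal(got, 0.26 * (1 - s_nitp) * (1 - 0.26)^3, tolerance = 1e-14)
})

test_that("degenerate chains stay put", {
  # zero acceptance everywhere: the chain never moves
  cfg <- italy_fixture(acceptance_rate = 0)
  ch <- chain_init(cfg)
  for (i in 1:3) ch <- evolve(cfg, ch)
  expect_length(ch$probs, 1)
  expect_equal(ch$probs, 1)
  expect_identical(ch$states[[1]], initial_state(cfg))
  # one slot, certain acceptance: a one-state chain
  cfg1 <- single_center_config(1)
  ch <- evolve(cfg1, chain_init(cfg1))
  expect_length(ch$probs, 1)
})

test_that("per-organ probabilities are conserved and Prop-4-consistent", {
  for (s in c(2, 11, 23)) {
    cfg <- random_config(s)
    M <- 4
    r <- nth_probability(cfg, M)
    expect_equal(unname(rowSums(r$prob) + r$lost), rep(1, M), tolerance = 1e-12)
    for (c in r$centers) {
      # position distribution is a distribution
      expect_equal(unname(rowSums(r$T[[c]])), rep(1, M), tolerance = 1e-12)
      # P_c^t is the T-weighted sum of position-conditional probabilities
      expect_equal(unname(rowSums(r$T[[c]] * r$Pcj[[c]])),
                   unname(r$prob[, c]), tolerance = 1e-12)
    }
  }
})

test_that("raising a centre's acceptance rate cannot lower its organ-1 probability", {
  for (s in c(5, 6, 7)) {
    cfg <- random_config(s)
    target <- names(cfg$centers)[1]
    p1 <- nth_probability(cfg, 1)$prob[1, target]
    cfg$centers[[target]]$acceptance_rate <-
      min(1, cfg$centers[[target]]$acceptance_rate + 0.3)
    p2 <- nth_probability(cfg, 1)$prob[1, target]
    expect_gte(p2, p1 - 1e-14)
  }
})

test_that("deterministic round-robin concentrates each organ on one centre", {
  cfg <- italy_fixture(acceptance_rate = 1, production = c("Valle d'Aosta" = 1L))
  r <- nth_probability(cfg, 8)
  expect_equal(unname(apply(r$prob, 1, max)), rep(1, 8))
  expect_identical(unname(apply(r$prob[1:4, ], 1, which.max)),
                   match(c("Piemonte", "Emilia Romagna", "Toscana", "NITp"),
                         colnames(r$prob)))
  expect_equal(r$lost, rep(0, 8))
})

test_that("the chain matches brute-force path enumeration to 1e-12", {
  for (s in c(1, 8, 31)) {
    cfg <- random_config(s, n_centers = c(1, 2), max_slots = 1,
                         n_extra_regions = c(0, 1), n_producers = 2)
    M <- 3
    orc <- oracle_enumerate(cfg, M)
    r <- nth_probability(cfg, M)
    expect_equal(unname(r$prob), unname(orc$prob[, r$centers, drop = FALSE]),
                 tolerance = 1e-12)
    expect_equal(r$lost, orc$lost, tolerance = 1e-12)
  }
})

test_that("per-organ probabilities converge to a plateau", {
  cfg <- italy_fixture()
  r <- nth_probability(cfg, 40)
  step_change <- sapply(c(10, 20, 40), function(t) max(abs(r$prob[t, ] - r$prob[t - 1, ])))
  expect_true(all(diff(step_change) < 0))  # geometric decay towards the plateau
  expect_lt(step_change[3], 1e-6)
  # the chain's joint-state support is finite (48 arrangements for Italy)
  ch <- chain_init(cfg)
  for (i in 1:12) ch <- evolve(cfg, ch)
  expect_lte(length(ch$probs), 48)
  expect_equal(sum(ch$probs), 1, tolerance = 1e-12)
})

test_that("the use probability matches its macroarea decomposition", {
  # closed form for two centres: donor in MA1's no-centre region
  cfg <- two_center_config(0.3, 0.7)
  expect_equal(overall_use_probability(cfg), 1 - (1 - 0.3) * (1 - 0.7),
               tolerance = 1e-14)
  # certain acceptance with >= 2 centres; certain refusal
  expect_equal(overall_use_probability(italy_fixture(acceptance_rate = 1)), 1)
  expect_equal(overall_use_probability(italy_fixture(acceptance_rate = 0)), 0)
  # decomposition vs 1 - P_lost on random configurations
  for (s in c(4, 14, 44)) {
    cfg <- random_config(s)
    expect_equal(overall_use_probability(cfg),
                 use_probability_decomposition(cfg), tolerance = 1e-12)
  }
})
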