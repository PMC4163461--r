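test_that("odds primitives match hand arithmetic and round-trip", {
  expect_equal(prior_odds(0.5), 1)
  expect_equal(prior_odds(0.02), 0.02 / 0.98)
  expect_error(prior_odds(1), "strictly inside")
  expect_error(prior_odds(0), "strictly inside")
  expect_equal(posterior_odds(1, c(2, 3)), 6)
  expect_equal(posterior_odds(prior_odds(0.02), 200), 200 * 0.02 / 0.98)
  expect_equal(posterior_odds(2), 2)  # empty likelihood product
  expect_error(posterior_odds(1, c(2, -1)), "nonnegative")
  expect_equal(posterior_prob_certain(1), 0.5)
  expect_equal(posterior_prob_certain(0), 0)
  expect_equal(posterior_prob_certain(posterior_odds(prior_odds(0.02), 200)),
               0.8032128514, tolerance = 1e-9)
  for (p in seq(0.001, 0.999, by = 0.007))
    expect_equal(posterior_prob_certain(prior_odds(p)), p, tolerance = 1e-12)
})

test_that("uncertain-evidence interpolation hits its three anchors continuously", {
  cases <- expand.grid(p_h = c(0.02, 0.3, 0.7), p_x = c(0.1, 0.5, 0.9))
  for (i in seq_len(nrow(cases))) {
    p_h <- cases$p_h[i]; p_x <- cases$p_x[i]
    p_hx <- posterior_prob_certain(posterior_odds(prior_odds(p_h), 200))
    p_hxp <- posterior_prob_certain(posterior_odds(prior_odds(p_h), 0.01))
    f <- function(pe) posterior_prob_uncertain(p_h, p_hx, p_hxp, p_x, pe)
    expect_equal(f(0), p_hxp)
    expect_equal(f(p_x), p_h)
    expect_equal(f(1), p_hx)
    # continuity at the junction and everywhere on a fine grid
    eps <- 1e-9
    expect_equal(f(p_x - eps), f(p_x + eps), tolerance = 1e-6)
    grid <- seq(0, 1, length.out = 401)
    vals <- vapply(grid, f, numeric(1))
    slope <- max(abs(p_hx - p_h) / (1 - p_x), abs(p_h - p_hxp) / p_x)
    expect_lt(max(abs(diff(vals))), slope / 400 + 1e-12)
    # monotone when LS pulls up and LN pushes down
    expect_true(all(diff(vals) >= -1e-12))
  }
  expect_error(posterior_prob_uncertain(0.1, 0.9, 0.01, 1, 0.5), "p_x")
  expect_error(posterior_prob_uncertain(0.1, 0.9, 0.01, 0, 0.5), "p_x")
})

test_that("logic combination is min/max with conjunction below disjunction", {
  expect_equal(combine_conjunction(c(0.3, 0.7)), 0.3)
  expect_equal(combine_disjunction(c(0.3, 0.7)), 0.7)
  expect_equal(combine_conjunction(0.42), 0.42)
  expect_error(combine_conjunction(numeric()), "empty")
  expect_error(combine_disjunction(numeric()), "empty")
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:6, 1))
    expect_lte(combine_conjunction(p), combine_disjunction(p))
  }
})

test_that("propagation matches the standalone equation oracle exhaustively", {
  cfg <- quantify_config()
  # one-stage conjunction + disjunction, and a two-stage chain: 6 evidences
  net <- build_net(c(
    "forall p. E1a(p) & E2a(p) -> H1(p)",
    "forall p. E3a(p) | E4a(p) -> H2(p)",
    "forall p. E5a(p) & E6a(p) & H1(p) -> H3(p)"))
  net <- assign_poi_params(net, cfg)
  hyps <- list(
    list(name = "H1", prior = 0.02, ls = 200, ln = 0.01, op = "and",
         antecedents = c("E1a", "E2a")),
    list(name = "H2", prior = 0.02, ls = 200, ln = 0.01, op = "or",
         antecedents = c("E3a", "E4a")),
    list(name = "H3", prior = 0.02, ls = 200, ln = 0.01, op = "and",
         antecedents = c("E5a", "E6a", "H1")))
  for (mask in 0:63) {
    bits <- as.numeric(intToBits(mask)[1:6])
    grades <- setNames(bits, paste0("E", 1:6, "a"))
    res <- propagate(net, crisp_evidence(grades, cfg), cfg)
    expected <- oracle_propagate(hyps, as.list(grades),
                                 ev_prior = cfg$symptom_prior)
    expect_equal(res$posteriors[names(expected)], expected, tolerance = 1e-12)
  }
})

test_that("oracle agreement extends to fractional membership grades", {
  cfg <- quantify_config()
  net <- assign_poi_params(build_net(c(
    "forall p. E1a(p) & E2a(p) -> H1(p)",
    "forall p. E3a(p) & H1(p) -> H2(p)")), cfg)
  hyps <- list(
    list(name = "H1", prior = 0.02, ls = 200, ln = 0.01, op = "and",
         antecedents = c("E1a", "E2a")),
    list(name = "H2", prior = 0.02, ls = 200, ln = 0.01, op = "and",
         antecedents = c("E3a", "H1")))
  set.seed(77)
  for (i in 1:100) {
    grades <- setNames(runif(3), c("E1a", "E2a", "E3a"))
    res <- propagate(net, crisp_evidence(grades, cfg), cfg)
    expected <- oracle_propagate(hyps, as.list(grades),
                                 ev_prior = cfg$symptom_prior)
    expect_equal(res$posteriors[names(expected)], expected, tolerance = 1e-12)
  }
})

test_that("unknown evidence leaves posteriors at their priors", {
  net <- assign_poi_params(default_net())
  q <- quantify_record(net, patient_record(numeric()))
  res <- propagate(q$net, q$evidence)
  expect_true(all(res$posteriors == 0.02))
  expect_true(all(vapply(res$trace, `[[`, "", "branch") == "unknown"))
})

test_that("with all likelihoods 1 the net is inert", {
  cfg <- quantify_config(poi_ls = 1, poi_ln = 1, alpha = 1, beta = 1)
  net <- assign_poi_params(build_net(c(
    "forall p. E1a(p) & E2a(p) -> H1(p)",
    "forall p. E3a(p) & H1(p) -> H2(p)")), cfg)
  set.seed(3)
  for (i in 1:20) {
    grades <- setNames(runif(3), c("E1a", "E2a", "E3a"))
    # alpha=beta=1 still scales by the grade; pin likelihoods to exactly 1
    ev <- crisp_evidence(grades, cfg)
    for (nm in names(ev)) { ev[[nm]]$ls <- 1; ev[[nm]]$ln <- 1 }
    res <- propagate(net, ev, cfg)
    expect_equal(unname(res$posteriors), c(0.02, 0.02), tolerance = 1e-12)
  }
})

test_that("single-symptom hypotheses use the symptom's dynamic likelihoods", {
  cfg <- quantify_config()
  net <- assign_poi_params(build_net("forall p. E1a(p) -> H1(p)"), cfg)
  # certainly-present evidence: rule 1 gives LS = 100 * 1
  res <- propagate(net, crisp_evidence(c(E1a = 1), cfg), cfg)
  expect_equal(unname(res$posteriors["H1"]),
               posterior_prob_certain(100 * prior_odds(0.02)), tolerance = 1e-12)
  # certainly-absent evidence with a configured node LN of 0.01
  ev <- crisp_evidence(c(E1a = 0), cfg)
  ev[["E1a"]]$ln <- 0.01
  res0 <- propagate(net, ev, cfg)
  expect_equal(unname(res0$posteriors["H1"]),
               posterior_prob_certain(0.01 * prior_odds(0.02)),
               tolerance = 1e-9)
  expect_equal(unname(res0$posteriors["H1"]), 0.000204, tolerance = 1e-3)
})

test_that("posterior responds monotonically to the evidence grade", {
  cfg <- quantify_config()
  net <- assign_poi_params(build_net("forall p. E1a(p) & E2a(p) -> H1(p)"), cfg)
  post <- vapply(seq(0, 1, by = 0.05), function(g) {
    propagate(net, crisp_evidence(c(E1a = g, E2a = 1), cfg), cfg)$posteriors[["H1"]]
  }, numeric(1))
  expect_true(all(diff(post) >= -1e-12))
  expect_gt(post[length(post)], post[1])
})

test_that("traces replay bit-for-bit and explanations trace to the symptoms", {
  net <- default_net()
  rec <- table2_fixture()
  res <- diagnose(net, rec)
  expect_identical(res$ranking[1], "HT")
  expect_equal(res$posteriors[["HT"]],
               posterior_prob_certain(200 * prior_odds(0.02)), tolerance = 1e-12)
  for (h in names(res$trace))
    expect_identical(replay_trace_entry(res$trace[[h]]), res$posteriors[[h]])
  txt <- explain(res, "HT", net)
  expect_true(any(grepl("SPa: grade 1", txt)))
  expect_true(any(grepl("certain_true", txt)))
  expect_error(explain(res, "NotAHypothesis"), "unknown hypothesis")
  # a hypothesis with all-unknown evidence explains as a retained prior
  txt2 <- explain(res, "Low_BE", net)
  expect_true(grepl("prior retained", txt2[1]))
})

test_that("propagation refuses an unquantified net", {
  net <- build_net("forall p. E1a(p) -> H1(p)")
  expect_error(propagate(net, crisp_evidence(c(E1a = 1))), "unquantified")
})
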