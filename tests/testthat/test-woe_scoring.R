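test_that("criterion scoring follows the published aspect-ratio rule", {
  expect_equal(score_physchem(list(aspect_ratio = "1:5")), 100)
  expect_equal(score_physchem(list(aspect_ratio = "1:1")), 25)
  expect_equal(score_physchem(list(aspect_ratio = 5)), 100)
  # mean over several scoreable criteria
  expect_equal(
    score_physchem(list(aspect_ratio = "1:4", particle_size = ">100")),
    62.5
  )
  # criteria without a rule or without data are excluded, never imputed
  expect_equal(
    score_physchem(list(aspect_ratio = "1:4", crystallinity = "anatase",
                        particle_size = NA)),
    100
  )
  expect_error(score_physchem(list(crystallinity = "anatase")),
               "unscorable")
})

test_that("toxicity index is the class-score dot product", {
  expect_equal(score_toxicity(c(0, 0, 0, 0, 1)), 100)
  expect_equal(score_toxicity(c(1, 0, 0, 0, 0)), 0)
  expect_equal(score_toxicity(c(0, 0, 0, 0.5, 0.5)), 87.50)
  expect_error(score_toxicity(c(0.4, 0.4, 0, 0, 0)), "sum to 1")
  expect_error(score_toxicity(c(0, 0, 0, 0, 1), class_scores = c(0, 50, 25, 75, 100)),
               "nondecreasing")
})

test_that("aggregation is the published weighted sum", {
  w <- aggregation_weights(0.3, 0.7)
  expect_equal(aggregate_loe(41.67, 87.50, w), 73.75, tolerance = 0.02 / 73.75)
  expect_equal(aggregate_loe(50.00, 75.00, w), 67.50, tolerance = 0.02 / 67.5)
  expect_equal(aggregate_loe(42, 42, w), 42)
  expect_error(aggregation_weights(0.6, 0.4), "smaller")
  expect_error(aggregate_loe(50, 60, c(0.5, 0.6)), "sum to 1")
})

test_that("aggregation weights are recoverable from printed index columns", {
  # exact recovery when rows were built with a known weight
  a_true <- 0.5
  sp <- c(20, 80, 45); st <- c(60, 10, 90)
  t <- evidence_table(data.frame(
    loe_id = 1:3, nm = "X", s_pchem = sp, s_tox = st,
    s_total = a_true * sp + (1 - a_true) * st, w = c(0.5, 0.5, 0.5)
  ), check_precomputed = FALSE)
  expect_equal(fit_aggregation_weights(t)$w_pchem, 0.5)

  # recovery within +-0.01 under rounding-scale noise
  set.seed(4)
  ok <- replicate(20, {
    sp <- runif(12, 0, 100); st <- runif(12, 0, 100)
    s <- 0.3 * sp + 0.7 * st + rnorm(12, 0, 0.005)
    tt <- evidence_table(data.frame(loe_id = 1:12, nm = "X", s_pchem = sp,
                                    s_tox = st, s_total = s),
                         check_precomputed = FALSE)
    abs(fit_aggregation_weights(tt)$w_pchem - 0.3) < 0.01
  })
  expect_true(all(ok))

  # published table: weights print as 0.30/0.70 with tiny residuals
  fit <- fit_aggregation_weights(tio2_fixture())
  expect_equal(fit$w_pchem, 0.30, tolerance = 0.005 / 0.3)
  expect_lt(fit$max_residual, 0.02)

  degen <- evidence_table(data.frame(loe_id = 1:2, nm = "X",
                                     s_pchem = c(50, 50), s_tox = c(50, 50),
                                     s_total = c(50, 50)),
                          check_precomputed = FALSE)
  expect_error(fit_aggregation_weights(degen), "degenerate")
})

test_that("weight normalization preserves order and scale-invariance", {
  t <- tio2_fixture()
  wn <- normalize_weights(t$w)
  expect_equal(sum(wn), 1)
  expect_equal(wn[1], 0.61 / 13.93)
  expect_equal(normalize_weights(rep(3, 5)), rep(0.2, 5))
  expect_equal(normalize_weights(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_equal(normalize_weights(10 * t$w), wn)
  expect_error(normalize_weights(c(0, 0)), "zero")
  expect_error(normalize_weights(c(-1, 2)), "nonnegative")
})

test_that("study-quality weights combine the four criteria", {
  expect_equal(quality_weight(list(weight_override = 0.94)), 0.94)
  expect_equal(quality_weight(list(adequacy = 1, reliability = 1,
                                   power = 1, significance = 1)), 1)
  expect_equal(quality_weight(list(adequacy = 0.8, reliability = 0.6,
                                   power = 0.4, significance = 0.6)), 0.6)
  expect_error(quality_weight(list(adequacy = 0.8, reliability = 0.6)),
               "missing quality criteria")
  # override takes precedence over criteria
  expect_equal(quality_weight(list(adequacy = 1, reliability = 1, power = 1,
                                   significance = 1, weight_override = 0.2)),
               0.2)
})

test_that("hazard score equals a hand-composed evaluation of the five steps", {
  for (seed in c(21, 22, 23)) {
    t <- make_record_table(seed, n = 4L)
    hs <- hazard_score(t)
    expect_equal(
      hs$V,
      woe_bruteforce(t, default_scoring_rules(), toxicity_class_scores(),
                     a = 0.3),
      tolerance = 1e-12
    )
    expect_equal(sum(hs$breakdown$w_norm), 1)
    expect_equal(hs$V, sum(hs$breakdown$wi))
  }
})

test_that("degenerate evidence tables score as expected", {
  one <- evidence_table(data.frame(loe_id = 1, nm = "X", s_pchem = 60,
                                   s_tox = 60, w = 0.4),
                        check_precomputed = FALSE)
  expect_equal(hazard_score(one)$V, 60)

  two <- evidence_table(data.frame(loe_id = 1:2, nm = "X",
                                   s_pchem = c(40, 80), s_tox = c(40, 80),
                                   w = c(1, 1)),
                        check_precomputed = FALSE)
  expect_equal(hazard_score(two)$V, 60)

  empty <- evidence_table(data.frame(loe_id = character(0),
                                     nm = character(0),
                                     s_pchem = numeric(0)))
  expect_error(hazard_score(empty), "empty")

  # an LOE without toxicity evidence keeps its row at toxicity score 0
  t <- make_record_table(31, n = 3L)
  t[paste0("d", 1:5)][2, ] <- NA
  t <- evidence_table(as.data.frame(t), nm = attr(t, "nm"))
  expect_equal(hazard_score(t)$breakdown$s_tox[2], 0)
  expect_identical(nrow(hazard_score(t)$breakdown), 3L)
})

test_that("the hazard score is a convex, weight-scale-invariant aggregate", {
  for (seed in 41:45) {
    set.seed(seed)
    n <- sample(3:10, 1)
    t <- evidence_table(data.frame(
      loe_id = seq_len(n), nm = "X",
      s_pchem = runif(n, 0, 100), s_tox = runif(n, 0, 100),
      w = runif(n, 0.05, 1)
    ), check_precomputed = FALSE)
    hs <- hazard_score(t)
    s <- hs$breakdown$s_total
    expect_gte(hs$V, min(s))
    expect_lte(hs$V, max(s))

    t2 <- t; t2$w <- t$w / 2
    t2 <- evidence_table(as.data.frame(t2), nm = "X",
                         check_precomputed = FALSE)
    expect_equal(hazard_score(t2)$V, hs$V)

    # raising one toxicity index never lowers the score
    t3 <- t; t3$s_tox[1] <- min(100, t3$s_tox[1] + 20)
    t3 <- evidence_table(as.data.frame(t3), nm = "X",
                         check_precomputed = FALSE)
    expect_gte(hazard_score(t3)$V, hs$V)
  }
})

test_that("the three-nanomaterial comparison ranks ZnO above Ag above TiO2", {
  tabs <- synthetic_comparison_tables()
  fit <- fit_aggregation_weights(tabs$TiO2)
  v <- vapply(tabs, function(t) hazard_score(t, weights = fit)$V, numeric(1))
  expect_equal(unname(v["TiO2"]), 44.24, tolerance = 0.05 / 44.24)
  expect_equal(unname(v["Ag"]), 45.26, tolerance = 0.05 / 45.26)
  expect_equal(unname(v["ZnO"]), 52.34, tolerance = 0.05 / 52.34)
  expect_identical(names(sort(v, decreasing = TRUE)),
                   c("ZnO", "Ag", "TiO2"))
})
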