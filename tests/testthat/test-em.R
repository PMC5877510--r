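test_that("complete data yields the smoothed empirical frequencies in one step", {
  truth <- three_node_truth()
  data <- sample_net_df(truth, 500, seed = 5)
  fit <- learn_parameters_em(build_network(
    lapply(names(truth$nodes), function(v) truth$nodes[[v]]),
    rbind(c("A", "B"), c("A", "C"), c("B", "C"))
  ), data, smoothing = 1, max_iter = 5)

  # hand-computed smoothed MLE for the root node A
  counts <- table(factor(data$A, levels = c("a1", "a2", "a3")))
  expect_equal(as.numeric(fit$cpts$A),
               as.numeric((counts + 1) / sum(counts + 1)))
  # hand-computed for one conditional column of C
  sel <- data$A == "a2" & data$B == "b1"
  cc <- table(factor(data$C[sel], levels = c("c1", "c2", "c3")))
  expect_equal(as.numeric(fit$cpts$C[, "a2", "b1"]),
               as.numeric((cc + 1) / sum(cc + 1)))
  # a further EM pass does not move the complete-data fixed point
  fit2 <- learn_parameters_em(fit, data, smoothing = 1, max_iter = 5)
  expect_equal(fit2$cpts, fit$cpts, tolerance = 1e-12)
})

test_that("EM recovers the generating parameters from incomplete data", {
  truth <- three_node_truth()
  data <- sample_net_df(truth, 20000, seed = 6)
  set.seed(7)
  for (v in names(data)) data[[v]][runif(nrow(data)) < 0.2] <- NA

  fit <- learn_parameters_em(build_network(
    lapply(names(truth$nodes), function(v) truth$nodes[[v]]),
    rbind(c("A", "B"), c("A", "C"), c("B", "C"))
  ), data, smoothing = 1)

  em <- attr(fit, "em")
  expect_true(all(diff(em$log_lik) >= -1e-8))
  expect_true(em$converged)
  for (v in c("A", "B", "C")) {
    expect_lt(max(abs(fit$cpts[[v]] - truth$cpts[[v]])), 0.03)
  }
  # KL divergence of every learned CPT column from the truth is small
  kl <- function(p, q) sum(ifelse(p > 0, p * log(p / q), 0))
  for (a in 1:3) for (b in 1:2) {
    expect_lt(kl(truth$cpts$C[, a, b], fit$cpts$C[, a, b]), 0.01)
  }
})

test_that("EM degenerate inputs behave as declared", {
  truth <- three_node_truth()
  expect_error(learn_parameters_em(truth, data.frame()), "non-empty")
  expect_error(
    learn_parameters_em(truth, data.frame(A = "a9", B = "b1", C = "c1")),
    "unknown state"
  )
  # one record: the smoothing prior dominates every CPT
  one <- data.frame(A = "a1", B = "b1", C = "c2", stringsAsFactors = FALSE)
  fit <- learn_parameters_em(build_network(
    lapply(names(truth$nodes), function(v) truth$nodes[[v]]),
    rbind(c("A", "B"), c("A", "C"), c("B", "C"))
  ), one, smoothing = 1)
  expect_equal(as.numeric(fit$cpts$A), c(2, 1, 1) / 4)
  # unobserved parent columns stay uniform
  expect_equal(as.numeric(fit$cpts$C[, "a3", "b2"]), rep(1 / 3, 3))
})

test_that("prediction is exact on a deterministic system", {
  nodes <- list(node_spec("nanoparticle", c("N1", "N2"), "physchem"),
                node_spec("nm_hazard", c("None", "Low", "Medium", "High"),
                          "hazard"))
  haz <- array(c(1, 0, 0, 0, 0, 0, 0, 1), dim = c(4, 2),
               dimnames = list(nm_hazard = c("None", "Low", "Medium", "High"),
                               nanoparticle = c("N1", "N2")))
  truth <- build_network(nodes, rbind(c("nanoparticle", "nm_hazard")),
                         list(nm_hazard = haz))
  data <- sample_net_df(truth, 400, seed = 11)
  cv <- cross_validate(data, data,
                       build_network(nodes,
                                     rbind(c("nanoparticle", "nm_hazard"))),
                       smoothing = 0.01)
  expect_equal(cv$accuracy, 1.0)
  expect_identical(cv$n_unusable, 0L)
})

test_that("chance-level labels give chance-level accuracy", {
  # hazard independent of the only input, four equiprobable states
  nodes <- list(node_spec("nanoparticle", c("N1", "N2"), "physchem"),
                node_spec("nm_hazard", c("None", "Low", "Medium", "High"),
                          "hazard"))
  net <- build_network(nodes, NULL)
  set.seed(12)
  n <- 2000
  data <- data.frame(
    nanoparticle = sample(c("N1", "N2"), n, replace = TRUE),
    nm_hazard = sample(c("None", "Low", "Medium", "High"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  cv <- cross_validate(data[1:1000, ], data[1001:2000, ], net)
  se <- sqrt(0.25 * 0.75 / 1000)
  expect_lt(abs(cv$accuracy - 0.25), 4 * se)
})

test_that("ties resolve to the lowest-severity hazard state", {
  nodes <- list(node_spec("nanoparticle", c("N1", "N2"), "physchem"),
                node_spec("nm_hazard", c("None", "Low", "Medium", "High"),
                          "hazard"))
  haz <- array(rep(0.25, 4), dim = 4,
               dimnames = list(nm_hazard = c("None", "Low", "Medium", "High")))
  net <- build_network(nodes, NULL, list(nm_hazard = haz))
  pred <- predict_hazard(net, data.frame(nanoparticle = "N1",
                                         stringsAsFactors = FALSE))
  expect_identical(pred$predicted, "None")
})

test_that("records without any observed evidence are flagged, not scored", {
  net <- synthetic_ground_truth()
  test <- data.frame(nanoparticle = NA_character_,
                     particle_size = NA_character_,
                     surface_area = NA_character_,
                     study_type = NA_character_,
                     admin_route = NA_character_,
                     nm_hazard = "High", stringsAsFactors = FALSE)
  pred <- predict_hazard(net, test)
  expect_false(pred$usable)
  expect_true(is.na(pred$predicted))
})
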