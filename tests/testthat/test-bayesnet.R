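chain_net <- function(pa = c(0.3, 0.7), pb_given_a = c(0.9, 0.1, 0.2, 0.8)) {
  nodes <- list(node_spec("A", c("a0", "a1"), "physchem"),
                node_spec("B", c("b0", "b1"), "hazard"))
  cpts <- list(
    A = array(pa, dim = 2, dimnames = list(A = c("a0", "a1"))),
    B = array(pb_given_a, dim = c(2, 2),
              dimnames = list(B = c("b0", "b1"), A = c("a0", "a1")))
  )
  build_network(nodes, rbind(c("A", "B")), cpts)
}

test_that("network construction validates structure and tables", {
  spec <- default_network_spec()
  net <- build_network(spec$nodes, spec$edges)
  expect_identical(length(net$nodes), 12L)
  expect_identical(net$parents$nm_hazard,
                   setdiff(names(net$nodes), "nm_hazard"))

  nodes <- list(node_spec("A", c("x", "y"), "physchem"),
                node_spec("B", c("x", "y"), "physchem"))
  expect_error(build_network(nodes, rbind(c("A", "B"), c("B", "A"))),
               "cycle")
  expect_error(build_network(nodes, rbind(c("A", "A"))), "cycle")
  expect_error(node_spec("A", "only_one"), "at least 2")

  bad_cpt <- array(c(0.5, 0.6), dim = 2, dimnames = list(A = c("x", "y")))
  expect_error(build_network(nodes, NULL, list(A = bad_cpt)), "sum to 1")
  wrong_shape <- array(0.25, dim = c(2, 2),
                       dimnames = list(A = c("x", "y"), B = c("x", "y")))
  expect_error(build_network(nodes, NULL, list(A = wrong_shape)),
               "dimensions")
})

test_that("a two-node chain reproduces closed-form Bayes results", {
  net <- chain_net()
  # joint equals P(A) P(B|A)
  J <- joint_table(net)
  expect_equal(J["a0", "b0"], 0.3 * 0.9)
  expect_equal(J["a1", "b1"], 0.7 * 0.8)

  # prior of a root with no evidence is its CPT column
  expect_equal(as.numeric(infer_posterior(net, list(), "A")), c(0.3, 0.7))

  # posterior on A after observing B = b1, by Bayes' rule
  post <- infer_posterior(net, list(B = "b1"), "A")
  expect_equal(as.numeric(post),
               c(0.3 * 0.1, 0.7 * 0.8) / (0.3 * 0.1 + 0.7 * 0.8))
  expect_equal(attr(post, "prob_evidence"), 0.3 * 0.1 + 0.7 * 0.8)
})

test_that("variable elimination equals brute-force joint enumeration", {
  for (seed in c(101, 202, 303, 404, 505)) {
    net <- random_net(seed)
    vars <- names(net$nodes)
    set.seed(seed + 1)
    for (rep in 1:3) {
      n_ev <- sample(0:(length(vars) - 1L), 1L)
      ev_nodes <- sample(vars, n_ev)
      evidence <- lapply(ev_nodes, function(v) sample(net$nodes[[v]]$states, 1L))
      names(evidence) <- ev_nodes
      query <- sample(setdiff(vars, ev_nodes), 1L)
      got <- tryCatch(as.numeric(infer_posterior(net, evidence, query)),
                      error = function(e) e)
      want <- bf_posterior(net, evidence, query)
      if (inherits(got, "error")) {
        expect_true(all(!is.finite(want)) || anyNA(want))
      } else {
        expect_equal(got, unname(want), tolerance = 1e-9)
      }
    }
  }
})

test_that("impossible evidence raises an inconsistent-evidence error", {
  net <- chain_net(pb_given_a = c(1, 0, 1, 0))  # B = b1 has probability 0
  expect_error(infer_posterior(net, list(B = "b1"), "A"), "inconsistent")
  expect_error(infer_posterior(net, list(B = "bX"), "A"), "invalid")
  expect_error(infer_posterior(net, list(Z = "b1"), "A"), "unknown")
})

test_that("entropy handles degenerate, uniform and mixed distributions", {
  expect_equal(entropy(c(1, 0, 0, 0)), 0)
  expect_equal(entropy(rep(0.25, 4)), log(4))
  expect_equal(entropy(c(0.5, 0.5, 0, 0)), log(2))
  expect_equal(entropy(rep(0.25, 4), base = 2), 2)
  expect_error(entropy(c(0.5, 0.6)), "probability")
})

test_that("value of information is the conditional mutual information", {
  # d-separated candidate: two disconnected roots
  nodes <- list(node_spec("X", c("x0", "x1"), "physchem"),
                node_spec("T", c("t0", "t1"), "hazard"))
  net <- build_network(nodes, NULL, list(
    X = array(c(0.4, 0.6), dim = 2, dimnames = list(X = c("x0", "x1"))),
    T = array(c(0.3, 0.7), dim = 2, dimnames = list(T = c("t0", "t1")))
  ))
  voi <- value_of_information(net, "T")
  expect_identical(unname(voi["X"] <= 1e-12), TRUE)

  # deterministic copy recovers the full entropy of the target
  copy <- build_network(
    list(node_spec("T", c("t0", "t1"), "hazard"),
         node_spec("X", c("x0", "x1"), "physchem")),
    rbind(c("T", "X")),
    list(T = array(c(0.3, 0.7), dim = 2, dimnames = list(T = c("t0", "t1"))),
         X = array(c(1, 0, 0, 1), dim = c(2, 2),
                   dimnames = list(X = c("x0", "x1"), T = c("t0", "t1"))))
  )
  voi2 <- value_of_information(copy, "T")
  expect_equal(unname(voi2["X"]), entropy(c(0.3, 0.7)))

  # equals brute-force mutual information on random small networks
  for (seed in c(31, 61)) {
    net <- random_net(seed, n_nodes = 5L)
    vars <- names(net$nodes)
    target <- vars[length(vars)]
    voi <- value_of_information(net, target)
    for (x in setdiff(vars, target)) {
      expect_equal(unname(voi[x]), bf_mutual_information(net, x, target),
                   tolerance = 1e-9)
    }
    expect_true(all(voi >= 0))
    expect_false(is.unsorted(-voi))
  }

  # candidates already observed are skipped with a warning
  expect_warning(
    value_of_information(copy, "T", candidates = "X",
                         evidence = list(X = "x0")),
    "skipping"
  )
})

test_that("the normalized hazard score is the utility-weighted posterior", {
  # published TiO2 marginal: scores 34% on the uniform scale
  p <- c(None = 0.5246, Low = 0.0738, Medium = 0.2541, High = 0.1475)
  s <- normalized_hazard_score(p)
  expect_equal(as.numeric(s), 0.3415, tolerance = 0.0001 / 0.3415)
  expect_identical(attr(s, "percent"), 34)

  expect_equal(as.numeric(normalized_hazard_score(c(1, 0, 0, 0))), 0)
  expect_equal(as.numeric(normalized_hazard_score(c(0, 0, 0, 1))), 1)
  expect_error(normalized_hazard_score(c(0.5, 0.5)), "states")
  expect_error(
    normalized_hazard_score(c(A = 0.5, B = 0.2, C = 0.2, D = 0.1)),
    "match"
  )

  # linear in the posterior and bounded in [0, 1]
  set.seed(8)
  rdir <- function() { g <- rgamma(4, 1); g / sum(g) }
  for (i in 1:20) {
    p1 <- rdir(); p2 <- rdir(); lam <- runif(1)
    s1 <- as.numeric(normalized_hazard_score(p1))
    s2 <- as.numeric(normalized_hazard_score(p2))
    s12 <- as.numeric(normalized_hazard_score(lam * p1 + (1 - lam) * p2))
    expect_equal(s12, lam * s1 + (1 - lam) * s2)
    expect_gte(s1, 0); expect_lte(s1, 1)
  }
  expect_error(hazard_scale(c(0, 0.5, 0.4, 1)), "nondecreasing")
})

test_that("per-state scenario tables respond to informative evidence only", {
  net <- synthetic_ground_truth()
  st <- scenario_table(net, "NM_C", "particle_size")
  expect_identical(st$state, c("0-10", "10-50", "50-100", ">100",
                               "No Evidence"))
  # small particles push the score up relative to large ones
  expect_gt(st$score[1], st$score[4])
  # baseline matches direct inference
  base <- normalized_hazard_score(
    infer_posterior(net, list(nanoparticle = "NM_C"), "nm_hazard"))
  expect_equal(st$score[5], as.numeric(base))

  # administration route is d-separated from the hazard once the study
  # type is observed: every row equals the baseline
  st2 <- scenario_table(net, "in vivo", "admin_route",
                        nm_node = "study_type")
  expect_equal(st2$score, rep(st2$score[4], 4), tolerance = 1e-9)

  # each cell matches brute-force enumeration
  for (s in net$nodes$particle_size$states) {
    want <- sum(bf_posterior(net, list(nanoparticle = "NM_C",
                                       particle_size = s), "nm_hazard") *
                  c(0, 1 / 3, 2 / 3, 1))
    expect_equal(st$score[match(s, st$state)], unname(want),
                 tolerance = 1e-9)
  }
})

test_that("a constructed deterministic state forces the top score", {
  nodes <- list(node_spec("nanoparticle", c("NM1", "NM2"), "physchem"),
                node_spec("particle_size", c("small", "large"), "physchem"),
                node_spec("nm_hazard", c("None", "Low", "Medium", "High"),
                          "hazard"))
  haz <- array(c(0, 0, 0, 1,   # NM1, small -> certainly High
                 0.7, 0.1, 0.1, 0.1,
                 0, 0, 0, 1,
                 0.7, 0.1, 0.1, 0.1),
               dim = c(4, 2, 2),
               dimnames = list(nm_hazard = c("None", "Low", "Medium", "High"),
                               particle_size = c("small", "large"),
                               nanoparticle = c("NM1", "NM2")))
  net <- build_network(nodes,
                       rbind(c("particle_size", "nm_hazard"),
                             c("nanoparticle", "nm_hazard")),
                       list(nm_hazard = haz))
  st <- scenario_table(net, "NM1", "particle_size")
  expect_equal(st$score[st$state == "small"], 1.0)
})

test_that("networks round-trip through the plain-text serialization", {
  for (seed in c(7, 70)) {
    net <- random_net(seed)
    path <- withr::local_tempfile(fileext = ".bn")
    write_bn(net, path)
    net2 <- read_bn(path)
    expect_identical(net$order, net2$order)
    expect_setequal(names(net$nodes), names(net2$nodes))
    for (v in names(net$nodes)) {
      expect_identical(net2$nodes[[v]]$states, net$nodes[[v]]$states)
      expect_identical(net2$parents[[v]], net$parents[[v]])
      expect_equal(net2$cpts[[v]], net$cpts[[v]])
    }
  }
  net <- synthetic_ground_truth()
  path <- withr::local_tempfile(fileext = ".bn")
  write_bn(net, path)
  expect_equal(read_bn(path)$cpts$nm_hazard, net$cpts$nm_hazard)
})
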