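discretized_normal_cpt <- function(mu, k = 4L, tau = 0.6) {
  w <- exp(-(seq_len(k) - 1 - mu)^2 / (2 * tau^2))
  w / sum(w)
}

#' Ground-truth network behind the synthetic line-of-evidence database
#'
#' A six-node discrete network over nanomaterial identity, particle
#' size, surface area, study type, administration route, and a
#' four-state hazard node with all inputs as parents. The three
#' nanomaterials are constructed with well-separated hazard profiles
#' (`NM_A` low, `NM_B` intermediate, `NM_C` high): the hazard CPT places
#' a discretized-normal distribution over the ordered hazard states
#' whose location shifts with the material, towards higher hazard for
#' small particle sizes and large surface areas, and slightly higher
#' for in vivo studies. Small enough for exact enumeration, which the
#' accuracy oracle requires.
#'
#' @return A `discrete_bn`.
#' @export
synthetic_ground_truth <- function() {
  nodes <- list(
    node_spec("nanoparticle", c("NM_A", "NM_B", "NM_C"), "physchem"),
    node_spec("particle_size", c("0-10", "10-50", "50-100", ">100"),
              "physchem"),
    node_spec("surface_area", c("0-15", "15-51", ">51"), "physchem"),
    node_spec("study_type", c("in vitro", "in vivo"), "experimental"),
    node_spec("admin_route", c("oral", "inhalation", "injection"),
              "experimental"),
    node_spec("nm_hazard", c("None", "Low", "Medium", "High"), "hazard")
  )
  edges <- rbind(
    c("nanoparticle", "particle_size"),
    c("nanoparticle", "surface_area"),
    c("study_type", "admin_route"),
    c("nanoparticle", "nm_hazard"),
    c("particle_size", "nm_hazard"),
    c("surface_area", "nm_hazard"),
    c("study_type", "nm_hazard")
  )
  nm_states <- c("NM_A", "NM_B", "NM_C")
  size_states <- c("0-10", "10-50", "50-100", ">100")
  sa_states <- c("0-15", "15-51", ">51")
  st_states <- c("in vitro", "in vivo")

  cpt_nm <- array(c(1, 1, 1) / 3, dim = 3L,
                  dimnames = stats::setNames(list(nm_states),
                                             "nanoparticle"))
  cpt_size <- array(
    c(0.05, 0.25, 0.35, 0.35,   # NM_A: mostly large particles
      0.15, 0.35, 0.30, 0.20,
      0.30, 0.40, 0.20, 0.10),  # NM_C: mostly small particles
    dim = c(4L, 3L),
    dimnames = stats::setNames(list(size_states, nm_states),
                               c("particle_size", "nanoparticle")))
  cpt_sa <- array(
    c(0.50, 0.35, 0.15,
      0.35, 0.40, 0.25,
      0.20, 0.35, 0.45),
    dim = c(3L, 3L),
    dimnames = stats::setNames(list(sa_states, nm_states),
                               c("surface_area", "nanoparticle")))
  cpt_st <- array(c(0.6, 0.4), dim = 2L,
                  dimnames = stats::setNames(list(st_states), "study_type"))
  cpt_route <- array(
    c(0.50, 0.30, 0.20,
      0.40, 0.35, 0.25),
    dim = c(3L, 2L),
    dimnames = stats::setNames(list(c("oral", "inhalation", "injection"),
                                    st_states),
                               c("admin_route", "study_type")))

  base <- c(NM_A = 0.5, NM_B = 1.5, NM_C = 2.5)
  size_eff <- c(0.7, 0.2, -0.1, -0.4)
  sa_eff <- c(-0.3, 0, 0.3)
  st_eff <- c(-0.1, 0.15)
  haz <- array(0, dim = c(4L, 3L, 4L, 3L, 2L),
               dimnames = stats::setNames(
                 list(c("None", "Low", "Medium", "High"), nm_states,
                      size_states, sa_states, st_states),
                 c("nm_hazard", "nanoparticle", "particle_size",
                   "surface_area", "study_type")))
  for (a in 1:3) for (b in 1:4) for (cc in 1:3) for (d in 1:2) {
    haz[, a, b, cc, d] <- discretized_normal_cpt(
      base[a] + size_eff[b] + sa_eff[cc] + st_eff[d])
  }
  build_network(nodes, edges,
                cpts = list(nanoparticle = cpt_nm, particle_size = cpt_size,
                            surface_area = cpt_sa, study_type = cpt_st,
                            admin_route = cpt_route, nm_hazard = haz))
}

#' Configuration of the synthetic line-of-evidence generator
#'
#' Defaults emulate the screening database the analyses assume: three
#' nanomaterials at roughly 75 cases each, 20% missingness (missing
#' completely at random) on every input node except the nanomaterial
#' identity, toxicity-class likelihood vectors drawn from a Dirichlet
#' concentrated (concentration 8) on the class aligned with the true
#' hazard state, and per-criterion study-quality scores drawn from a
#' Beta(4, 2.5).
#'
#' @param net ground-truth `discrete_bn`.
#' @param n_per_nm named vector of case counts per nanomaterial state.
#' @param missingness per-node MCAR rate in `[0, 1)` applied to the
#'   maskable input nodes of the network tables.
#' @param test_fraction fraction of cases per nanomaterial held out for
#'   cross-validation.
#' @param tox_concentration Dirichlet concentration on the aligned
#'   toxicity class.
#' @param class_map index of the toxicity class aligned with each hazard
#'   state.
#' @param quality_shape1,quality_shape2 Beta parameters of the four
#'   study-quality criterion scores.
#' @param nm_node,hazard_node node names.
#' @param seed RNG seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(net = synthetic_ground_truth(),
                             n_per_nm = c(NM_A = 75, NM_B = 75, NM_C = 75),
                             missingness = 0.2,
                             test_fraction = 0.15,
                             tox_concentration = 8,
                             class_map = c(None = 1, Low = 2,
                                           Medium = 4, High = 5),
                             quality_shape1 = 4, quality_shape2 = 2.5,
                             nm_node = "nanoparticle",
                             hazard_node = "nm_hazard",
                             seed = 1L) {
  stopifnot(inherits(net, "discrete_bn"),
            all(n_per_nm >= 1), missingness >= 0, missingness < 1,
            test_fraction > 0, test_fraction < 1,
            tox_concentration > 0)
  if (!all(names(n_per_nm) %in% net$nodes[[nm_node]]$states)) {
    stop("n_per_nm names must be states of the nanomaterial node")
  }
  structure(list(net = net, n_per_nm = n_per_nm,
                 missingness = missingness, test_fraction = test_fraction,
                 tox_concentration = tox_concentration,
                 class_map = class_map,
                 quality_shape1 = quality_shape1,
                 quality_shape2 = quality_shape2,
                 nm_node = nm_node, hazard_node = hazard_node,
                 seed = seed),
            class = "generator_config")
}

maskable_nodes <- function(config) {
  setdiff(names(config$net$nodes), c(config$nm_node, config$hazard_node))
}

sample_from_net <- function(net, n, fix = list()) {
  out <- as.data.frame(matrix(NA_character_, n, length(net$nodes)),
                       stringsAsFactors = FALSE)
  names(out) <- net$order
  for (v in net$order) {
    states <- net$nodes[[v]]$states
    if (v %in% names(fix)) {
      out[[v]] <- rep(fix[[v]], n)
      next
    }
    cpt <- net$cpts[[v]]
    pars <- net$parents[[v]]
    if (length(pars) == 0L) {
      out[[v]] <- states[sample.int(length(states), n, replace = TRUE,
                                    prob = as.numeric(cpt))]
    } else {
      pidx <- vapply(pars, function(p) {
        match(out[[p]], net$nodes[[p]]$states)
      }, integer(n))
      if (n == 1L) pidx <- matrix(pidx, nrow = 1L)
      cols <- matrix(cpt, nrow = length(states))
      pdims <- vapply(net$nodes[pars], function(nd) length(nd$states),
                      integer(1))
      lin <- 1L + as.vector((pidx - 1L) %*% cumprod(c(1L, pdims))[
        seq_along(pars)])
      out[[v]] <- vapply(seq_len(n), function(i) {
        states[sample.int(length(states), 1L, prob = cols[, lin[i]])]
      }, character(1))
    }
  }
  out
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic line-of-evidence bundle
#'
#' Samples cases from the ground-truth network conditioned on each
#' nanomaterial, applies MCAR missingness to the input nodes of the
#' network tables, splits train/held-out test sets, and derives a
#' WoE-ready evidence table per nanomaterial (physico-chemical states,
#' toxicity likelihood vectors aligned with the true hazard state, and
#' study-quality criteria). The WoE tables carry the unmasked case
#' values: the evidence-base reader sees the full study, while the
#' network tables inherit database gaps. Reproducible: the same config
#' (including seed) returns the identical bundle.
#'
#' @param config a [generator_config()].
#' @return List of class `synthetic_bundle`: `woe_tables` (named list
#'   of [evidence_table()]s), `bn_train`, `bn_test` (data.frames with
#'   `NA` gaps), and `ground_truth` (`net`, `hazard_marginals`,
#'   `expected_scores`, `config`).
#' @export
generate_loe_database <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  net <- config$net
  nm_node <- config$nm_node
  hz <- config$hazard_node
  hz_states <- net$nodes[[hz]]$states
  prior_nm <- as.numeric(net$cpts[[nm_node]])
  names(prior_nm) <- net$nodes[[nm_node]]$states

  set.seed(config$seed)
  cases <- list(); woe_tables <- list()
  for (nm in names(config$n_per_nm)) {
    if (prior_nm[[nm]] <= 0) {
      stop("cannot condition on nanomaterial state '", nm,
           "' with zero prior probability")
    }
    n <- config$n_per_nm[[nm]]
    smp <- sample_from_net(net, n, fix = stats::setNames(list(nm), nm_node))
    smp$case_id <- paste0(nm, "_", seq_len(n))
    cases[[nm]] <- smp

    d <- t(vapply(smp[[hz]], function(h) {
      alpha <- rep(1, 5)
      alpha[config$class_map[[h]]] <- config$tox_concentration
      rdirichlet1(alpha)
    }, numeric(5)))
    q <- matrix(stats::rbeta(4L * n, config$quality_shape1,
                             config$quality_shape2), n, 4L)
    woe <- data.frame(
      loe_id = smp$case_id, reference = paste0("synthetic:", smp$case_id),
      nm = nm, stringsAsFactors = FALSE
    )
    for (v in maskable_nodes(config)) woe[[v]] <- smp[[v]]
    woe[paste0("d", 1:5)] <- as.data.frame(d)
    woe[c("q_adequacy", "q_reliability", "q_power", "q_significance")] <-
      as.data.frame(q)
    woe$hazard_label <- smp[[hz]]
    woe_tables[[nm]] <- evidence_table(woe, nm = nm)
  }

  all_cases <- do.call(rbind, cases)
  rownames(all_cases) <- NULL
  # held-out split, per nanomaterial
  test_idx <- unlist(lapply(names(config$n_per_nm), function(nm) {
    rows <- which(all_cases[[nm_node]] == nm)
    sample(rows, max(1L, round(config$test_fraction * length(rows))))
  }))
  bn_cols <- names(net$nodes)
  mask_mcar <- function(df) {
    for (v in maskable_nodes(config)) {
      hit <- stats::runif(nrow(df)) < config$missingness
      df[[v]][hit] <- NA_character_
    }
    df
  }
  bn_test <- mask_mcar(all_cases[test_idx, c(bn_cols, "case_id")])
  bn_train <- mask_mcar(all_cases[-test_idx, c(bn_cols, "case_id")])
  rownames(bn_test) <- rownames(bn_train) <- NULL

  marg <- t(vapply(names(config$n_per_nm), function(nm) {
    as.numeric(infer_posterior(net, stats::setNames(list(nm), nm_node), hz))
  }, numeric(length(hz_states))))
  colnames(marg) <- hz_states
  scale <- hazard_scale(states = hz_states,
                        utilities = seq(0, 1, length.out = length(hz_states)))
  expected_scores <- apply(marg, 1L, function(p) {
    as.numeric(normalized_hazard_score(p, scale))
  })
  structure(list(
    woe_tables = woe_tables, bn_train = bn_train, bn_test = bn_test,
    ground_truth = list(net = net, hazard_marginals = marg,
                        expected_scores = expected_scores,
                        config = config)
  ), class = "synthetic_bundle")
}

#' Exact expected accuracy of the Bayes-optimal hazard predictor
#'
#' Enumerates the joint distribution of the ground-truth network and
#' every missingness pattern of the maskable input nodes, and computes
#' the expected accuracy of the predictor that reports the
#' maximum-posterior hazard state given the observed inputs — the
#' ceiling against which the learned network's cross-validation
#' accuracy is judged.
#'
#' @param config a [generator_config()].
#' @param max_cells enumeration guard; beyond it an error instructs a
#'   Monte Carlo estimate instead.
#' @return Expected accuracy in \[0, 1\].
#' @export
oracle_bayes_accuracy <- function(config = generator_config(),
                                  max_cells = 1e6) {
  stopifnot(inherits(config, "generator_config"))
  net <- config$net
  dims <- vapply(net$nodes, function(nd) length(nd$states), integer(1))
  mask_vars <- maskable_nodes(config)
  if (prod(dims) * 2^length(mask_vars) > max_cells) {
    stop("enumeration too large (", prod(dims), " joint cells x 2^",
         length(mask_vars), " masks); estimate by Monte Carlo instead")
  }
  # the generator conditions on the nanomaterial with fixed counts, so
  # replace the nanomaterial prior with the design proportions
  prop <- config$n_per_nm / sum(config$n_per_nm)
  nm_states <- net$nodes[[config$nm_node]]$states
  pr <- array(0, dim = length(nm_states),
              dimnames = stats::setNames(list(nm_states), config$nm_node))
  pr[match(names(prop), nm_states)] <- prop
  net <- set_cpt(net, config$nm_node, pr)

  J <- joint_table(net)
  ord <- net$order
  pos_h <- match(config$hazard_node, ord)
  p <- config$missingness
  acc <- 0
  n_mask <- length(mask_vars)
  for (code in 0:(2^n_mask - 1)) {
    masked <- mask_vars[bitwAnd(code, 2^(seq_len(n_mask) - 1L)) > 0]
    p_mask <- p^length(masked) * (1 - p)^(n_mask - length(masked))
    if (p_mask == 0) next
    keep <- sort(c(pos_h, match(setdiff(ord, c(config$hazard_node, masked)),
                                ord)))
    M <- margin_array(J, keep)
    hdim <- match(pos_h, keep)
    perm <- c(hdim, setdiff(seq_along(keep), hdim))
    Mm <- matrix(aperm(M, perm), nrow = dims[[config$hazard_node]])
    acc <- acc + p_mask * sum(apply(Mm, 2L, max))
  }
  acc
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("Synthetic LOE bundle: %d nanomaterials, %d train / %d test network cases\n",
              length(x$woe_tables), nrow(x$bn_train), nrow(x$bn_test)))
  cat("Ground-truth expected normalized hazard scores:\n")
  print(round(x$ground_truth$expected_scores, 3))
  invisible(x)
}
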