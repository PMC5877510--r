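#' Declare a categorical network node
#'
#' @param name node name.
#' @param states ordered character vector of at least two unique states.
#' @param category one of `"physchem"`, `"experimental"`,
#'   `"biological"`, `"hazard"` — the layer the node belongs to.
#' @return Object of class `node_spec`.
#' @export
node_spec <- function(name, states,
                      category = c("physchem", "experimental",
                                   "biological", "hazard")) {
  category <- match.arg(category)
  states <- as.character(states)
  if (length(states) < 2L) stop("node '", name, "' needs at least 2 states")
  if (anyDuplicated(states)) stop("node '", name, "' has duplicate states")
  structure(list(name = name, states = states, category = category),
            class = "node_spec")
}

topo_sort <- function(nodes, parents) {
  indeg <- vapply(parents, length, integer(1))
  order <- character(0)
  avail <- names(indeg)[indeg == 0L]
  indeg_work <- indeg
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    order <- c(order, v)
    children <- names(parents)[vapply(parents, function(p) v %in% p,
                                      logical(1))]
    for (ch in children) {
      indeg_work[ch] <- indeg_work[ch] - 1L
      if (indeg_work[ch] == 0L) avail <- c(avail, ch)
    }
    parents <- lapply(parents, setdiff, v)
  }
  if (length(order) != length(nodes)) {
    stop("graph has a cycle involving: ",
         paste(setdiff(nodes, order), collapse = ", "))
  }
  order
}

uniform_cpt <- function(node, parents, state_list) {
  states <- state_list[[node]]
  pdims <- vapply(state_list[parents], length, integer(1))
  dims <- unname(c(length(states), pdims))
  dn <- c(list(states), state_list[parents])
  names(dn) <- c(node, parents)
  array(1 / length(states), dim = dims, dimnames = dn)
}

check_cpt <- function(cpt, node, parents, state_list, tol = 1e-9) {
  dn <- dimnames(cpt)
  expect_dn <- c(node, parents)
  if (!identical(names(dn), expect_dn)) {
    stop("CPT for '", node, "' must have dimensions (",
         paste(expect_dn, collapse = ", "), ")")
  }
  for (v in expect_dn) {
    if (!identical(dn[[v]], state_list[[v]])) {
      stop("CPT for '", node, "': state labels of '", v,
           "' do not match the node declaration")
    }
  }
  sums <- margin_array(cpt^0 * cpt, keep = seq_along(dim(cpt))[-1L])
  if (length(parents) == 0L) sums <- sum(cpt)
  if (any(abs(sums - 1) > tol)) {
    stop("CPT for '", node, "': columns must sum to 1")
  }
  if (any(cpt < 0)) stop("CPT for '", node, "': negative probabilities")
  invisible(cpt)
}

#' Build a discrete Bayesian network
#'
#' Assembles nodes, directed edges, and conditional probability tables
#' (CPTs) into a validated acyclic network. CPTs not supplied are
#' initialized uniform. A CPT for a node with parents is an array whose
#' first dimension indexes the node's states and remaining dimensions
#' index the parents' states; every column (fixing the parents) sums
#' to 1.
#'
#' @param nodes list of [node_spec()]s.
#' @param edges two-column matrix or data.frame of directed edges
#'   (from, to), or a list of length-2 character vectors.
#' @param cpts optional named list of CPT arrays.
#' @return Object of class `discrete_bn` with elements `nodes`,
#'   `parents`, `cpts`, `order` (a topological order).
#' @export
build_network <- function(nodes, edges = NULL, cpts = NULL) {
  if (inherits(nodes, "node_spec")) nodes <- list(nodes)
  names(nodes) <- vapply(nodes, `[[`, character(1), "name")
  node_names <- names(nodes)
  if (anyDuplicated(node_names)) stop("duplicate node names")
  state_list <- lapply(nodes, `[[`, "states")

  if (is.null(edges)) {
    edges <- matrix(character(0), ncol = 2L)
  } else if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, edges)
  } else {
    edges <- as.matrix(edges)
  }
  if (ncol(edges) != 2L && nrow(edges) > 0) stop("edges must be (from, to) pairs")
  bad <- setdiff(c(edges), node_names)
  if (length(bad)) stop("edge references unknown node(s): ",
                        paste(bad, collapse = ", "))
  if (nrow(edges) > 0 && any(edges[, 1L] == edges[, 2L])) {
    stop("graph has a cycle involving: ",
         edges[edges[, 1L] == edges[, 2L], 1L][1L])
  }
  parents <- stats::setNames(lapply(node_names, function(v) {
    unique(edges[edges[, 2L] == v, 1L])
  }), node_names)
  order <- topo_sort(node_names, parents)

  full_cpts <- stats::setNames(vector("list", length(node_names)), node_names)
  for (v in node_names) {
    if (!is.null(cpts[[v]])) {
      full_cpts[[v]] <- check_cpt(cpts[[v]], v, parents[[v]], state_list)
    } else {
      full_cpts[[v]] <- uniform_cpt(v, parents[[v]], state_list)
    }
  }
  structure(list(nodes = nodes, parents = parents, cpts = full_cpts,
                 order = order),
            class = "discrete_bn")
}

#' Replace one node's conditional probability table
#'
#' @param net a `discrete_bn`.
#' @param node node name.
#' @param cpt replacement CPT array (validated).
#' @return The updated network.
#' @export
set_cpt <- function(net, node, cpt) {
  stopifnot(inherits(net, "discrete_bn"), node %in% names(net$nodes))
  state_list <- lapply(net$nodes, `[[`, "states")
  net$cpts[[node]] <- check_cpt(cpt, node, net$parents[[node]], state_list)
  net
}

#' @export
print.discrete_bn <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  cat(sprintf("Discrete Bayesian network: %d nodes, %d edges\n",
              length(x$nodes), n_edges))
  for (v in x$order) {
    p <- x$parents[[v]]
    cat(sprintf("  %s [%s; %d states]%s\n", v, x$nodes[[v]]$category,
                length(x$nodes[[v]]$states),
                if (length(p)) paste0(" <- ", paste(p, collapse = ", "))
                else ""))
  }
  invisible(x)
}

check_evidence <- function(net, evidence) {
  if (length(evidence) == 0L) return(invisible(NULL))
  if (is.null(names(evidence)) || any(!nzchar(names(evidence)))) {
    stop("evidence must be a named list: node = state")
  }
  for (v in names(evidence)) {
    if (!v %in% names(net$nodes)) stop("unknown evidence node '", v, "'")
    if (!evidence[[v]] %in% net$nodes[[v]]$states) {
      stop("state '", evidence[[v]], "' invalid for node '", v, "'")
    }
  }
  invisible(NULL)
}

#' Joint posterior over a set of nodes by variable elimination
#'
#' Exact inference: all CPT factors are reduced by the evidence, every
#' other variable is summed out (greedy smallest-factor elimination
#' ordering), and the result is normalized. The normalization constant
#' is the probability of the evidence; zero-probability evidence raises
#' an inconsistent-evidence error.
#'
#' @param net a `discrete_bn`.
#' @param evidence named list `node = state`; omitted nodes are
#'   unobserved.
#' @param nodes nodes whose joint distribution is required.
#' @return List: `factor` (probability array over `nodes`),
#'   `prob_evidence`.
#' @export
infer_joint <- function(net, evidence = list(), nodes) {
  stopifnot(inherits(net, "discrete_bn"))
  check_evidence(net, evidence)
  nodes <- as.character(nodes)
  if (any(nodes %in% names(evidence))) {
    stop("query node(s) already fixed by evidence: ",
         paste(intersect(nodes, names(evidence)), collapse = ", "))
  }
  factors <- lapply(names(net$nodes), function(v) factor_from_cpt(net, v))
  for (v in names(evidence)) {
    factors <- lapply(factors, factor_reduce, var = v,
                      state = evidence[[v]])
  }
  elim <- setdiff(names(net$nodes), c(nodes, names(evidence)))
  factors <- eliminate_vars(factors, elim)
  res <- factor_product_list(factors)
  z <- sum(res$tab)
  if (!is.finite(z) || z <= 0) {
    stop("inconsistent evidence: zero probability under the model")
  }
  # reorder dims to the requested node order
  if (length(res$vars) > 1L) {
    res <- new_factor(nodes, aperm(res$tab, match(nodes, res$vars)))
  }
  list(factor = res$tab / z, prob_evidence = z)
}

#' Posterior distribution of a single node
#'
#' @inheritParams infer_joint
#' @param node query node (must not be in the evidence).
#' @return Named numeric vector of state probabilities (class
#'   `posterior`), with attributes `node` and `prob_evidence`.
#' @export
infer_posterior <- function(net, evidence = list(), node) {
  res <- infer_joint(net, evidence, node)
  p <- as.numeric(res$factor)
  names(p) <- net$nodes[[node]]$states
  structure(p, node = node, prob_evidence = res$prob_evidence,
            class = "posterior")
}

#' @export
print.posterior <- function(x, ...) {
  cat(sprintf("P(%s | evidence):\n", attr(x, "node")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Full joint probability table by enumeration
#'
#' Enumerates every configuration of all nodes and multiplies the CPT
#' entries (chain rule). Intended for small networks; errors beyond
#' `max_cells` configurations.
#'
#' @param net a `discrete_bn`.
#' @param max_cells guard on the table size.
#' @return Array over all nodes (in `net$order`) summing to 1.
#' @export
joint_table <- function(net, max_cells = 5e6) {
  state_list <- lapply(net$nodes, `[[`, "states")[net$order]
  dims <- vapply(state_list, length, integer(1))
  if (prod(dims) > max_cells) {
    stop("joint table would have ", prod(dims), " cells (> ", max_cells, ")")
  }
  grid <- do.call(expand.grid, c(lapply(dims, seq_len),
                                 KEEP.OUT.ATTRS = FALSE))
  names(grid) <- net$order
  p <- rep(1, nrow(grid))
  for (v in net$order) {
    idx <- as.matrix(grid[, c(v, net$parents[[v]]), drop = FALSE])
    p <- p * net$cpts[[v]][idx]
  }
  array(p, dim = dims, dimnames = state_list)
}

#' Shannon entropy of a discrete distribution
#'
#' `H = -sum(p * log(p))` with the convention `0 * log(0) = 0`.
#'
#' @param p probability vector (or `posterior`).
#' @param base logarithm base; natural log by default.
#' @return Nonnegative entropy; `log(k, base)` for a uniform
#'   distribution over `k` states.
#' @export
entropy <- function(p, base = exp(1)) {
  p <- as.numeric(p)
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-6) {
    stop("not a probability distribution")
  }
  p <- p[p > 0]
  -sum(p * log(p) / log(base))
}

#' Value-of-information analysis by entropy reduction
#'
#' For each candidate node X, computes the expected reduction in the
#' entropy of the target node from observing X:
#' `H(target | e) - sum_x P(X = x | e) * H(target | e, X = x)` — the
#' conditional mutual information between X and the target given the
#' evidence. Nonnegative; zero exactly when X is conditionally
#' independent of the target.
#'
#' @param net a `discrete_bn`.
#' @param target hypothesis node (not in the evidence).
#' @param candidates nodes to evaluate; defaults to all nodes except the
#'   target and evidence nodes. Candidates already in the evidence are
#'   skipped with a warning.
#' @param evidence named list of observed states.
#' @param base entropy log base.
#' @return Named numeric vector of entropy reductions, sorted
#'   decreasing.
#' @export
value_of_information <- function(net, target, candidates = NULL,
                                 evidence = list(), base = exp(1)) {
  stopifnot(inherits(net, "discrete_bn"))
  if (target %in% names(evidence)) stop("target must not be in the evidence")
  if (is.null(candidates)) {
    candidates <- setdiff(names(net$nodes), c(target, names(evidence)))
  }
  in_ev <- candidates %in% names(evidence)
  if (any(in_ev)) {
    warning("skipping candidate(s) already in evidence: ",
            paste(candidates[in_ev], collapse = ", "))
    candidates <- candidates[!in_ev]
  }
  h0 <- entropy(infer_posterior(net, evidence, target), base = base)
  out <- vapply(candidates, function(x) {
    joint <- infer_joint(net, evidence, c(x, target))$factor
    px <- margin_array(joint, keep = 1L)
    h_cond <- 0
    for (i in seq_along(px)) {
      if (px[i] <= 0) next
      h_cond <- h_cond + px[i] * entropy(joint[i, ] / px[i], base = base)
    }
    max(0, h0 - h_cond)
  }, numeric(1))
  sort(out, decreasing = TRUE)
}

#' Utility scale over ordered hazard states
#'
#' The default is the uniform scale (0, 1/3, 2/3, 1) over
#' (None, Low, Medium, High).
#'
#' @param utilities nondecreasing utilities with first 0 and last 1.
#' @param states state labels, one per utility.
#' @return Named numeric vector of class `hazard_scale`.
#' @export
hazard_scale <- function(utilities = c(0, 1 / 3, 2 / 3, 1),
                         states = c("None", "Low", "Medium", "High")) {
  stopifnot(length(utilities) == length(states))
  if (any(diff(utilities) < 0) || utilities[1L] != 0 ||
      utilities[length(utilities)] != 1) {
    stop("utilities must be nondecreasing from 0 to 1")
  }
  structure(stats::setNames(utilities, states), class = "hazard_scale")
}

#' Normalized hazard score from a hazard-state posterior
#'
#' Weighted sum of the posterior state probabilities and the utility
#' scale: a score in \[0, 1\], displayed as a percentage rounded to the
#' nearest integer.
#'
#' @param posterior probabilities over exactly the scale's states
#'   (named vector or `posterior` object; names, when present, must
#'   match the scale's states in order).
#' @param scale a [hazard_scale()].
#' @return Score in \[0, 1\] with attribute `percent` (rounded display
#'   value).
#' @export
normalized_hazard_score <- function(posterior, scale = hazard_scale()) {
  p <- as.numeric(posterior)
  if (length(p) != length(scale)) {
    stop("posterior has ", length(p), " states but the scale has ",
         length(scale))
  }
  nms <- names(posterior)
  if (!is.null(nms) && !identical(nms, names(scale))) {
    stop("posterior states do not match the hazard scale states")
  }
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-6) {
    stop("not a probability distribution")
  }
  score <- sum(p * as.numeric(scale))
  structure(score, percent = round(100 * score))
}

#' Per-state scenario analysis of one input node
#'
#' Fixes the nanomaterial node to `nm` and, for each state of
#' `input_node`, computes the normalized hazard score of the hazard node
#' given that additional evidence; a `No Evidence` baseline row carries
#' the score under nanomaterial evidence alone. States inconsistent with
#' the model yield `NA` cells.
#'
#' @param net a `discrete_bn`.
#' @param nm nanomaterial state for `nm_node`.
#' @param input_node node whose states are scanned.
#' @param nm_node,hazard_node node names for the nanomaterial identity
#'   and the hazard hypothesis.
#' @param scale a [hazard_scale()].
#' @return data.frame with columns `state` and `score` (\[0,1\]); the
#'   last row is the baseline.
#' @export
scenario_table <- function(net, nm, input_node, nm_node = "nanoparticle",
                           hazard_node = "nm_hazard",
                           scale = hazard_scale()) {
  stopifnot(inherits(net, "discrete_bn"),
            input_node %in% names(net$nodes))
  states <- net$nodes[[input_node]]$states
  if (length(states) < 2L) stop("input node needs at least 2 states")
  score_for <- function(ev) {
    tryCatch(
      as.numeric(normalized_hazard_score(
        infer_posterior(net, ev, hazard_node), scale)),
      error = function(e) NA_real_
    )
  }
  base_ev <- stats::setNames(list(nm), nm_node)
  rows <- vapply(states, function(s) {
    score_for(c(base_ev, stats::setNames(list(s), input_node)))
  }, numeric(1))
  data.frame(state = c(states, "No Evidence"),
             score = c(rows, score_for(base_ev)),
             stringsAsFactors = FALSE)
}

#' Default 12-node screening network specification
#'
#' The default node set mirrors the screening database header: eleven
#' input nodes (shape, nanoparticle identity, dissolution, surface area,
#' surface charge, surface coatings, surface reactivity, aggregation,
#' particle size, administration route, study type) and a four-state
#' hazard node. The default edge set is the naive design with every
#' input node a parent of the hazard node; the layered
#' biological-effects structure used in expert-built networks can be
#' declared through `build_network()` with a custom edge list, since no
#' final learned edge set is published.
#'
#' @return List with `nodes` and `edges` ready for [build_network()].
#' @export
default_network_spec <- function() {
  sch <- default_loe_schema()$categorical
  nodes <- list(
    node_spec("shape", sch$shape, "physchem"),
    node_spec("nanoparticle", c("TiO2", "Ag", "ZnO"), "physchem"),
    node_spec("dissolution", sch$dissolution, "physchem"),
    node_spec("surface_area", c("0-15", "15-51", "51-101.25",
                                "101.25-189", "189-2025"), "physchem"),
    node_spec("surface_charge", sch$surface_charge, "physchem"),
    node_spec("surface_coatings", sch$surface_coatings, "physchem"),
    node_spec("surface_reactivity", sch$surface_reactivity, "physchem"),
    node_spec("aggregation", sch$aggregation, "physchem"),
    node_spec("particle_size", sch$particle_size, "physchem"),
    node_spec("admin_route", sch$admin_route, "experimental"),
    node_spec("study_type", sch$study_type, "experimental"),
    node_spec("nm_hazard", sch$hazard_label, "hazard")
  )
  inputs <- setdiff(vapply(nodes, `[[`, character(1), "name"), "nm_hazard")
  list(nodes = nodes,
       edges = cbind(from = inputs, to = "nm_hazard"))
}
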