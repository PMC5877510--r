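# Independent oracles used across the suite. These deliberately avoid the
# package's factor algebra and scoring chain: inference is checked against
# plain enumeration of the full joint with character indexing, and the WoE
# score against a literal hand-composition of the scoring steps.

# enumerate all full assignments of a network as a data.frame of states
bf_grid <- function(net) {
  states <- lapply(net$nodes, function(nd) nd$states)
  grid <- do.call(expand.grid, c(states, stringsAsFactors = FALSE,
                                 KEEP.OUT.ATTRS = FALSE))
  names(grid) <- names(net$nodes)
  grid
}

# joint probability of each assignment by the chain rule, one CPT lookup
# at a time using state names
bf_joint_probs <- function(net, grid) {
  p <- rep(1, nrow(grid))
  for (v in names(net$nodes)) {
    pars <- net$parents[[v]]
    for (i in seq_len(nrow(grid))) {
      idx <- as.list(c(grid[i, v], unlist(grid[i, pars])))
      p[i] <- p[i] * do.call(`[`, c(list(net$cpts[[v]]), idx))
    }
  }
  p
}

bf_posterior <- function(net, evidence, node) {
  grid <- bf_grid(net)
  p <- bf_joint_probs(net, grid)
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  states <- net$nodes[[node]]$states
  out <- vapply(states, function(s) sum(p[keep & grid[[node]] == s]),
                numeric(1))
  out / sum(p[keep])
}

# conditional mutual information I(x ; target | evidence) from the joint
bf_mutual_information <- function(net, x, target, evidence = list()) {
  grid <- bf_grid(net)
  p <- bf_joint_probs(net, grid)
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  p <- p[keep] / sum(p[keep])
  grid <- grid[keep, , drop = FALSE]
  xs <- net$nodes[[x]]$states; ts <- net$nodes[[target]]$states
  mi <- 0
  for (a in xs) for (b in ts) {
    pab <- sum(p[grid[[x]] == a & grid[[target]] == b])
    pa <- sum(p[grid[[x]] == a]); pb <- sum(p[grid[[target]] == b])
    if (pab > 0) mi <- mi + pab * log(pab / (pa * pb))
  }
  mi
}

# random small network: random DAG over <=6 nodes with 2-4 states and
# Dirichlet CPT columns
random_net <- function(seed, n_nodes = NULL) {
  set.seed(seed)
  if (is.null(n_nodes)) n_nodes <- sample(3:6, 1L)
  names_v <- paste0("V", seq_len(n_nodes))
  nodes <- lapply(names_v, function(v) {
    k <- sample(2:4, 1L)
    node_spec(v, paste0(v, "_s", seq_len(k)), "physchem")
  })
  edges <- NULL
  for (i in seq_len(n_nodes - 1L)) {
    for (j in (i + 1L):n_nodes) {
      if (stats::runif(1) < 0.4) edges <- rbind(edges, c(names_v[i], names_v[j]))
    }
  }
  net <- build_network(nodes, edges)
  for (v in names_v) {
    cpt <- net$cpts[[v]]
    d <- dim(cpt)
    m <- matrix(stats::rgamma(prod(d), 1.2) + 1e-3, nrow = d[1L])
    m <- sweep(m, 2L, colSums(m), "/")
    net <- set_cpt(net, v, array(m, dim = d, dimnames = dimnames(cpt)))
  }
  net
}

# literal composition of the five scoring steps for a record-level table:
# mean criterion score, class-score dot product, weighted aggregation,
# weight normalization, weighted sum
woe_bruteforce <- function(table, rules, class_scores, a) {
  n <- nrow(table)
  V <- 0
  s_vec <- numeric(n); w_vec <- numeric(n)
  for (j in seq_len(n)) {
    scores <- c()
    for (crit in names(rules)) {
      if (!crit %in% names(table)) next
      val <- table[[crit]][j]
      if (is.na(val)) next
      r <- rules[[crit]]
      scores <- c(scores, if (identical(r$kind, "numeric")) {
        v <- if (is.character(val)) parse_aspect_ratio(val) else val
        r$scores[findInterval(v, r$breaks)]
      } else r$scores[[val]])
    }
    sp <- sum(scores) / length(scores)
    d <- as.numeric(table[j, paste0("d", 1:5)])
    st <- if (anyNA(d)) 0 else sum(class_scores * d)
    s_vec[j] <- a * sp + (1 - a) * st
    w_vec[j] <- (table$q_adequacy[j] + table$q_reliability[j] +
                   table$q_power[j] + table$q_significance[j]) / 4
  }
  for (j in seq_len(n)) V <- V + s_vec[j] * (w_vec[j] / sum(w_vec))
  V
}

# three-node network with random (seeded) non-degenerate CPTs, shared by
# the EM tests
three_node_truth <- function(seed = 99) {
  set.seed(seed)
  nodes <- list(node_spec("A", c("a1", "a2", "a3"), "physchem"),
                node_spec("B", c("b1", "b2"), "physchem"),
                node_spec("C", c("c1", "c2", "c3"), "hazard"))
  edges <- rbind(c("A", "B"), c("A", "C"), c("B", "C"))
  net <- build_network(nodes, edges)
  for (v in c("A", "B", "C")) {
    cpt <- net$cpts[[v]]; d <- dim(cpt)
    m <- matrix(stats::rgamma(prod(d), 2) + 0.05, nrow = d[1])
    m <- sweep(m, 2, colSums(m), "/")
    net <- set_cpt(net, v, array(m, dim = d, dimnames = dimnames(cpt)))
  }
  net
}

sample_net_df <- function(net, n, seed) {
  set.seed(seed)
  nanoscreen:::sample_from_net(net, n)
}

# record-level table with physchem states, toxicity vectors and quality
# criteria, for exercising the raw scoring path
make_record_table <- function(seed, n = 4L, nm = "NM_test") {
  set.seed(seed)
  sizes <- c("0-10", "10-50", "50-100", ">100")
  sas <- c("0-15", "15-51", ">51")
  d <- t(vapply(seq_len(n), function(i) {
    g <- stats::rgamma(5, c(1, 1, 1, 1, 1) + 5 * (stats::runif(5) < 0.3))
    g / sum(g)
  }, numeric(5)))
  df <- data.frame(
    loe_id = seq_len(n), nm = nm,
    particle_size = sample(sizes, n, replace = TRUE),
    surface_area = sample(sas, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  df[paste0("d", 1:5)] <- as.data.frame(d)
  df$q_adequacy <- stats::runif(n, 0.3, 1)
  df$q_reliability <- stats::runif(n, 0.3, 1)
  df$q_power <- stats::runif(n, 0.3, 1)
  df$q_significance <- stats::runif(n, 0.3, 1)
  evidence_table(df, nm = nm)
}
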