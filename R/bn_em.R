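# ---- internal helpers shared by EM and prediction ----

# collapse a categorical data.frame (NA = unobserved) into unique
# observation patterns with counts
unique_patterns <- function(data, node_names) {
  cols <- intersect(node_names, names(data))
  if (length(cols) == 0L) stop("no dataset column maps to a network node")
  d <- as.data.frame(data)[, cols, drop = FALSE]
  for (col in cols) d[[col]] <- as.character(d[[col]])
  key <- do.call(paste, c(d, sep = "\x1f"))
  first <- !duplicated(key)
  list(patterns = d[first, , drop = FALSE],
       counts = as.numeric(table(key)[key[first]]))
}

check_states_in_data <- function(net, data) {
  for (v in intersect(names(net$nodes), names(data))) {
    vals <- unique(stats::na.omit(as.character(data[[v]])))
    bad <- setdiff(vals, net$nodes[[v]]$states)
    if (length(bad)) {
      stop("unknown state(s) for node '", v, "': ",
           paste(bad, collapse = ", "))
    }
  }
  invisible(NULL)
}

normalize_cpt_counts <- function(counts) {
  d <- dim(counts)
  m <- matrix(counts, nrow = d[1L])
  cs <- colSums(m)
  zero <- cs <= 0
  if (any(zero)) m[, zero] <- 1 / d[1L]
  cs[zero] <- 1
  m <- m / rep(cs, each = d[1L])
  array(m, dim = d, dimnames = dimnames(counts))
}

# E-step over one pattern using the full joint table (small networks)
estep_joint <- function(J, net, pattern, weight, counts) {
  ord <- net$order
  idx <- lapply(ord, function(v) {
    s <- pattern[[v]]
    if (is.null(s) || is.na(s)) seq_along(net$nodes[[v]]$states)
    else match(s, net$nodes[[v]]$states)
  })
  sub <- do.call(`[`, c(list(J), idx, list(drop = FALSE)))
  pe <- sum(sub)
  if (pe <= 0) return(list(counts = counts, ll = -Inf))
  post <- sub / pe
  for (v in names(net$nodes)) {
    fam <- c(v, net$parents[[v]])
    pos <- match(fam, ord)
    keep <- sort(pos)
    m <- margin_array(post, keep)
    m <- aperm(m, match(pos, keep))  # into CPT dim order (node, parents)
    fam_idx <- idx[pos]
    cur <- do.call(`[`, c(list(counts[[v]]), fam_idx, list(drop = FALSE)))
    counts[[v]] <- do.call(`[<-`, c(list(counts[[v]]), fam_idx,
                                    list(value = cur + weight * m)))
  }
  list(counts = counts, ll = weight * log(pe))
}

# E-step over one pattern via variable elimination (large networks)
estep_ve <- function(net, pattern, weight, counts) {
  obs <- pattern[!is.na(unlist(pattern))]
  evidence <- as.list(obs)
  hidden <- setdiff(names(net$nodes), names(evidence))
  if (length(hidden)) {
    pe <- infer_joint(net, evidence, hidden[1L])$prob_evidence
  } else {
    pe <- 1
    for (v in names(net$nodes)) {
      i <- c(match(evidence[[v]], net$nodes[[v]]$states),
             vapply(net$parents[[v]], function(p) {
               match(evidence[[p]], net$nodes[[p]]$states)
             }, integer(1)))
      pe <- pe * net$cpts[[v]][matrix(i, nrow = 1L)]
    }
  }
  if (pe <= 0) return(list(counts = counts, ll = -Inf))
  for (v in names(net$nodes)) {
    fam <- c(v, net$parents[[v]])
    fam_hidden <- setdiff(fam, names(evidence))
    fam_idx <- lapply(fam, function(u) {
      if (u %in% names(evidence)) match(evidence[[u]], net$nodes[[u]]$states)
      else seq_along(net$nodes[[u]]$states)
    })
    if (length(fam_hidden) == 0L) {
      add <- 1
    } else {
      post <- infer_joint(net, evidence, fam_hidden)$factor
      fam_obs <- setdiff(fam, fam_hidden)
      dpost <- dim(post)
      if (is.null(dpost)) dpost <- length(post)
      # posterior spans the hidden dims; observed dims have length 1
      exp_post <- array(post, dim = c(dpost, rep(1L, length(fam_obs))))
      add <- aperm(exp_post, match(fam, c(fam_hidden, fam_obs)))
    }
    cur <- do.call(`[`, c(list(counts[[v]]), fam_idx, list(drop = FALSE)))
    counts[[v]] <- do.call(`[<-`, c(list(counts[[v]]), fam_idx,
                                    list(value = cur + weight * add)))
  }
  list(counts = counts, ll = weight * log(pe))
}

#' Learn conditional probability tables by expectation-maximization
#'
#' Estimates all CPTs of a fixed-structure network from categorical
#' records with missing values (`NA` = unobserved). Each E-step computes
#' exact expected family counts given the observed entries of every
#' record (records are grouped into unique observation patterns first);
#' each M-step re-normalizes the smoothed counts. The observed-data
#' log-likelihood is nondecreasing across iterations; with complete data
#' the algorithm reaches the smoothed empirical frequencies in a single
#' M-step.
#'
#' @param net a `discrete_bn` whose CPTs serve as the starting point.
#' @param data data.frame whose columns map to node names; values are
#'   state labels or `NA`.
#' @param max_iter maximum EM iterations.
#' @param tol stop when the relative log-likelihood change falls below
#'   this.
#' @param smoothing Laplace pseudo-count added to every CPT cell in the
#'   M-step (default 1).
#' @return The network with learned CPTs; attribute `em` carries
#'   `log_lik` (trace), `iterations`, `converged`.
#' @export
learn_parameters_em <- function(net, data, max_iter = 200, tol = 1e-6,
                                smoothing = 1) {
  stopifnot(inherits(net, "discrete_bn"))
  if (!is.data.frame(data) || nrow(data) == 0L) {
    stop("EM needs a non-empty data.frame")
  }
  check_states_in_data(net, data)
  up <- unique_patterns(data, names(net$nodes))
  dims <- vapply(net$nodes, function(nd) length(nd$states), integer(1))
  use_joint <- prod(dims) <= 2e5

  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    counts <- lapply(names(net$nodes), function(v) {
      net$cpts[[v]] * 0
    })
    names(counts) <- names(net$nodes)
    ll <- 0
    J <- if (use_joint) joint_table(net) else NULL
    for (i in seq_len(nrow(up$patterns))) {
      pat <- as.list(up$patterns[i, , drop = FALSE])
      res <- if (use_joint) {
        estep_joint(J, net, pat, up$counts[i], counts)
      } else {
        estep_ve(net, pat, up$counts[i], counts)
      }
      counts <- res$counts
      ll <- ll + res$ll
    }
    ll_trace <- c(ll_trace, ll)
    for (v in names(net$nodes)) {
      net$cpts[[v]] <- normalize_cpt_counts(counts[[v]] + smoothing)
    }
    if (iter > 1L) {
      prev <- ll_trace[iter - 1L]
      if (is.finite(ll) && is.finite(prev) &&
          abs(ll - prev) / (abs(prev) + 1e-12) < tol) break
    }
  }
  attr(net, "em") <- list(log_lik = ll_trace, iterations = length(ll_trace),
                          converged = length(ll_trace) < max_iter)
  net
}

#' Observed-data log-likelihood of a dataset under a network
#'
#' @param net a `discrete_bn`.
#' @param data data.frame of records (`NA` = unobserved).
#' @return Total log-likelihood of the observed entries.
#' @export
bn_log_lik <- function(net, data) {
  check_states_in_data(net, data)
  up <- unique_patterns(data, names(net$nodes))
  ll <- 0
  for (i in seq_len(nrow(up$patterns))) {
    pat <- as.list(up$patterns[i, , drop = FALSE])
    obs <- pat[!is.na(unlist(pat))]
    hidden <- setdiff(names(net$nodes), names(obs))
    pe <- if (length(hidden)) {
      infer_joint(net, obs, hidden[1L])$prob_evidence
    } else {
      f <- 1
      for (v in names(net$nodes)) {
        i2 <- c(match(obs[[v]], net$nodes[[v]]$states),
                vapply(net$parents[[v]], function(p) {
                  match(obs[[p]], net$nodes[[p]]$states)
                }, integer(1)))
        f <- f * net$cpts[[v]][matrix(i2, nrow = 1L)]
      }
      f
    }
    ll <- ll + up$counts[i] * log(pe)
  }
  ll
}

#' Predict the hazard state for each record
#'
#' Sets every observed non-hazard entry of a record as evidence,
#' computes the hazard-node posterior, and predicts the state with the
#' highest probability; ties resolve to the lowest-severity (first)
#' state. Records with no observed evidence are flagged and left
#' unpredicted.
#'
#' @param net a `discrete_bn`.
#' @param data data.frame of records.
#' @param hazard_node name of the hypothesis node.
#' @return data.frame with `predicted`, `p_predicted`,
#'   `normalized_score`, and `usable` columns, one row per record.
#' @export
predict_hazard <- function(net, data, hazard_node = "nm_hazard",
                           scale = hazard_scale()) {
  check_states_in_data(net, data)
  cols <- setdiff(intersect(names(net$nodes), names(data)), hazard_node)
  states <- net$nodes[[hazard_node]]$states
  n <- nrow(data)
  predicted <- character(n); pmax_ <- numeric(n); score <- numeric(n)
  usable <- logical(n)
  for (i in seq_len(n)) {
    row <- as.list(as.data.frame(data)[i, cols, drop = FALSE])
    ev <- row[!vapply(row, function(z) is.na(z), logical(1))]
    if (length(ev) == 0L) {
      predicted[i] <- NA_character_; pmax_[i] <- NA_real_
      score[i] <- NA_real_; usable[i] <- FALSE
      next
    }
    post <- infer_posterior(net, ev, hazard_node)
    j <- which.max(post)  # first maximum = lowest-severity tie-break
    predicted[i] <- states[j]
    pmax_[i] <- post[j]
    score[i] <- as.numeric(normalized_hazard_score(post, scale))
    usable[i] <- TRUE
  }
  data.frame(predicted = predicted, p_predicted = pmax_,
             normalized_score = score, usable = usable,
             stringsAsFactors = FALSE)
}

#' Out-of-sample cross-validation of the Bayesian network
#'
#' Learns CPTs on the training records by EM, then predicts the hazard
#' state of every held-out test record from its observed inputs and
#' compares against the recorded hazard label. Reports overall and
#' per-nanomaterial accuracy plus a per-case table (actual vs
#' predicted).
#'
#' @param train,test data.frames of records; test rows must carry the
#'   hazard label.
#' @param net a `discrete_bn` giving the structure and initial CPTs.
#' @param hazard_node,nm_node node names of the hazard hypothesis and
#'   nanomaterial identity.
#' @param scale a [hazard_scale()] for the reported normalized scores.
#' @param ... passed on to [learn_parameters_em()].
#' @return Object of class `bn_cv`: `accuracy`, `by_nm`, `cases`
#'   (per-case table), `n_unusable`, `fit` (the learned network).
#' @export
cross_validate <- function(train, test, net, hazard_node = "nm_hazard",
                           nm_node = "nanoparticle",
                           scale = hazard_scale(), ...) {
  if (!hazard_node %in% names(test) || all(is.na(test[[hazard_node]]))) {
    stop("test records must carry observed hazard labels")
  }
  fit <- learn_parameters_em(net, train, ...)
  pred <- predict_hazard(fit, test, hazard_node = hazard_node,
                         scale = scale)
  actual <- as.character(test[[hazard_node]])
  cases <- data.frame(
    case = seq_len(nrow(test)),
    nm = if (nm_node %in% names(test)) as.character(test[[nm_node]])
         else NA_character_,
    actual = actual, predicted = pred$predicted,
    correct = !is.na(pred$predicted) & pred$predicted == actual,
    p_predicted = pred$p_predicted, usable = pred$usable,
    stringsAsFactors = FALSE
  )
  ok <- cases$usable & !is.na(actual)
  accuracy <- mean(cases$correct[ok])
  by_nm <- if (!all(is.na(cases$nm))) {
    tapply(cases$correct[ok], cases$nm[ok], mean)
  } else NULL
  structure(list(accuracy = accuracy, by_nm = by_nm, cases = cases,
                 n_unusable = sum(!cases$usable), fit = fit),
            class = "bn_cv")
}

#' @export
print.bn_cv <- function(x, ...) {
  cat(sprintf("BN cross-validation: %.1f%% accuracy over %d usable cases (%d unusable)\n",
              100 * x$accuracy, sum(x$cases$usable), x$n_unusable))
  if (!is.null(x$by_nm)) {
    for (nm in names(x$by_nm)) {
      cat(sprintf("  %s: %.1f%%\n", nm, 100 * x$by_nm[[nm]]))
    }
  }
  invisible(x)
}
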