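#' Monte Carlo sampling scenario for WoE uncertainty analysis
#'
#' A scenario flags which of the three input quantities of the scoring
#' chain are treated as uncertain: the per-LOE physico-chemical index,
#' the per-LOE toxicity index, and the per-LOE study-quality weight.
#' Flagged quantities are redrawn independently per LOE and iteration,
#' uniformly over the full normalization range (indices on \[0,100\],
#' weights on \[0,1\] by default); unflagged quantities keep their
#' observed values. Weights are renormalized after perturbation.
#'
#' @param vary_pchem,vary_tox,vary_weights logical flags; at least one
#'   must be set.
#' @param n_iter number of iterations (default 10000).
#' @param seed RNG seed for reproducibility.
#' @param ranges list with elements `pchem`, `tox` (sub-ranges of
#'   \[0,100\]) and `w` (sub-range of \[0,1\]).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(vary_pchem = FALSE, vary_tox = FALSE,
                          vary_weights = FALSE, n_iter = 10000,
                          seed = NULL,
                          ranges = list(pchem = c(0, 100),
                                        tox = c(0, 100),
                                        w = c(0, 1))) {
  if (!any(vary_pchem, vary_tox, vary_weights)) {
    stop("at least one vary flag must be set")
  }
  n_iter <- as.integer(n_iter)
  if (is.na(n_iter) || n_iter < 1L) stop("n_iter must be a positive integer")
  stopifnot(all(ranges$pchem >= 0 & ranges$pchem <= 100),
            all(ranges$tox >= 0 & ranges$tox <= 100),
            all(ranges$w >= 0 & ranges$w <= 1),
            diff(ranges$pchem) >= 0, diff(ranges$tox) >= 0,
            diff(ranges$w) >= 0)
  structure(list(vary_pchem = vary_pchem, vary_tox = vary_tox,
                 vary_weights = vary_weights, n_iter = n_iter,
                 seed = seed, ranges = ranges),
            class = "scenario_spec")
}

#' The four published sampling scenarios
#'
#' Convenience constructor for the standard designs: (i) vary the
#' physico-chemical index only, (ii) the toxicity index only, (iii) the
#' study-quality weights only, (iv) all three simultaneously.
#'
#' @param n_iter iterations per scenario.
#' @param seed base seed; scenario k uses `seed + k - 1`.
#' @return Named list of four [scenario_spec()]s
#'   (`pchem`, `tox`, `weights`, `all`).
#' @export
standard_scenarios <- function(n_iter = 10000, seed = 1L) {
  list(
    pchem   = scenario_spec(vary_pchem = TRUE, n_iter = n_iter, seed = seed),
    tox     = scenario_spec(vary_tox = TRUE, n_iter = n_iter, seed = seed + 1L),
    weights = scenario_spec(vary_weights = TRUE, n_iter = n_iter,
                            seed = seed + 2L),
    all     = scenario_spec(vary_pchem = TRUE, vary_tox = TRUE,
                            vary_weights = TRUE, n_iter = n_iter,
                            seed = seed + 3L)
  )
}

mc_base_columns <- function(table, weights, ...) {
  hs <- hazard_score(table, weights = weights, ...)
  list(sp = hs$breakdown$s_pchem, st = hs$breakdown$s_tox,
       w = hs$breakdown$w, V = hs$V)
}

runif_range <- function(n, range) {
  if (diff(range) == 0) rep(range[1L], n) else stats::runif(n, range[1L], range[2L])
}

#' Perturb an evidence table once according to a sampling scenario
#'
#' Replaces the flagged per-LOE quantities with fresh uniform draws over
#' their scenario ranges, holding the others constant, and returns the
#' perturbed table with precomputed index columns. Draws come from the
#' current RNG state; seed externally for reproducibility.
#'
#' @param table an [evidence_table()].
#' @param spec a [scenario_spec()] (its `seed`/`n_iter` are ignored here).
#' @param weights aggregation weights used to recompute `s_total`.
#' @return A perturbed [evidence_table()] with columns `s_pchem`,
#'   `s_tox`, `s_total`, `w`.
#' @export
perturb_table <- function(table, spec, weights = aggregation_weights()) {
  stopifnot(inherits(spec, "scenario_spec"))
  base <- mc_base_columns(table, weights)
  n <- nrow(table)
  sp <- if (spec$vary_pchem) runif_range(n, spec$ranges$pchem) else base$sp
  st <- if (spec$vary_tox) runif_range(n, spec$ranges$tox) else base$st
  w <- if (spec$vary_weights) runif_range(n, spec$ranges$w) else base$w
  wpair <- as_weight_pair(weights)
  evidence_table(data.frame(
    loe_id = table$loe_id, nm = table$nm,
    s_pchem = sp, s_tox = st, s_total = sp * wpair[1L] + st * wpair[2L],
    w = w, stringsAsFactors = FALSE
  ), nm = attr(table, "nm"), check_precomputed = FALSE)
}

mc_samples <- function(base, spec, wpair) {
  n <- length(base$sp)
  N <- spec$n_iter
  # draw order fixed (pchem, tox, weights) so seeds are comparable
  SP <- if (spec$vary_pchem) {
    matrix(runif_range(N * n, spec$ranges$pchem), N, n)
  } else matrix(base$sp, N, n, byrow = TRUE)
  ST <- if (spec$vary_tox) {
    matrix(runif_range(N * n, spec$ranges$tox), N, n)
  } else matrix(base$st, N, n, byrow = TRUE)
  W <- if (spec$vary_weights) {
    matrix(runif_range(N * n, spec$ranges$w), N, n)
  } else matrix(base$w, N, n, byrow = TRUE)
  S <- SP * wpair[1L] + ST * wpair[2L]
  rs <- rowSums(W)
  if (any(rs <= 0)) stop("all-zero weight draw; narrow the weight range")
  rowSums(S * (W / rs))
}

#' Run one Monte Carlo sampling scenario on an evidence table
#'
#' Simulates `n_iter` independent perturbations of the table, recomputes
#' the hazard score `V'` for each, and summarizes the resulting
#' distribution by its mean, standard deviation, and average absolute
#' deviation `mean(|V' - V|)` from the observed score.
#'
#' @inheritParams perturb_table
#' @return Object of class `mc_result`: `nm`, `spec`, `V` (baseline),
#'   `samples`, `mean`, `sd`, `avg_abs_dev`.
#' @export
run_scenario <- function(table, spec, weights = aggregation_weights()) {
  stopifnot(inherits(spec, "scenario_spec"))
  base <- mc_base_columns(table, weights)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  v <- mc_samples(base, spec, as_weight_pair(weights))
  structure(list(nm = attr(table, "nm"), spec = spec, V = base$V,
                 samples = v, mean = mean(v), sd = stats::sd(v),
                 avg_abs_dev = mean(abs(v - base$V))),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  flags <- paste(c("pchem", "tox", "weights")[c(x$spec$vary_pchem,
                                                x$spec$vary_tox,
                                                x$spec$vary_weights)],
                 collapse = "+")
  cat(sprintf("MC scenario [%s] for %s: V = %.2f; mean V' = %.2f (sd %.2f), avg |V'-V| = %.2f over %d iterations\n",
              flags, x$nm, x$V, x$mean, x$sd, x$avg_abs_dev, x$spec$n_iter))
  invisible(x)
}

permutations_of <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Stability of the hazard ranking order under Monte Carlo perturbation
#'
#' For each sampling scenario, every nanomaterial's evidence table is
#' perturbed independently (one RNG substream per nanomaterial, derived
#' from the scenario seed) and scored; at each iteration the
#' nanomaterials are ranked by `V'` ascending and the resulting
#' permutation counted. Ties — a probability-zero event under continuous
#' draws — are broken by the fixed order of `tables`. Permutation rows
#' are listed in lexicographic order of the input table order, so with
#' tables in observed-rank order, row `a` is the observed ranking.
#'
#' @param tables named list of [evidence_table()]s, one per nanomaterial.
#' @param specs list of [scenario_spec()]s with equal `n_iter`.
#' @param weights aggregation weights shared by all tables.
#' @return Object of class `rank_distribution`: `orders` (permutation
#'   labels a, b, ... with their rankings) and `percent`, a matrix of
#'   percentages with one column per scenario plus an unweighted `Total`
#'   column.
#' @export
rank_stability <- function(tables, specs, weights = aggregation_weights()) {
  stopifnot(length(tables) >= 2L, !is.null(names(tables)))
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  n_iter <- unique(vapply(specs, `[[`, integer(1), "n_iter"))
  if (length(n_iter) != 1L) stop("all scenarios must share the same n_iter")
  k <- length(tables)
  perms <- permutations_of(seq_len(k))
  perm_key <- vapply(perms, paste, character(1), collapse = "-")
  labels <- letters[seq_along(perms)]
  if (is.null(names(specs))) names(specs) <- paste0("scenario_", seq_along(specs))

  wpair <- as_weight_pair(weights)
  pct <- matrix(0, nrow = length(perms), ncol = length(specs),
                dimnames = list(labels, names(specs)))
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    vmat <- matrix(NA_real_, n_iter, k)
    for (j in seq_len(k)) {
      base <- mc_base_columns(tables[[j]], weights)
      if (!is.null(spec$seed)) set.seed(spec$seed * 1000L + j)
      vmat[, j] <- mc_samples(base, spec, wpair)
    }
    obs <- apply(vmat, 1L, function(v) paste(order(v), collapse = "-"))
    counts <- table(factor(obs, levels = perm_key))
    pct[, s] <- 100 * as.numeric(counts) / n_iter
  }
  pct <- cbind(pct, Total = rowMeans(pct))
  orders <- data.frame(
    label = labels,
    order = vapply(perms, function(p) paste(names(tables)[p],
                                            collapse = " < "), character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(orders = orders, percent = pct, n_iter = n_iter),
            class = "rank_distribution")
}

#' @export
print.rank_distribution <- function(x, digits = 1, ...) {
  cat(sprintf("Hazard ranking stability over %d iterations per scenario\n",
              x$n_iter))
  out <- cbind(x$orders, round(x$percent, digits))
  print(out, row.names = FALSE)
  invisible(x)
}
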