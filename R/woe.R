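#' Default per-criterion scoring rules for physico-chemical hazard
#'
#' Each rule maps a criterion to a hazard score in \[0, 100\]. Two rule
#' kinds exist: `"numeric"` rules carry strictly increasing breakpoints
#' defining half-open bins `[low, high)` with one score per bin;
#' `"categorical"` rules carry one score per declared state.
#'
#' The aspect-ratio rule is the published one (elongation at or above
#' 3, i.e. an aspect ratio of at least 1:3, scores 100 = high hazard;
#' below 3 scores 25 = low hazard). The remaining entries are
#' package defaults for the categorical state vocabularies used by the
#' synthetic generator and are meant to be replaced by a user-supplied
#' rule set when scoring real literature data.
#'
#' @return A named list of rules (class `scoring_rules`).
#' @export
default_scoring_rules <- function() {
  rules <- list(
    aspect_ratio = list(kind = "numeric",
                        breaks = c(0, 3, Inf), scores = c(25, 100)),
    particle_size = list(kind = "categorical",
                         scores = c("0-10" = 100, "10-50" = 75,
                                    "50-100" = 50, ">100" = 25)),
    surface_area = list(kind = "categorical",
                        scores = c("0-15" = 25, "15-51" = 50,
                                   "51-101.25" = 60, "101.25-189" = 80,
                                   "189-2025" = 100, ">51" = 75)),
    dissolution = list(kind = "categorical",
                       scores = c("0-25%" = 25, "25-50%" = 50,
                                  ">50%" = 100)),
    surface_coatings = list(kind = "categorical",
                            scores = c("none" = 75, "coated" = 25)),
    surface_reactivity = list(kind = "categorical",
                              scores = c("low" = 25, "medium" = 50,
                                         "high" = 100)),
    aggregation = list(kind = "categorical",
                       scores = c("low" = 100, "medium" = 50,
                                  "high" = 25))
  )
  validate_scoring_rules(rules)
}

validate_scoring_rules <- function(rules) {
  stopifnot(is.list(rules), !is.null(names(rules)))
  for (nmc in names(rules)) {
    r <- rules[[nmc]]
    if (identical(r$kind, "numeric")) {
      if (any(diff(r$breaks) <= 0)) {
        stop("breakpoints for '", nmc, "' must be strictly increasing")
      }
      if (length(r$scores) != length(r$breaks) - 1L) {
        stop("rule '", nmc, "': need one score per bin")
      }
    } else if (identical(r$kind, "categorical")) {
      if (is.null(names(r$scores)) || any(!nzchar(names(r$scores)))) {
        stop("rule '", nmc, "': every state needs a score")
      }
    } else {
      stop("rule '", nmc, "': unknown kind")
    }
    if (any(r$scores < 0 | r$scores > 100)) {
      stop("rule '", nmc, "': scores must lie in [0,100]")
    }
  }
  structure(rules, class = "scoring_rules")
}

#' Parse an aspect ratio given as "a:b" into an elongation factor
#'
#' `"1:5"` parses to 5 (the longer axis relative to the shorter), so the
#' published threshold "aspect ratio of 1:3 or more = high hazard"
#' becomes elongation >= 3.
#'
#' @param x character vector like `"1:5"`, or numeric (returned as-is).
#' @return numeric elongation factors.
#' @export
parse_aspect_ratio <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) == 1L) return(as.numeric(p))
    ab <- as.numeric(p)
    if (anyNA(ab) || any(ab <= 0)) stop("malformed aspect ratio: ",
                                        paste(p, collapse = ":"))
    max(ab) / min(ab)
  }, numeric(1))
}

score_one_criterion <- function(value, rule) {
  if (is.na(value)) return(NA_real_)
  if (identical(rule$kind, "numeric")) {
    v <- if (is.character(value)) parse_aspect_ratio(value) else as.numeric(value)
    bin <- findInterval(v, rule$breaks, rightmost.closed = FALSE)
    if (bin < 1L || bin > length(rule$scores)) {
      stop("value ", v, " outside scored range")
    }
    unname(rule$scores[bin])
  } else {
    if (!value %in% names(rule$scores)) {
      stop("state '", value, "' has no score in rule")
    }
    unname(rule$scores[[value]])
  }
}

#' Physico-chemical LOE index
#'
#' Scores every criterion of the profile that has a rule and returns the
#' arithmetic mean of the scores, an index in \[0, 100\]. Criteria absent
#' from the profile (or recorded as missing) are excluded from the mean
#' rather than imputed.
#'
#' @param profile named list or named vector of criterion values
#'   (numeric measurements or categorical states).
#' @param rules a `scoring_rules` list, see [default_scoring_rules()].
#' @return Mean score in \[0, 100\].
#' @export
score_physchem <- function(profile, rules = default_scoring_rules()) {
  profile <- as.list(profile)
  usable <- intersect(names(profile), names(rules))
  scores <- vapply(usable, function(nmc) {
    score_one_criterion(profile[[nmc]], rules[[nmc]])
  }, numeric(1))
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) {
    stop("unscorable physico-chemical profile: no criterion has both a ",
         "value and a scoring rule")
  }
  mean(scores)
}

#' Default toxicity-class scores
#'
#' Five hazard classes of increasing evidence of human toxicity mapped
#' onto \[0, 100\]: the top class is fixed at 100 (convincing causal
#' evidence) and the grid is evenly spaced, the only even spacing
#' consistent with published toxicity indices that are all multiples of
#' 12.5.
#'
#' @return numeric vector `c(0, 25, 50, 75, 100)`.
#' @export
toxicity_class_scores <- function() c(0, 25, 50, 75, 100)

#' Toxicity LOE index
#'
#' Dot product of the class scores with the likelihood assignment: the
#' study's conclusions are split across the five classes as proportions
#' `d` summing to 1, and the index is `sum(class_scores * d)`.
#'
#' @param d numeric vector of 5 likelihoods in \[0,1\] summing to 1.
#' @param class_scores nondecreasing vector of 5 scores with last = 100.
#' @return Index in \[0, 100\].
#' @export
score_toxicity <- function(d, class_scores = toxicity_class_scores()) {
  stopifnot(length(d) == 5L, length(class_scores) == 5L)
  if (any(diff(class_scores) < 0) || class_scores[5L] != 100) {
    stop("class scores must be nondecreasing with top class fixed at 100")
  }
  if (anyNA(d) || any(d < 0 | d > 1) || abs(sum(d) - 1) > 1e-9) {
    stop("toxicity likelihoods must lie in [0,1] and sum to 1")
  }
  sum(class_scores * d)
}

#' Aggregation weights for the physico-chemical and toxicity indices
#'
#' @param w_pchem,w_tox nonnegative proportions summing to 1 with
#'   `w_pchem < w_tox` (toxicity evidence carries more weight than
#'   physico-chemical evidence).
#' @return numeric vector `c(w_pchem, w_tox)` of class
#'   `aggregation_weights`.
#' @export
aggregation_weights <- function(w_pchem = 0.3, w_tox = 0.7) {
  if (w_pchem < 0 || w_tox < 0 || abs(w_pchem + w_tox - 1) > 1e-9) {
    stop("aggregation weights must be nonnegative and sum to 1")
  }
  if (w_pchem >= w_tox) {
    stop("w_pchem must be strictly smaller than w_tox")
  }
  structure(c(w_pchem = w_pchem, w_tox = w_tox),
            class = "aggregation_weights")
}

as_weight_pair <- function(weights) {
  if (inherits(weights, "aggregation_fit")) {
    c(weights$w_pchem, weights$w_tox)
  } else if (is.numeric(weights) && length(weights) == 2L) {
    if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
      stop("aggregation weights must be nonnegative and sum to 1")
    }
    unname(weights)
  } else {
    stop("weights must be a length-2 numeric vector, aggregation_weights, ",
         "or an aggregation_fit")
  }
}

#' Aggregate the two LOE indices into a total LOE index
#'
#' Convex combination `S = s_pchem * w_pchem + s_tox * w_tox`.
#'
#' @param s_pchem,s_tox indices in \[0, 100\] (vectorized).
#' @param weights see [aggregation_weights()].
#' @return Total index, elementwise between the two inputs.
#' @export
aggregate_loe <- function(s_pchem, s_tox,
                          weights = aggregation_weights()) {
  w <- as_weight_pair(weights)
  if (any(c(s_pchem, s_tox) < 0 | c(s_pchem, s_tox) > 100, na.rm = TRUE)) {
    stop("LOE indices must lie in [0,100]")
  }
  s_pchem * w[1L] + s_tox * w[2L]
}

#' Recover the aggregation weights from a table with printed indices
#'
#' When a published table prints `s_pchem`, `s_tox` and the aggregated
#' `s_total` but not the weights, the weight on the physico-chemical
#' index is the least-squares solution of
#' `s_total = a * s_pchem + (1 - a) * s_tox`, i.e. a regression of
#' `s_total - s_tox` on `s_pchem - s_tox` through the origin.
#'
#' @param table an [evidence_table()] with the three index columns.
#' @return List of class `aggregation_fit`: `w_pchem`, `w_tox`,
#'   `residuals`, `max_residual`.
#' @export
fit_aggregation_weights <- function(table) {
  need <- c("s_pchem", "s_tox", "s_total")
  if (!all(need %in% names(table))) {
    stop("table must carry s_pchem, s_tox and s_total columns")
  }
  x <- table$s_pchem - table$s_tox
  y <- table$s_total - table$s_tox
  if (sum(abs(x) > 1e-12) < 1L || sum(x^2) == 0) {
    stop("degenerate system: need rows with distinct s_pchem and s_tox")
  }
  a <- sum(x * y) / sum(x * x)
  res <- table$s_total - (a * table$s_pchem + (1 - a) * table$s_tox)
  structure(list(w_pchem = a, w_tox = 1 - a, residuals = res,
                 max_residual = max(abs(res))),
            class = "aggregation_fit")
}

#' @export
print.aggregation_fit <- function(x, ...) {
  cat(sprintf("Aggregation weights: w_pchem = %.4f, w_tox = %.4f (max |residual| = %.4f)\n",
              x$w_pchem, x$w_tox, x$max_residual))
  invisible(x)
}

#' Normalize study-quality weights
#'
#' Divides each weight by the column total so the normalized weights sum
#' to 1; order-preserving and invariant under uniform rescaling.
#'
#' @param w nonnegative weights with a positive sum.
#' @return Normalized weights summing to 1.
#' @export
normalize_weights <- function(w) {
  if (anyNA(w) || any(w < 0)) stop("weights must be nonnegative")
  s <- sum(w)
  if (s <= 0) stop("weights must not all be zero")
  w / s
}

#' Study-quality weight of one LOE
#'
#' Combines the four regulatory data-quality criteria (adequacy,
#' reliability, statistical power, toxicological significance), each in
#' \[0,1\], into a single weight. The default combination is the
#' arithmetic mean — a declared placeholder for the full decision-rule
#' table of the originating quality-evaluation framework, whose exact
#' rules are not published; a precomputed `weight_override` passes
#' through unchanged and takes precedence.
#'
#' @param quality named numeric vector/list with entries `adequacy`,
#'   `reliability`, `power`, `significance`, or a list carrying a
#'   `weight_override` element.
#' @param logic combination rule; only `"mean"` is built in. A function
#'   `(numeric[4]) -> numeric` may be supplied for a custom rule table.
#' @return Weight in \[0, 1\].
#' @export
quality_weight <- function(quality, logic = "mean") {
  q <- as.list(quality)
  if (!is.null(q$weight_override) && !is.na(q$weight_override)) {
    w <- q$weight_override
    if (w < 0 || w > 1) stop("weight_override outside [0,1]")
    return(w)
  }
  need <- c("adequacy", "reliability", "power", "significance")
  if (!all(need %in% names(q))) {
    stop("missing quality criteria (", paste(setdiff(need, names(q)),
                                             collapse = ", "),
         ") and no weight_override")
  }
  v <- vapply(q[need], as.numeric, numeric(1))
  if (anyNA(v) || any(v < 0 | v > 1)) stop("quality criteria must lie in [0,1]")
  if (is.function(logic)) return(logic(v))
  switch(logic, mean = mean(v), stop("unknown quality logic: ", logic))
}

resolve_loe_columns <- function(table, rules, class_scores, schema) {
  n <- nrow(table)
  sp <- if ("s_pchem" %in% names(table) && !anyNA(table$s_pchem)) {
    table$s_pchem
  } else {
    crit <- intersect(names(rules), names(table))
    if (length(crit) == 0L) stop("no physico-chemical data to score")
    vapply(seq_len(n), function(i) {
      score_physchem(as.list(as.data.frame(table)[i, crit, drop = FALSE]),
                     rules)
    }, numeric(1))
  }
  st <- if ("s_tox" %in% names(table) && !anyNA(table$s_tox)) {
    table$s_tox
  } else if (all(schema$tox_cols %in% names(table))) {
    d <- as.matrix(as.data.frame(table)[, schema$tox_cols])
    vapply(seq_len(n), function(i) {
      # an LOE with no toxicity evidence keeps its row and scores 0
      if (anyNA(d[i, ])) 0 else score_toxicity(d[i, ], class_scores)
    }, numeric(1))
  } else {
    stop("no toxicity data to score (need s_tox or d1..d5 columns)")
  }
  w <- if ("w" %in% names(table) && !anyNA(table$w)) {
    table$w
  } else {
    qmap <- c(adequacy = "q_adequacy", reliability = "q_reliability",
              power = "q_power", significance = "q_significance")
    vapply(seq_len(n), function(i) {
      q <- list()
      for (k in names(qmap)) {
        if (qmap[[k]] %in% names(table)) q[[k]] <- table[[qmap[[k]]]][i]
      }
      if ("w_override" %in% names(table) && !is.na(table$w_override[i])) {
        q$weight_override <- table$w_override[i]
      }
      quality_weight(q)
    }, numeric(1))
  }
  list(s_pchem = sp, s_tox = st, w = w)
}

#' Weight-of-evidence hazard score of a nanomaterial
#'
#' Runs the full scoring chain over an evidence table: per-LOE
#' physico-chemical index (mean of criterion scores), toxicity index
#' (class-score dot product), weighted aggregation into the total LOE
#' index, normalization of the study-quality weights, and the hazard
#' score `V = sum(S_j * w'_j)` in \[0, 100\]. Tables carrying
#' precomputed index columns are scored from those columns directly.
#'
#' @param table an [evidence_table()] with at least one row.
#' @param rules scoring rules for raw physico-chemical columns.
#' @param class_scores toxicity class scores, see
#'   [toxicity_class_scores()].
#' @param weights aggregation weights (`c(w_pchem, w_tox)`, an
#'   [aggregation_weights()] object, or a [fit_aggregation_weights()]
#'   result).
#' @return Object of class `hazard_score`: `nm`, `V`, `weights`, and a
#'   per-LOE `breakdown` data.frame with columns `loe_id`, `s_pchem`,
#'   `s_tox`, `s_total`, `w`, `w_norm`, `wi`.
#' @export
hazard_score <- function(table, rules = default_scoring_rules(),
                         class_scores = toxicity_class_scores(),
                         weights = aggregation_weights(),
                         schema = default_loe_schema()) {
  stopifnot(inherits(table, "evidence_table"))
  if (nrow(table) == 0L) stop("empty evidence table")
  wpair <- as_weight_pair(weights)
  cols <- resolve_loe_columns(table, rules, class_scores, schema)
  s_total <- cols$s_pchem * wpair[1L] + cols$s_tox * wpair[2L]
  w_norm <- normalize_weights(cols$w)
  wi <- s_total * w_norm
  structure(list(
    nm = attr(table, "nm"),
    V = sum(wi),
    weights = wpair,
    breakdown = data.frame(
      loe_id = table$loe_id, s_pchem = cols$s_pchem, s_tox = cols$s_tox,
      s_total = s_total, w = cols$w, w_norm = w_norm, wi = wi,
      stringsAsFactors = FALSE
    )
  ), class = "hazard_score")
}

#' @param schema column schema used to locate raw data columns.
#' @rdname hazard_score
#' @export
print.hazard_score <- function(x, ...) {
  cat(sprintf("WoE hazard score for %s: V = %.2f over %d LOE (w_pchem = %.2f, w_tox = %.2f)\n",
              x$nm, x$V, nrow(x$breakdown), x$weights[1L], x$weights[2L]))
  invisible(x)
}
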