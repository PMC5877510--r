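#' Compare the WoE and Bayesian-network hazard rankings
#'
#' Joins the per-nanomaterial WoE hazard scores (V, on \[0,100\]) with
#' the network's normalized hazard scores (on \[0,1\]), ranks each set
#' from highest to lowest hazard, and flags whether the two frameworks
#' agree on the relative ordering.
#'
#' @param woe named numeric vector of WoE scores V, or a list of
#'   `hazard_score` objects.
#' @param bn named numeric vector of normalized network hazard scores
#'   over the same nanomaterials.
#' @return Object of class `hazard_comparison`: `table` (nm, both
#'   scores, both ranks), `woe_order` and `bn_order` (highest hazard
#'   first), `agreement`.
#' @export
compare_frameworks <- function(woe, bn) {
  if (is.list(woe) && all(vapply(woe, inherits, logical(1), "hazard_score"))) {
    woe <- stats::setNames(vapply(woe, `[[`, numeric(1), "V"),
                           vapply(woe, `[[`, character(1), "nm"))
  }
  bn <- unlist(bn)
  if (is.null(names(woe)) || is.null(names(bn))) {
    stop("both score sets must be named by nanomaterial")
  }
  common <- intersect(names(woe), names(bn))
  if (length(common) < 1L) stop("no common nanomaterials between the two score sets")
  woe <- woe[common]; bn <- bn[common]
  woe_order <- names(sort(woe, decreasing = TRUE))
  bn_order <- names(sort(bn, decreasing = TRUE))
  tab <- data.frame(
    nm = common,
    woe_V = as.numeric(woe),
    woe_rank = rank(-woe, ties.method = "first"),
    bn_score = as.numeric(bn),
    bn_rank = rank(-bn, ties.method = "first"),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, woe_order = woe_order, bn_order = bn_order,
                 agreement = identical(woe_order, bn_order)),
            class = "hazard_comparison")
}

#' @export
print.hazard_comparison <- function(x, ...) {
  cat("Comparative hazard ranking (highest hazard first)\n")
  cat("  WoE:", paste(x$woe_order, collapse = " > "), "\n")
  cat("  BN: ", paste(x$bn_order, collapse = " > "), "\n")
  cat(if (x$agreement) "  Frameworks AGREE on the ranking\n"
      else "  Frameworks DISAGREE on the ranking\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
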