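# Internal factor algebra over named categorical variables.
# A factor is list(vars = character(), tab = array with dimnames whose
# names are the variable names, in the order of `vars`).

new_factor <- function(vars, tab) {
  if (length(vars)) {
    stopifnot(identical(names(dimnames(tab)), vars))
  }
  list(vars = vars, tab = tab)
}

factor_from_cpt <- function(net, node) {
  vars <- c(node, net$parents[[node]])
  new_factor(vars, net$cpts[[node]])
}

# sum out all dims except `keep` (by position); returns array over kept
# dims in their original relative order
margin_array <- function(tab, keep) {
  d <- dim(tab)
  if (is.null(d)) d <- length(tab)
  all_idx <- seq_along(d)
  if (length(keep) == length(all_idx)) return(tab)
  if (length(keep) == 0L) return(sum(tab))
  drop_idx <- setdiff(all_idx, keep)
  perm <- c(keep, drop_idx)
  tp <- aperm(tab, perm)
  dn <- dimnames(tab)
  m <- matrix(tp, nrow = prod(d[keep]), ncol = prod(d[drop_idx]))
  out <- rowSums(m)
  array(out, dim = d[keep], dimnames = dn[keep])
}

factor_marginalize <- function(f, var) {
  pos <- match(var, f$vars)
  stopifnot(!is.na(pos))
  keep <- setdiff(seq_along(f$vars), pos)
  new_factor(f$vars[keep], margin_array(f$tab, keep))
}

# condition on var = state and drop the dimension
factor_reduce <- function(f, var, state) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  st_idx <- match(state, dimnames(f$tab)[[pos]])
  if (is.na(st_idx)) stop("state '", state, "' invalid for node '", var, "'")
  idx <- rep(list(quote(expr = )), length(f$vars))
  idx[[pos]] <- st_idx
  tab <- do.call(`[`, c(list(f$tab), idx, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), pos)
  if (length(keep) == 0L) return(new_factor(character(0), sum(tab)))
  dn <- dimnames(f$tab)[keep]
  tab <- array(tab, dim = dim(f$tab)[keep], dimnames = dn)
  new_factor(f$vars[keep], tab)
}

# expand a factor's table to span `all_vars` (with dims `all_dims`,
# a named list var -> state names)
expand_to <- function(f, all_vars, all_dims) {
  if (length(f$vars) == 0L) {
    tab <- array(as.numeric(f$tab),
                 dim = vapply(all_dims, length, integer(1)),
                 dimnames = all_dims)
    return(new_factor(all_vars, tab))
  }
  extra <- setdiff(all_vars, f$vars)
  ord_vars <- c(f$vars, extra)
  dims <- c(dim(f$tab), vapply(all_dims[extra], length, integer(1)))
  tab <- array(f$tab, dim = dims,
               dimnames = c(dimnames(f$tab), all_dims[extra]))
  perm <- match(all_vars, ord_vars)
  new_factor(all_vars, aperm(tab, perm))
}

factor_product <- function(f1, f2) {
  if (length(f1$vars) == 0L) {
    return(new_factor(f2$vars, f2$tab * as.numeric(f1$tab)))
  }
  if (length(f2$vars) == 0L) {
    return(new_factor(f1$vars, f1$tab * as.numeric(f2$tab)))
  }
  all_vars <- union(f1$vars, f2$vars)
  all_dims <- c(dimnames(f1$tab), dimnames(f2$tab))
  all_dims <- all_dims[!duplicated(names(all_dims))][all_vars]
  a <- expand_to(f1, all_vars, all_dims)
  b <- expand_to(f2, all_vars, all_dims)
  new_factor(all_vars, a$tab * b$tab)
}

factor_product_list <- function(fs) {
  Reduce(factor_product, fs)
}

# greedy variable elimination: repeatedly eliminate the variable whose
# combined factor is smallest
eliminate_vars <- function(factors, elim) {
  for (iter in seq_along(elim)) {
    remaining <- elim[!elim %in% ""]
    if (length(remaining) == 0L) break
    cost <- vapply(remaining, function(v) {
      touched <- factors[vapply(factors, function(f) v %in% f$vars,
                                logical(1))]
      vars <- unique(unlist(lapply(touched, `[[`, "vars")))
      dims <- unlist(lapply(touched, function(f) {
        stats::setNames(dim(f$tab), f$vars)
      }))
      prod(dims[!duplicated(names(dims))][vars])
    }, numeric(1))
    v <- remaining[which.min(cost)]
    hit <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (any(hit)) {
      prod_f <- factor_product_list(factors[hit])
      factors <- c(factors[!hit], list(factor_marginalize(prod_f, v)))
    }
    elim[match(v, elim)] <- ""
  }
  factors
}
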