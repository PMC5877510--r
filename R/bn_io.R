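#' Serialize a discrete Bayesian network to plain text
#'
#' One block per node in topological order:
#' ```
#' node: <name>
#' category: <category>
#' states: s1 | s2 | ...
#' parents: p1 | p2 | ...        (blank when the node is a root)
#' cpt: v1 v2 v3 ...             (flattened column-major, node dim first)
#' ```
#' Values are written at full precision so the network round-trips.
#'
#' @param net a `discrete_bn`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bn <- function(net, path) {
  stopifnot(inherits(net, "discrete_bn"))
  lines <- c("# discrete Bayesian network (nanoscreen text format v1)")
  for (v in net$order) {
    nd <- net$nodes[[v]]
    lines <- c(
      lines,
      paste0("node: ", v),
      paste0("category: ", nd$category),
      paste0("states: ", paste(nd$states, collapse = " | ")),
      paste0("parents: ", paste(net$parents[[v]], collapse = " | ")),
      paste0("cpt: ", paste(sprintf("%.17g", as.numeric(net$cpts[[v]])),
                            collapse = " ")),
      ""
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a discrete Bayesian network from the plain-text format
#'
#' @param path file written by [write_bn()].
#' @return A `discrete_bn`.
#' @export
read_bn <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  field <- function(line, key) {
    if (!startsWith(line, paste0(key, ":"))) {
      stop("expected '", key, ":' line, got: ", line)
    }
    trimws(sub(paste0("^", key, ":"), "", line))
  }
  split_bar <- function(s) {
    if (!nzchar(s)) character(0) else trimws(strsplit(s, "|", fixed = TRUE)[[1]])
  }
  nodes <- list(); parents <- list(); cpts_raw <- list()
  i <- 1L
  while (i <= length(lines)) {
    v <- field(lines[i], "node")
    cat_ <- field(lines[i + 1L], "category")
    states <- split_bar(field(lines[i + 2L], "states"))
    pars <- split_bar(field(lines[i + 3L], "parents"))
    vals <- as.numeric(strsplit(field(lines[i + 4L], "cpt"), "\\s+")[[1]])
    nodes[[v]] <- node_spec(v, states, cat_)
    parents[[v]] <- pars
    cpts_raw[[v]] <- vals
    i <- i + 5L
  }
  edges <- do.call(rbind, unlist(lapply(names(parents), function(v) {
    lapply(parents[[v]], function(p) c(p, v))
  }), recursive = FALSE))
  state_list <- lapply(nodes, `[[`, "states")
  cpts <- lapply(names(nodes), function(v) {
    dims <- unname(c(length(state_list[[v]]),
                     vapply(state_list[parents[[v]]], length, integer(1))))
    dn <- c(list(state_list[[v]]), state_list[parents[[v]]])
    names(dn) <- c(v, parents[[v]])
    array(cpts_raw[[v]], dim = dims, dimnames = dn)
  })
  names(cpts) <- names(nodes)
  build_network(unname(nodes), edges = edges, cpts = cpts)
}
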