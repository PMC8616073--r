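#' Build a tumor topology (mutation tree + antigen patterns)
#'
#' A topology couples the mutation tree of the tumor sub-clones (which clone
#' feeds which by mutation) with the binary antigen-pattern matrix `P`
#' assigning pattern components to each population. `P` has one row per
#' antigen component and one column per population (all sub-clones, then the
#' host); entry 1 means the population bears that component. The routing
#' matrix `q` has `q[child, parent] = 1` when mutation of `parent` feeds
#' `child`.
#'
#' @param patterns binary matrix, components x (clones + host). Column names
#'   are used as clone labels; the last column is the host.
#' @param parents integer vector of length `n_clones`; `parents[i]` is the
#'   index of the mutation parent of clone `i`, `NA` for the founder.
#' @return object of class `ite_topology` with elements `n_clones`,
#'   `n_components`, `P`, `q`, `parents`, `labels`, `has_child`.
#' @export
#' @examples
#' # a single clone bearing the single component, no mutation
#' build_topology(matrix(c(1, 0), 1, 2), parents = NA_integer_)
build_topology <- function(patterns, parents) {
  patterns <- as.matrix(patterns)
  if (!all(patterns %in% c(0, 1)))
    stop("antigen patterns must be binary (0/1)")
  n_clones <- ncol(patterns) - 1L
  if (n_clones < 1L)
    stop("patterns must have at least two columns (one clone + host)")
  n_comp <- nrow(patterns)
  parents <- as.integer(parents)
  if (length(parents) != n_clones)
    stop(sprintf("parents must have length %d (one per clone)", n_clones))
  if (any(parents == seq_len(n_clones), na.rm = TRUE))
    stop("mutation tree may not contain self-loops")
  # reject cycles: follow parent links from every clone
  for (i in seq_len(n_clones)) {
    seen <- logical(n_clones)
    j <- i
    while (!is.na(j)) {
      if (seen[j]) stop("mutation graph is cyclic")
      seen[j] <- TRUE
      j <- parents[j]
    }
  }
  q <- matrix(0, n_clones, n_clones)
  for (i in seq_len(n_clones))
    if (!is.na(parents[i])) q[i, parents[i]] <- 1
  labels <- colnames(patterns)
  if (is.null(labels))
    labels <- c(paste0("T", seq_len(n_clones)), "H")
  structure(list(
    n_clones = n_clones,
    n_components = n_comp,
    P = patterns,
    q = q,
    parents = parents,
    labels = labels,
    has_child = as.integer(colSums(q) > 0)
  ), class = "ite_topology")
}

#' Default nine-clone topology
#'
#' The default study topology: nine tumor sub-clones `T11..T14` (first
#' generation, branches 1-4), `T21..T24` (second generation) and `T31`
#' (third generation, branch 1), plus the host, with nine antigen-pattern
#' components. It is the package's own construction, built to satisfy the
#' constraints the model states for its reference pattern: component 1 is
#' borne by exactly the four first-generation clones `T11, T12, T13, T14`;
#' each deeper sub-clone bears one private (neo-)antigen component
#' (components 3-7); the host bears three components of its own (2, 8, 9),
#' so the host-directed effector populations behave identically to each
#' other. `T11` is the founder; `T12..T14` and `T21` arise from `T11`, and
#' each branch then deepens by one generation.
#'
#' Alternative topologies are data, not code: pass any pattern/parent
#' description to [build_topology()] or ship one in a config file.
#'
#' @return an `ite_topology` object with 9 clones and 9 components.
#' @export
#' @examples
#' topo <- default_topology()
#' topo$labels
#' rowSums(topo$P)
default_topology <- function() {
  path <- system.file("extdata", "topology_default.yaml", package = "itesim")
  topology_from_list(yaml::read_yaml(path))
}

#' Build a topology from a config-style list
#'
#' The list has one entry per population under `populations`: each gives
#' `components` (integer vector of borne antigen components) and `parent`
#' (label of the mutation parent, absent/null for the founder and the host).
#' `n_components` fixes the number of pattern rows.
#'
#' @param spec a list as read from the `[topology]` config section.
#' @return an `ite_topology` object.
#' @export
topology_from_list <- function(spec) {
  pops <- spec$populations
  if (is.null(pops) || length(pops) < 2L)
    stop("topology spec needs a 'populations' list (clones + host)")
  n_comp <- spec$n_components
  labels <- vapply(pops, function(p) as.character(p$name), character(1))
  host_idx <- which(vapply(pops, function(p) isTRUE(p$host), logical(1)))
  if (length(host_idx) != 1L)
    stop("exactly one population must be flagged 'host: true'")
  # host goes last
  ord <- c(setdiff(seq_along(pops), host_idx), host_idx)
  pops <- pops[ord]
  labels <- labels[ord]
  n_pop <- length(pops)
  P <- matrix(0, n_comp, n_pop, dimnames = list(NULL, labels))
  for (j in seq_len(n_pop)) {
    comp <- as.integer(unlist(pops[[j]]$components))
    if (any(comp < 1L | comp > n_comp))
      stop(sprintf("population '%s' bears a component outside 1..%d",
                   labels[j], n_comp))
    P[comp, j] <- 1
  }
  parents <- rep(NA_integer_, n_pop - 1L)
  for (j in seq_len(n_pop - 1L)) {
    par <- pops[[j]]$parent
    if (!is.null(par)) {
      k <- match(as.character(par), labels[seq_len(n_pop - 1L)])
      if (is.na(k))
        stop(sprintf("unknown mutation parent '%s' for '%s'", par, labels[j]))
      parents[j] <- k
    }
  }
  build_topology(P, parents)
}

#' @export
print.ite_topology <- function(x, ...) {
  cat(sprintf("<ite_topology> %d sub-clones + host, %d antigen components\n",
              x$n_clones, x$n_components))
  cat("  clones:", paste(x$labels[seq_len(x$n_clones)], collapse = " "), "\n")
  for (i in seq_len(x$n_clones)) {
    par <- if (is.na(x$parents[i])) "founder" else
      paste0("from ", x$labels[x$parents[i]])
    comp <- which(x$P[, i] == 1)
    cat(sprintf("  %-4s %-10s components {%s}\n", x$labels[i], par,
                paste(comp, collapse = ",")))
  }
  cat(sprintf("  %-4s %-10s components {%s}\n", x$labels[x$n_clones + 1L],
              "host", paste(which(x$P[, x$n_clones + 1L] == 1), collapse = ",")))
  invisible(x)
}
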