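#' Network structure over named discrete variables
#'
#' A `bn_structure` holds the directed acyclic graph of a discrete Bayesian
#' belief network: a set of named ordinal variables, each with an ordered
#' vector of state labels (state indices are 0-based and ordinal), and a set
#' of directed edges `parent -> child`.
#'
#' @param variables either a named list of character vectors of state labels
#'   (ordered; ordinal semantics, index 0..r-1), or a named integer vector of
#'   cardinalities, in which case states are labelled `"0" ... "r-1"`.
#' @param edges a two-column character matrix (or data.frame, or list of
#'   length-2 character vectors) of `c(parent, child)` pairs; may be empty.
#'
#' @return An object of class `bn_structure` with elements `vars` (named list
#'   of state labels) and `edges` (two-column character matrix with columns
#'   `from`, `to`).
#' @examples
#' s <- bn_structure(c(A = 2L, B = 3L), list(c("A", "B")))
#' validate_dag(s)$ok
#' @export
bn_structure <- function(variables, edges = NULL) {
  if (is.numeric(variables)) {
    if (is.null(names(variables)) || any(!nzchar(names(variables))))
      stop("cardinality vector must be named")
    variables <- lapply(variables, function(r) as.character(seq_len(r) - 1L))
  }
  if (!is.list(variables) || is.null(names(variables)))
    stop("'variables' must be a named list of state labels or named cardinalities")
  vn <- names(variables)
  if (anyDuplicated(vn)) stop("duplicate variable names")
  for (v in vn) {
    st <- as.character(variables[[v]])
    if (length(st) < 2L) stop("variable '", v, "' must have at least 2 states")
    if (anyDuplicated(st)) stop("variable '", v, "' has duplicate state labels")
    variables[[v]] <- st
  }
  structure(
    list(vars = variables, edges = as_edge_matrix(edges)),
    class = "bn_structure"
  )
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L) ||
      (!is.matrix(edges) && length(edges) == 0L)) {
    m <- matrix(character(0), ncol = 2L)
  } else if (is.matrix(edges) || is.data.frame(edges)) {
    m <- as.matrix(edges)
    storage.mode(m) <- "character"
  } else if (is.list(edges)) {
    if (any(lengths(edges) != 2L)) stop("each edge must be a (parent, child) pair")
    m <- matrix(unlist(lapply(edges, as.character)), ncol = 2L, byrow = TRUE)
  } else stop("cannot interpret 'edges'")
  if (ncol(m) != 2L) stop("edges must have two columns (parent, child)")
  colnames(m) <- c("from", "to")
  rownames(m) <- NULL
  m
}

#' @export
print.bn_structure <- function(x, ...) {
  cat("Discrete network structure:", length(x$vars), "variables,",
      nrow(x$edges), "edges\n")
  card <- vapply(x$vars, length, 1L)
  cat("  variables:", paste0(names(card), "(", card, ")", collapse = " "), "\n")
  if (nrow(x$edges)) {
    cat("  edges:", paste(x$edges[, 1L], "->", x$edges[, 2L], collapse = ", "),
        "\n")
  }
  invisible(x)
}

variable_names <- function(structure) names(structure$vars)

n_states <- function(structure, v) {
  lengths(structure$vars[v])
}

#' Parents and children of a variable
#'
#' @param structure a [bn_structure].
#' @param v a variable name.
#' @return Character vector of parent (child) names, in edge-declaration order.
#' @export
bn_parents <- function(structure, v) {
  unname(structure$edges[structure$edges[, 2L] == v, 1L])
}

#' @rdname bn_parents
#' @export
bn_children <- function(structure, v) {
  unname(structure$edges[structure$edges[, 1L] == v, 2L])
}

adjacent <- function(structure, a, b) {
  e <- structure$edges
  any((e[, 1L] == a & e[, 2L] == b) | (e[, 1L] == b & e[, 2L] == a))
}

#' Check that a network structure is a valid DAG
#'
#' Reports (rather than raises) violations of the structural invariants:
#' every edge endpoint declared, no self-loops, no duplicate edges, and
#' acyclicity.
#'
#' @param structure a [bn_structure].
#' @return A list with `ok` (logical) and `violations` (character vector,
#'   empty when `ok`).
#' @examples
#' s <- bn_structure(c(A = 2L, B = 2L), list(c("A", "B"), c("B", "A")))
#' validate_dag(s)
#' @export
validate_dag <- function(structure) {
  viol <- character(0)
  vn <- variable_names(structure)
  e <- structure$edges
  unknown <- setdiff(unique(c(e)), vn)
  if (length(unknown))
    viol <- c(viol, paste0("unknown variable: ", paste(unknown, collapse = ", ")))
  if (any(e[, 1L] == e[, 2L]))
    viol <- c(viol, paste0("self-loop: ",
                           paste(unique(e[e[, 1L] == e[, 2L], 1L]), collapse = ", ")))
  key <- paste(e[, 1L], e[, 2L], sep = "\r")
  if (anyDuplicated(key))
    viol <- c(viol, paste0("duplicate edge: ",
                           paste(unique(gsub("\r", "->", key[duplicated(key)])),
                                 collapse = ", ")))
  if (!length(unknown)) {
    cyc <- find_cycle(vn, e)
    if (!is.null(cyc))
      viol <- c(viol, paste0("cycle ", paste(cyc, collapse = ",")))
  }
  list(ok = length(viol) == 0L, violations = viol)
}

# Kahn's algorithm; returns NULL if acyclic, else the variables left on a cycle
find_cycle <- function(vn, edges) {
  indeg <- stats::setNames(integer(length(vn)), vn)
  tab <- table(factor(edges[, 2L], levels = vn))
  indeg[names(tab)] <- as.integer(tab)
  active <- stats::setNames(rep(TRUE, length(vn)), vn)
  queue <- vn[indeg == 0L]
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    active[[v]] <- FALSE
    for (w in edges[edges[, 1L] == v, 2L]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (any(active)) sort(vn[active]) else NULL
}

#' Topological order of a DAG
#'
#' @param structure a valid [bn_structure].
#' @return Variable names sorted so that every parent precedes its children.
#' @export
topological_order <- function(structure) {
  vn <- variable_names(structure)
  e <- structure$edges
  indeg <- stats::setNames(integer(length(vn)), vn)
  tab <- table(factor(e[, 2L], levels = vn))
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  queue <- vn[indeg == 0L]
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in e[e[, 1L] == v, 2L]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(vn)) stop("structure contains a cycle")
  out
}

ancestors_of <- function(structure, vs) {
  e <- structure$edges
  anc <- character(0)
  frontier <- vs
  while (length(frontier)) {
    pa <- unique(e[e[, 2L] %in% frontier, 1L])
    new <- setdiff(pa, c(anc, vs))
    anc <- union(anc, pa)
    frontier <- new
  }
  anc
}

#' Level-wise causal ordering of variables
#'
#' A causal ordering partitions the variables into ordered levels: a variable
#' may only cause variables in the same or later levels, and within a level
#' the listed position breaks ties. The implied total order is by level, then
#' by position within level. In a food-security network the outcome variable
#' occupies the last level alone, so every other variable is a potential
#' cause of it and it causes nothing.
#'
#' @param levels a list of character vectors, earliest (root causes) first.
#' @return An object of class `causal_ordering`.
#' @examples
#' ord <- causal_ordering(list(c("SES", "WA"), "FS"))
#' ordering_rank(ord)
#' @export
causal_ordering <- function(levels) {
  levels <- lapply(levels, as.character)
  if (!length(levels) || any(lengths(levels) == 0L))
    stop("levels must be non-empty character vectors")
  all <- unlist(levels)
  if (anyDuplicated(all))
    stop("a variable appears in more than one level: ",
         paste(unique(all[duplicated(all)]), collapse = ", "))
  structure(list(levels = levels), class = "causal_ordering")
}

#' @export
print.causal_ordering <- function(x, ...) {
  cat("Causal ordering with", length(x$levels), "levels:\n")
  for (i in seq_along(x$levels))
    cat("  L", i, ": ", paste(x$levels[[i]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname causal_ordering
#' @param ordering a `causal_ordering`.
#' @return `ordering_rank()`: a named integer vector giving each variable's
#'   position in the implied total order (1 = earliest).
#' @export
ordering_rank <- function(ordering) {
  all <- unlist(ordering$levels)
  stats::setNames(seq_along(all), all)
}

check_ordering_covers <- function(ordering, vars) {
  miss <- setdiff(vars, unlist(ordering$levels))
  if (length(miss))
    stop("variables missing from the causal ordering: ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

# TRUE iff every edge goes from an earlier to a later variable in the ordering
ordering_consistent <- function(structure, ordering) {
  if (!nrow(structure$edges)) return(TRUE)
  rk <- ordering_rank(ordering)
  all(rk[structure$edges[, 1L]] < rk[structure$edges[, 2L]])
}
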