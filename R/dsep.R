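#' d-separation in a directed acyclic graph
#'
#' Decides whether every path between `a` and `b` is blocked given the
#' conditioning set `c`, using the moral-ancestral-graph criterion: restrict
#' the DAG to the ancestral set of `{a, b} U c`, moralise (marry co-parents,
#' drop directions), delete the conditioning nodes, and test reachability.
#'
#' @param structure a valid [bn_structure].
#' @param a,b variable names, distinct.
#' @param c character vector of conditioning variable names (default empty);
#'   must not contain `a` or `b`.
#' @return `TRUE` iff `a` and `b` are d-separated given `c`.
#' @examples
#' chain <- bn_structure(c(A = 2, B = 2, C = 2),
#'                       list(c("A", "B"), c("B", "C")))
#' d_separated(chain, "A", "C", "B")   # TRUE
#' d_separated(chain, "A", "C")        # FALSE
#' @export
d_separated <- function(structure, a, b, c = character(0)) {
  vn <- variable_names(structure)
  c <- as.character(c)
  unknown <- setdiff(c(a, b, c), vn)
  if (length(unknown))
    stop("unknown variable: ", paste(unknown, collapse = ", "))
  if (a == b) stop("'a' and 'b' must differ")
  if (a %in% c || b %in% c) stop("conditioning set must not contain 'a' or 'b'")
  adj <- moral_ancestral_adjacency(structure, c(a, b, c))
  # remove conditioning nodes, then search for a path a ~ b
  keep <- setdiff(rownames(adj), c)
  adj <- adj[keep, keep, drop = FALSE]
  !undirected_reachable(adj, a, b)
}

# Symmetric logical adjacency matrix of the moralised ancestral graph of 'nodes'
moral_ancestral_adjacency <- function(structure, nodes) {
  anc <- union(nodes, ancestors_of(structure, nodes))
  e <- structure$edges
  e <- e[e[, 1L] %in% anc & e[, 2L] %in% anc, , drop = FALSE]
  n <- length(anc)
  adj <- matrix(FALSE, n, n, dimnames = list(anc, anc))
  if (nrow(e)) {
    adj[cbind(e[, 1L], e[, 2L])] <- TRUE
    adj[cbind(e[, 2L], e[, 1L])] <- TRUE
    # marry parents of a common child
    for (v in unique(e[, 2L])) {
      pa <- e[e[, 2L] == v, 1L]
      if (length(pa) > 1L) {
        pr <- utils::combn(pa, 2L)
        adj[cbind(pr[1L, ], pr[2L, ])] <- TRUE
        adj[cbind(pr[2L, ], pr[1L, ])] <- TRUE
      }
    }
  }
  adj
}

undirected_reachable <- function(adj, from, to) {
  if (!(from %in% rownames(adj)) || !(to %in% rownames(adj))) return(FALSE)
  seen <- stats::setNames(logical(nrow(adj)), rownames(adj))
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier)) {
    nxt <- rownames(adj)[colSums(adj[frontier, , drop = FALSE]) > 0]
    nxt <- nxt[!seen[nxt]]
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen[[to]]
}

#' Smallest d-separating set for a non-adjacent pair
#'
#' Searches subsets of the ancestral variables of `{a, b}` in order of
#' increasing size for a set `C` with `a` d-separated from `b` given `C`.
#' (Any minimal d-separator of a non-adjacent pair lies among those
#' ancestors, and for non-adjacent pairs in a DAG one always exists.)
#' Ties between equal-cardinality separators are broken lexicographically on
#' the sorted member list, so the result is reproducible.
#'
#' @inheritParams d_separated
#' @return A character vector (possibly empty, meaning marginal independence),
#'   or `NULL` in the degenerate case that no separating set exists.
#' @examples
#' v <- bn_structure(c(A = 2, B = 2, C = 2),
#'                   list(c("A", "C"), c("B", "C")))
#' find_minimal_separator(v, "A", "B")  # character(0): marginally independent
#' @export
find_minimal_separator <- function(structure, a, b) {
  vn <- variable_names(structure)
  unknown <- setdiff(c(a, b), vn)
  if (length(unknown)) stop("unknown variable: ", paste(unknown, collapse = ", "))
  if (a == b) stop("'a' and 'b' must differ")
  if (adjacent(structure, a, b))
    stop("adjacent pair: no d-separating set can exist for ", a, " -- ", b)
  pool <- sort(setdiff(union(c(a, b), ancestors_of(structure, c(a, b))), c(a, b)))
  for (k in 0:length(pool)) {
    if (k == 0L) {
      if (d_separated(structure, a, b, character(0))) return(character(0))
    } else {
      sets <- utils::combn(pool, k, simplify = FALSE)  # lexicographic order
      for (s in sets) if (d_separated(structure, a, b, s)) return(s)
    }
  }
  NULL
}

independence_relation <- function(a, b, c) {
  data.frame(A = a, B = b,
             C = if (length(c)) paste(sort(c), collapse = ",") else "",
             stringsAsFactors = FALSE)
}

#' Reduce a structure's implied independencies to one per variable pair
#'
#' For expert validation of an elicited structure, the (typically thousands
#' of) conditional independencies a DAG implies are reduced to a reviewable
#' list: one statement `A _||_ B | C` per non-adjacent unordered pair, with
#' `A` the variable that comes later in the causal ordering and `C` the
#' smallest separating set (ties broken lexicographically). Pairs with no
#' separating set are skipped.
#'
#' @param structure a valid [bn_structure].
#' @param ordering a [causal_ordering] covering the structure's variables.
#' @return A data.frame with columns `A`, `B`, `C` (comma-joined sorted
#'   conditioning names, `""` for the empty set), sorted by `(A, B)`.
#' @export
reduce_relationships <- function(structure, ordering) {
  vn <- variable_names(structure)
  check_ordering_covers(ordering, vn)
  rk <- ordering_rank(ordering)
  out <- list()
  if (length(vn) >= 2L) {
    prs <- utils::combn(sort(vn), 2L)
    for (i in seq_len(ncol(prs))) {
      u <- prs[1L, i]; v <- prs[2L, i]
      if (adjacent(structure, u, v)) next
      # A is the later variable in the ordering ("B came before A")
      a <- if (rk[[u]] > rk[[v]]) u else v
      b <- if (rk[[u]] > rk[[v]]) v else u
      sep <- find_minimal_separator(structure, a, b)
      if (is.null(sep)) next
      out[[length(out) + 1L]] <- independence_relation(a, b, sep)
    }
  }
  if (!length(out))
    return(data.frame(A = character(0), B = character(0), C = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$A, res$B), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Enumerate the pairwise conditional independencies a DAG implies
#'
#' Lists every relation `A _||_ B | C` with singleton `A`, `B` and
#' `|C| <= max_conditioning` that holds by d-separation. Pairs are reported
#' once with `A < B` lexicographically; the output is sorted by
#' `(A, B, |C|, C)` so enumeration is deterministic.
#'
#' @param structure a valid [bn_structure].
#' @param max_conditioning largest conditioning-set size to enumerate
#'   (>= 0). The count grows combinatorially with this bound.
#' @return A data.frame with columns `A`, `B`, `C` as in
#'   [reduce_relationships()].
#' @export
implied_independencies <- function(structure, max_conditioning) {
  stopifnot(max_conditioning >= 0)
  vn <- sort(variable_names(structure))
  out <- list()
  if (length(vn) >= 2L) {
    prs <- utils::combn(vn, 2L)
    for (i in seq_len(ncol(prs))) {
      a <- prs[1L, i]; b <- prs[2L, i]
      rest <- sort(setdiff(vn, c(a, b)))
      for (k in 0:min(max_conditioning, length(rest))) {
        sets <- if (k == 0L) list(character(0))
                else utils::combn(rest, k, simplify = FALSE)
        for (s in sets)
          if (d_separated(structure, a, b, s))
            out[[length(out) + 1L]] <- independence_relation(a, b, s)
      }
    }
  }
  if (!length(out))
    return(data.frame(A = character(0), B = character(0), C = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
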