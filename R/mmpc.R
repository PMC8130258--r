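#' Learn an undirected skeleton with Max-Min Parents and Children
#'
#' Runs the MMPC constraint-based local-discovery algorithm for every
#' variable, using the stratified Jonckheere-Terpstra test
#' ([jt_ci_test()]) as the conditional-independence oracle, and assembles
#' the per-variable parents-and-children sets into an undirected skeleton
#' under the AND symmetry rule.
#'
#' For each target the forward phase repeatedly adds the candidate with the
#' largest min-association, where association is `1 - p` and the minimum is
#' taken over all subsets (up to `max_conditioning`) of the current
#' candidate set; candidates whose min-association ever becomes
#' non-significant are permanently discarded (the minimum can only shrink as
#' the set grows). The backward phase then removes any member rendered
#' independent of the target given some subset of the remaining members.
#'
#' The level-wise causal ordering enters in two ways: the outcome variable
#' (the sole occupant of the last level, food security in the intended
#' application) is disallowed from the start as a candidate cause of every
#' other variable, and all edge directions are later forced by the ordering
#' ([orient_edges()]). For an edge incident to the outcome only the
#' outcome's own parents-and-children set is consulted, since the reverse
#' membership test is forbidden by design.
#'
#' @param data a complete data.frame of 0-based integer state columns.
#' @param ordering a [causal_ordering] covering the data columns; its last
#'   level must contain exactly one variable (the outcome).
#' @param alpha per-test significance level in (0, 1).
#' @param max_conditioning largest conditioning-set size searched.
#' @param min_stratum smallest usable stratum in the JT test.
#' @param expert_edges optional two-column character matrix of undirected
#'   expert edges; these are admitted at the laxer level `alpha_keep`
#'   (see [learn_structure()]).
#' @param alpha_keep significance level applied to expert edges (> alpha).
#' @return An object of class `bn_skeleton`: list with `variables` (named
#'   cardinalities) and `edges` (two-column character matrix of unordered
#'   pairs, each sorted, sorted overall).
#' @export
mmpc_skeleton <- function(data, ordering, alpha = 0.05, max_conditioning = 3L,
                          min_stratum = 5L, expert_edges = NULL,
                          alpha_keep = 0.2) {
  if (nrow(data) == 0L) stop("empty data")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  vn <- names(data)
  check_ordering_covers(ordering, vn)
  last <- ordering$levels[[length(ordering$levels)]]
  outcome <- if (length(last) == 1L && last %in% vn) last else NA_character_
  is_expert <- expert_pair_lookup(expert_edges)
  cache <- new.env(parent = emptyenv())
  p_of <- function(c, t, S) {
    key <- paste(c, t, paste(sort(S), collapse = ","), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    p <- jt_ci_test(data, c, t, S, min_stratum = min_stratum)$p_value
    cache[[key]] <- p
    p
  }
  pc <- lapply(vn, function(t) {
    cand <- setdiff(vn, t)
    if (!is.na(outcome) && t != outcome) cand <- setdiff(cand, outcome)
    mmpc_target(t, cand, p_of, alpha, max_conditioning, is_expert, alpha_keep)
  })
  names(pc) <- vn
  edges <- list()
  for (i in seq_along(vn)) for (j in seq_along(vn)) {
    if (i >= j) next
    u <- vn[[i]]; v <- vn[[j]]
    u_in_v <- u %in% pc[[v]]; v_in_u <- v %in% pc[[u]]
    # the outcome never appears in another variable's candidate set, so an
    # outcome edge is judged by the outcome's own neighbour search alone
    keep <- if (!is.na(outcome) && u == outcome) v_in_u
            else if (!is.na(outcome) && v == outcome) u_in_v
            else u_in_v && v_in_u
    if (keep) edges[[length(edges) + 1L]] <- sort(c(u, v))
  }
  em <- if (length(edges)) do.call(rbind, edges) else matrix(character(0), ncol = 2L)
  if (nrow(em)) em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  colnames(em) <- c("u", "v")
  structure(list(variables = vapply(data, function(x) max(2L, max(x) + 1L), 1L),
                 edges = em),
            class = "bn_skeleton")
}

#' @export
print.bn_skeleton <- function(x, ...) {
  cat("Undirected skeleton:", length(x$variables), "variables,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges))
    cat(" ", paste(x$edges[, 1L], "--", x$edges[, 2L], collapse = ", "), "\n")
  invisible(x)
}

expert_pair_lookup <- function(expert_edges) {
  if (is.null(expert_edges) || !nrow(expert_edges)) return(function(a, b) FALSE)
  keys <- apply(expert_edges, 1L, function(e) paste(sort(e), collapse = "|"))
  function(a, b) paste(sort(c(a, b)), collapse = "|") %in% keys
}

# forward + backward phase for one target; returns its parents-children set
mmpc_target <- function(t, cand, p_of, alpha, max_conditioning, is_expert,
                        alpha_keep) {
  level <- function(c) if (is_expert(c, t)) alpha_keep else alpha
  maxp <- vapply(cand, function(c) p_of(c, t, character(0)), 1)
  alive <- maxp < vapply(cand, level, 1)
  cand <- cand[alive]; maxp <- maxp[alive]
  cpc <- character(0)
  while (length(cand)) {
    pick <- which.min(maxp)
    c_star <- cand[[pick]]
    cpc <- c(cpc, c_star)
    cand <- cand[-pick]; maxp <- maxp[-pick]
    if (!length(cand)) break
    # refresh the min-association of the survivors against the new subsets
    # (those containing c_star), up to the conditioning cap
    others <- setdiff(cpc, c_star)
    new_sets <- lapply(subsets_up_to(others, max_conditioning - 1L),
                       function(s) c(s, c_star))
    for (idx in seq_along(cand)) {
      c <- cand[[idx]]
      for (S in new_sets) {
        if (maxp[[idx]] >= level(c)) break
        p <- p_of(c, t, S)
        if (p > maxp[[idx]]) maxp[[idx]] <- p
      }
    }
    keep <- maxp < vapply(cand, level, 1)
    cand <- cand[keep]; maxp <- maxp[keep]
  }
  # backward phase
  for (x in cpc) {
    rest <- setdiff(cpc, x)
    for (S in subsets_up_to(rest, max_conditioning)) {
      if (p_of(x, t, S) >= level(x)) { cpc <- setdiff(cpc, x); break }
    }
  }
  cpc
}

subsets_up_to <- function(xs, k) {
  out <- list(character(0))
  for (m in seq_len(min(k, length(xs)))) {
    out <- c(out, utils::combn(xs, m, simplify = FALSE))
  }
  out
}

#' Orient a skeleton by the causal ordering
#'
#' Directs every undirected edge from the earlier to the later variable in
#' the ordering's implied total order (level, then within-level position —
#' the order the variables were presented in the expert elicitation). The
#' result is acyclic by construction.
#'
#' @param skeleton a `bn_skeleton` from [mmpc_skeleton()].
#' @param ordering a [causal_ordering] covering the skeleton's variables.
#' @return A [bn_structure].
#' @export
orient_edges <- function(skeleton, ordering) {
  vn <- names(skeleton$variables)
  check_ordering_covers(ordering, vn)
  rk <- ordering_rank(ordering)
  e <- skeleton$edges
  directed <- matrix(character(0), ncol = 2L)
  if (nrow(e)) {
    flip <- rk[e[, 1L]] > rk[e[, 2L]]
    directed <- cbind(ifelse(flip, e[, 2L], e[, 1L]),
                      ifelse(flip, e[, 1L], e[, 2L]))
  }
  bn_structure(stats::setNames(as.integer(skeleton$variables[vn]), vn),
               directed)
}

#' Learn a directed network structure from household data
#'
#' Full structure-learning pipeline: MMPC skeleton discovery with the
#' stratified Jonckheere-Terpstra conditional-independence test, optionally
#' seeded with an expert-elicited network as a prior, then edge orientation
#' by the causal ordering.
#'
#' In expert-prior mode the prior structure's edges (taken as undirected)
#' are admitted into the candidate sets like any other pair but are tested
#' at the laxer level `alpha_keep` (> `alpha`): an expert edge is retained
#' unless some conditioning subset fails to reject independence even at
#' `alpha_keep`, while non-expert edges must pass the stricter `alpha`.
#' Expert edges with no support at all in the data are still dropped.
#'
#' @inheritParams mmpc_skeleton
#' @param expert_prior optional [bn_structure] of expert-elicited edges;
#'   must satisfy the ordering.
#' @return A directed acyclic [bn_structure].
#' @seealso [fsbn()] for the one-call model fit built on this.
#' @export
learn_structure <- function(data, ordering, alpha = 0.05,
                            max_conditioning = 3L, min_stratum = 5L,
                            expert_prior = NULL, alpha_keep = 0.2) {
  expert_edges <- NULL
  if (!is.null(expert_prior)) {
    if (alpha_keep <= alpha) stop("alpha_keep must exceed alpha")
    if (!ordering_consistent(expert_prior, ordering))
      stop("expert prior violates the causal ordering")
    expert_edges <- expert_prior$edges
  }
  sk <- mmpc_skeleton(data, ordering, alpha = alpha,
                      max_conditioning = max_conditioning,
                      min_stratum = min_stratum,
                      expert_edges = expert_edges, alpha_keep = alpha_keep)
  orient_edges(sk, ordering)
}
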