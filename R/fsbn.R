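#' Fit a food-security Bayesian belief network
#'
#' One-call model fit: learns the directed network structure from a
#' complete table of ordinal household observations under a level-wise
#' causal ordering (optionally seeded with an expert-elicited structure as
#' a prior, or skipping learning entirely when a structure is supplied),
#' then estimates every conditional probability table by MAP with add-one
#' smoothing. The result is a fitted network that supports posterior
#' prediction, forward simulation, interventional queries and sensitivity
#' analysis.
#'
#' Three learning modes mirror the usual model-building options:
#' * `structure` supplied — fixed (e.g. expert-elicited) structure,
#'   parameters from data;
#' * `expert_prior` supplied — MMPC learning with the expert edges
#'   admitted at the laxer level `alpha_keep`;
#' * neither — pure data-driven MMPC learning.
#'
#' @param data a complete data.frame of 0-based integer state columns, one
#'   row per household.
#' @param ordering a [causal_ordering] covering the columns; the outcome
#'   (food security) must be alone in the last level.
#' @param structure optional fixed [bn_structure]; when given, no structure
#'   learning is performed (it must satisfy the ordering).
#' @param expert_prior optional expert [bn_structure] used as a prior
#'   during learning; see [learn_structure()].
#' @param alpha per-test significance level of the
#'   Jonckheere-Terpstra conditional-independence test.
#' @param max_conditioning largest conditioning-set size in MMPC.
#' @param min_stratum smallest usable stratum in the stratified test.
#' @param alpha_keep laxer significance level applied to expert edges.
#' @param pseudocount Dirichlet pseudocount for CPT estimation (1 =
#'   add-one smoothing).
#' @return An object of class `c("fsbn", "bn")`: a fitted [bn] with
#'   additional elements `ordering`, `outcome`, `n`, `learn` (the learning
#'   parameters used) and `call`.
#' @examples
#' net <- make_agincourt_like_network(generator_config(seed = 7))
#' d <- sample_households(net, 2000, seed = 7)
#' fit <- fsbn(d, agincourt_ordering())
#' fit
#' predict(fit, d[1:3, ], type = "posterior")
#' @export
fsbn <- function(data, ordering, structure = NULL, expert_prior = NULL,
                 alpha = 0.05, max_conditioning = 3L, min_stratum = 5L,
                 alpha_keep = 0.2, pseudocount = 1) {
  if (nrow(data) == 0L) stop("empty data")
  check_ordering_covers(ordering, names(data))
  last <- ordering$levels[[length(ordering$levels)]]
  if (length(last) != 1L)
    stop("the outcome must occupy the last ordering level alone")
  outcome <- last
  if (!is.null(structure)) {
    if (!is.null(expert_prior))
      stop("give either a fixed structure or an expert prior, not both")
    if (!ordering_consistent(structure, ordering))
      stop("supplied structure violates the causal ordering")
    str <- structure
    mode <- "fixed"
  } else {
    str <- learn_structure(data, ordering, alpha = alpha,
                           max_conditioning = max_conditioning,
                           min_stratum = min_stratum,
                           expert_prior = expert_prior,
                           alpha_keep = alpha_keep)
    mode <- if (is.null(expert_prior)) "mmpc" else "mmpc+expert_prior"
  }
  net <- fit_cpts(str, data, pseudocount = pseudocount)
  net$ordering <- ordering
  net$outcome <- outcome
  net$n <- nrow(data)
  net$learn <- list(mode = mode, alpha = alpha,
                    max_conditioning = as.integer(max_conditioning),
                    min_stratum = as.integer(min_stratum),
                    alpha_keep = alpha_keep, pseudocount = pseudocount)
  net$call <- match.call()
  class(net) <- c("fsbn", class(net))
  net
}

#' @export
print.fsbn <- function(x, ...) {
  cat("Food-security Bayesian belief network\n")
  cat("Call: ", deparse1(x$call), "\n\n")
  cat("Structure (", x$learn$mode, "): ", length(x$structure$vars),
      " variables, ", nrow(x$structure$edges), " edges, fitted to ",
      x$n, " households\n", sep = "")
  pa <- bn_parents(x$structure, x$outcome)
  cat("Parents of ", x$outcome, ": ",
      if (length(pa)) paste(pa, collapse = ", ") else "(none)", "\n", sep = "")
  invisible(x)
}

#' @export
summary.fsbn <- function(object, ...) {
  marg <- posterior(object, object$outcome)$prob
  sens <- sensitivity_table(object, object$outcome)
  sens <- sens[order(-sens$I), , drop = FALSE]
  out <- list(call = object$call, n = object$n, mode = object$learn$mode,
              n_edges = nrow(object$structure$edges),
              outcome = object$outcome,
              outcome_marginal = marg,
              outcome_parents = bn_parents(object$structure, object$outcome),
              sensitivity = sens)
  class(out) <- "summary.fsbn"
  out
}

#' @export
print.summary.fsbn <- function(x, ...) {
  cat("Food-security Bayesian belief network (", x$mode, ", n = ", x$n,
      ", ", x$n_edges, " edges)\n\n", sep = "")
  cat("Marginal distribution of ", x$outcome, ":\n", sep = "")
  print(round(x$outcome_marginal, 4))
  cat("\nParents of ", x$outcome, ": ",
      if (length(x$outcome_parents)) paste(x$outcome_parents, collapse = ", ")
      else "(none)", "\n", sep = "")
  cat("\nSensitivity of ", x$outcome,
      " to each variable (sorted by I, bits):\n", sep = "")
  print(transform(x$sensitivity, I = round(I, 4),
                  I_over_H = round(I_over_H, 4), S2 = round(S2, 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.fsbn <- function(object, ...) {
  object$cpts
}

#' Predict food-security posteriors for new households
#'
#' For each row of `newdata`, computes the exact posterior of the target
#' variable given all other network variables as evidence.
#'
#' @param object a fitted [fsbn] model.
#' @param newdata a data.frame covering the non-target network variables
#'   (0-based integer states).
#' @param type `"posterior"` for the full probability matrix, `"state"`
#'   for the most probable 0-based state (ties toward the lower state,
#'   i.e. food secure).
#' @param target the predicted variable; defaults to the model's outcome.
#' @param ... unused.
#' @return A numeric matrix (rows = households, columns = target states)
#'   or an integer vector of state indices.
#' @export
predict.fsbn <- function(object, newdata,
                         type = c("posterior", "state"),
                         target = object$outcome, ...) {
  type <- match.arg(type)
  nd <- newdata
  if (!(target %in% names(nd))) nd[[target]] <- 0L  # ignored as evidence
  post <- posterior_given_rest(object, target, nd)
  if (type == "posterior") post
  else max.col(post, ties.method = "first") - 1L
}

#' Simulate households from a fitted network
#'
#' @param object a fitted [fsbn] model (or any [bn]).
#' @param nsim number of households to draw.
#' @param seed integer seed (required for reproducibility).
#' @param ... unused.
#' @return A data.frame of 0-based integer state columns.
#' @export
simulate.fsbn <- function(object, nsim = 1L, seed = 1L, ...) {
  sample_households(object, nsim, seed = seed)
}

#' Plot a network structure as a layered DAG
#'
#' Lays variables out by causal-ordering level (or topological depth when
#' no ordering is available) and draws directed edges. Uses igraph when
#' installed; otherwise falls back to a simple base-graphics layout.
#'
#' @param x a [fsbn], [bn] or [bn_structure].
#' @param ordering optional [causal_ordering] controlling the layers.
#' @param ... passed to the underlying plotting routine.
#' @export
plot.fsbn <- function(x, ordering = x$ordering, ...) {
  plot_structure(x$structure, ordering, ...)
}

#' @export
plot.bn_structure <- function(x, ordering = NULL, ...) {
  plot_structure(x, ordering, ...)
}

plot_structure <- function(str, ordering = NULL, ...) {
  vn <- variable_names(str)
  lv <- if (!is.null(ordering)) level_of(ordering)[vn] else topo_depth(str)[vn]
  xs <- ys <- stats::setNames(numeric(length(vn)), vn)
  for (l in sort(unique(lv))) {
    members <- vn[lv == l]
    ys[members] <- -l
    xs[members] <- seq_along(members) - (length(members) + 1) / 2
  }
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_data_frame(
      as.data.frame(str$edges), directed = TRUE,
      vertices = data.frame(name = vn))
    igraph::plot.igraph(g, layout = cbind(xs[igraph::V(g)$name],
                                          ys[igraph::V(g)$name]),
                        vertex.size = 24, vertex.color = "lightsteelblue",
                        vertex.label.cex = 0.8, edge.arrow.size = 0.4, ...)
  } else {
    graphics::plot(xs, ys, type = "n", axes = FALSE, xlab = "", ylab = "",
                   xlim = range(xs) + c(-0.5, 0.5),
                   ylim = range(ys) + c(-0.5, 0.5), ...)
    if (nrow(str$edges))
      graphics::arrows(xs[str$edges[, 1L]], ys[str$edges[, 1L]] - 0.08,
                       xs[str$edges[, 2L]], ys[str$edges[, 2L]] + 0.08,
                       length = 0.08, col = "grey40")
    graphics::points(xs, ys, pch = 21, bg = "lightsteelblue", cex = 3)
    graphics::text(xs, ys, vn, cex = 0.7)
  }
  invisible(NULL)
}

topo_depth <- function(str) {
  depth <- stats::setNames(integer(length(str$vars)), variable_names(str))
  for (v in topological_order(str)) {
    pa <- bn_parents(str, v)
    depth[[v]] <- if (length(pa)) max(depth[pa]) + 1L else 1L
  }
  depth
}
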