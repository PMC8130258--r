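#' Graph surgery for interventional (do-operator) queries
#'
#' Models an external intervention do(X = x) by severing every incoming
#' edge of each intervened variable and replacing its CPT with a point mass
#' on the forced state; all other CPTs are untouched. Multi-variable
#' interventions are performed as one simultaneous surgery.
#'
#' @param network a [bn].
#' @param spec named integer vector mapping intervened variable names to
#'   forced 0-based state indices.
#' @return A modified [bn] representing the post-intervention distribution.
#' @examples
#' s <- bn_structure(c(Z = 2, X = 2, Y = 2),
#'                   list(c("Z", "X"), c("Z", "Y"), c("X", "Y")))
#' @export
do_surgery <- function(network, spec) {
  spec <- check_intervention(network, spec)
  str <- network$structure
  drop <- str$edges[, 2L] %in% names(spec)
  new_str <- bn_structure(str$vars, str$edges[!drop, , drop = FALSE])
  cpts <- network$cpts
  for (v in names(spec)) {
    r <- length(str$vars[[v]])
    point <- numeric(r)
    point[spec[[v]] + 1L] <- 1
    cpts[[v]] <- check_cpt(point, v, character(0), new_str)
  }
  # re-anchor untouched CPTs (structure object changed, tables identical)
  bn(new_str, cpts)
}

check_intervention <- function(network, spec) {
  if (!length(spec)) stop("empty intervention")
  if (is.null(names(spec)) || any(!nzchar(names(spec))))
    stop("intervention must be a named vector")
  if (anyDuplicated(names(spec))) stop("variable assigned twice")
  vn <- variable_names(network$structure)
  unknown <- setdiff(names(spec), vn)
  if (length(unknown)) stop("unknown variable: ", paste(unknown, collapse = ", "))
  spec <- vapply(spec, as.integer, 1L)
  for (v in names(spec)) check_state_range(network$structure, v, spec[[v]])
  spec
}

#' Posterior of a target under an intervention
#'
#' Computes P(target | do(spec)) exactly: performs [do_surgery()] and then
#' queries the target's posterior in the mutilated network with the forced
#' states as evidence (equivalently, reads off the target's marginal there).
#'
#' @inheritParams do_surgery
#' @param target the queried variable; must not be intervened on.
#' @return A `bn_posterior` (see [posterior()]).
#' @export
interventional_query <- function(network, target, spec) {
  spec <- check_intervention(network, spec)
  if (target %in% names(spec))
    stop("target '", target, "' cannot be intervened on in its own query")
  cut <- do_surgery(network, spec)
  posterior(cut, target, spec)
}

#' Sensitivity of food security to each network variable
#'
#' Two belief-based sensitivity metrics, both computed from exact
#' observational inference (base-2 logarithms):
#'
#' * mutual information reduction
#'   \deqn{I = H(T) - \sum_x P(x) H(T | X = x),}
#'   the expected reduction in entropy (bits) of the target T from
#'   observing X, also reported as the fraction `I / H(T)`;
#' * expected change of belief
#'   \deqn{S^2 = \sum_x P(x) \sum_s (P(T = s | x) - P(T = s))^2,}
#'   the observation-weighted squared shift of the target's posterior from
#'   its prior.
#'
#' @param network a fitted [bn].
#' @param target the outcome variable (food security).
#' @param variable the observed variable X (distinct from `target`).
#' @return `mutual_information_reduction()`: list with `I`, `I_over_H`,
#'   `H_target`, and `degenerate` (TRUE when H(target) = 0, in which case
#'   `I_over_H` is reported as 0). `expected_change_of_belief()`: the
#'   scalar S^2.
#' @export
mutual_information_reduction <- function(network, target, variable) {
  sens <- sensitivity_components(network, target, variable)
  H <- entropy_bits(sens$p_target)
  Hcond <- sum(sens$p_x * apply(sens$post, 1L, entropy_bits))
  I <- max(0, H - Hcond)  # clip tiny negative rounding
  list(I = I,
       I_over_H = if (H > 0) I / H else 0,
       H_target = H,
       degenerate = H <= 0)
}

#' @rdname mutual_information_reduction
#' @export
expected_change_of_belief <- function(network, target, variable) {
  sens <- sensitivity_components(network, target, variable)
  sum(sens$p_x * rowSums(sweep(sens$post, 2L, sens$p_target)^2))
}

sensitivity_components <- function(network, target, variable) {
  if (identical(target, variable)) stop("variable must differ from target")
  p_target <- posterior(network, target)$prob
  p_x <- posterior(network, variable)$prob
  rx <- length(p_x)
  post <- matrix(0, rx, length(p_target))
  for (x in seq_len(rx) - 1L) {
    post[x + 1L, ] <- if (p_x[[x + 1L]] > 0)
      posterior(network, target, stats::setNames(x, variable))$prob
    else p_target  # unobservable state: contributes nothing (weight 0)
  }
  list(p_target = p_target, p_x = as.numeric(p_x), post = post)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Sensitivity table over all non-target variables
#'
#' One row per variable other than the target, sorted by variable name,
#' with the mutual information reduction `I`, its fraction `I_over_H` of
#' the target's entropy, and the expected change of belief `S2`.
#'
#' @inheritParams mutual_information_reduction
#' @return A data.frame with columns `variable`, `I`, `I_over_H`, `S2`.
#' @export
sensitivity_table <- function(network, target) {
  vars <- sort(setdiff(variable_names(network$structure), target))
  rows <- lapply(vars, function(v) {
    mi <- mutual_information_reduction(network, target, v)
    data.frame(variable = v, I = mi$I, I_over_H = mi$I_over_H,
               S2 = expected_change_of_belief(network, target, v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
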