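#' Discrete Bayesian belief network
#'
#' Couples a [bn_structure] with one conditional probability table (CPT) per
#' variable. Each CPT is a numeric array whose first dimension indexes the
#' variable's own states and whose remaining dimensions index the states of
#' its parents, in the structure's parent order; every parent-configuration
#' slice sums to 1. Together the CPTs factorise the joint distribution
#' \deqn{P(x_1,\dots,x_n) = \prod_i \theta_i^{j k} =
#'       \prod_i P(x_i \mid pa(x_i)).}
#'
#' @param structure a valid [bn_structure].
#' @param cpts a named list, one entry per variable, each a numeric array as
#'   produced by [make_cpt()] (a plain vector/array is accepted and checked).
#' @return An object of class `bn` with elements `structure` and `cpts`.
#' @seealso [fit_cpts()] to estimate CPTs from data, [posterior()] for
#'   queries.
#' @export
bn <- function(structure, cpts) {
  val <- validate_dag(structure)
  if (!val$ok) stop("invalid structure: ", paste(val$violations, collapse = "; "))
  vn <- variable_names(structure)
  if (!setequal(names(cpts), vn))
    stop("cpts must have exactly one entry per variable")
  cpts <- cpts[vn]
  for (v in vn) {
    cpts[[v]] <- check_cpt(cpts[[v]], v, bn_parents(structure, v), structure)
  }
  structure(list(structure = structure, cpts = cpts), class = "bn")
}

#' Build a CPT array
#'
#' @param structure a [bn_structure].
#' @param variable the child variable name.
#' @param values numeric vector or array of probabilities; the first
#'   dimension runs over the child's states, subsequent dimensions over the
#'   parents' states in structure parent order (column-major, so values can
#'   be given as the flat vector in that layout).
#' @return A probability array with dimnames set from the state labels.
#' @export
make_cpt <- function(structure, variable, values) {
  check_cpt(values, variable, bn_parents(structure, variable), structure)
}

check_cpt <- function(x, v, parents, structure, tol = 1e-9) {
  card <- c(lengths(structure$vars[v]), lengths(structure$vars[parents]))
  x <- as.numeric(x)
  if (length(x) != prod(card))
    stop("CPT for '", v, "' has length ", length(x), ", expected ", prod(card))
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1 + tol))
    stop("CPT for '", v, "' has entries outside [0, 1]")
  dim(x) <- unname(card)
  dimnames(x) <- unname(structure$vars[c(v, parents)])
  sums <- if (length(card) == 1L) sum(x)
          else apply(x, seq_along(card)[-1L], sum)
  if (any(abs(sums - 1) > tol))
    stop("CPT for '", v, "' has a parent configuration not summing to 1")
  attr(x, "variable") <- v
  attr(x, "parents") <- parents
  x
}

#' @export
print.bn <- function(x, ...) {
  cat("Discrete Bayesian belief network\n")
  print(x$structure)
  npar <- sum(vapply(x$cpts, function(p) length(p) - length(p) / dim(p)[1L], 1))
  cat("  free CPT parameters:", npar, "\n")
  invisible(x)
}

# state index (0-based) -> linear index into a CPT slice; used everywhere
# a CPT is addressed by (child state, parent states).
cpt_linear_index <- function(cpt, child_state0, parent_states0) {
  d <- dim(cpt)
  idx <- child_state0
  mult <- d[1L]
  if (length(d) > 1L) {
    for (j in seq_along(parent_states0)) {
      idx <- idx + parent_states0[[j]] * mult
      mult <- mult * d[j + 1L]
    }
  }
  idx + 1L
}

#' Probability of a complete assignment
#'
#' Computes the joint probability of one full configuration as the product of
#' CPT entries \eqn{\prod_i \theta_i^{jk}}.
#'
#' @param network a [bn].
#' @param assignment named integer vector covering every variable, with
#'   0-based state indices.
#' @return A probability in `[0, 1]`.
#' @export
joint_probability <- function(network, assignment) {
  vn <- variable_names(network$structure)
  miss <- setdiff(vn, names(assignment))
  if (length(miss))
    stop("assignment is missing variables: ", paste(miss, collapse = ", "))
  p <- 1
  for (v in vn) {
    cpt <- network$cpts[[v]]
    pa <- attr(cpt, "parents")
    check_state_range(network$structure, v, assignment[[v]])
    i <- cpt_linear_index(cpt, assignment[[v]],
                          as.integer(assignment[pa]))
    p <- p * cpt[i]
  }
  unname(p)
}

check_state_range <- function(structure, v, s) {
  r <- length(structure$vars[[v]])
  if (!is.finite(s) || s != as.integer(s) || s < 0L || s >= r)
    stop("state ", s, " out of range for variable '", v, "' (0..", r - 1L, ")")
  invisible(TRUE)
}
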