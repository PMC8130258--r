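#' Exact posterior queries on a Bayesian belief network
#'
#' `posterior()` computes the exact conditional distribution of one target
#' variable given evidence on any other variables, by variable elimination
#' with a min-fill elimination order. `enumerate_posterior()` computes the
#' same quantity by brute-force summation of the joint over all completions
#' and serves as the reference oracle; the two must agree to numerical
#' precision. `map_predict()` returns the posterior mode, with ties broken
#' toward the lower state index.
#'
#' @param network a [bn].
#' @param target a variable name.
#' @param evidence named integer vector of observed 0-based state indices;
#'   must not include `target`. May be empty.
#' @return `posterior()` and `enumerate_posterior()`: an object of class
#'   `bn_posterior` — a list with `variable` and `prob` (named probability
#'   vector over the target's states, summing to 1). `map_predict()`: a
#'   0-based state index.
#' @examples
#' s <- bn_structure(c(A = 2, B = 2), list(c("A", "B")))
#' net <- bn(s, list(A = make_cpt(s, "A", c(.3, .7)),
#'                   B = make_cpt(s, "B", c(.9, .1, .2, .8))))
#' posterior(net, "B", c(A = 1))$prob
#' @export
posterior <- function(network, target, evidence = NULL) {
  ev <- check_evidence(network, target, evidence)
  factors <- lapply(network$cpts, cpt_factor)
  factors <- lapply(factors, reduce_factor, ev = ev)
  elim <- setdiff(unique(unlist(lapply(factors, `[[`, "vars"))), target)
  factors <- eliminate_all(factors, elim, network$structure)
  res <- Reduce(factor_product, factors)
  if (!identical(res$vars, target)) {
    # only possible if target dropped out entirely (no factor mentions it)
    stop("internal error: elimination did not isolate the target")
  }
  z <- sum(res$val)
  if (!is.finite(z) || z <= 0) stop("impossible evidence: P(evidence) = 0")
  new_posterior(target, res$val / z, network$structure)
}

#' @rdname posterior
#' @param max_cells guard on the joint table size for enumeration.
#' @export
enumerate_posterior <- function(network, target, evidence = NULL,
                                max_cells = 1e7) {
  ev <- check_evidence(network, target, evidence)
  str <- network$structure
  vn <- variable_names(str)
  free <- setdiff(vn, names(ev))
  card <- vapply(str$vars[free], length, 1L)
  if (prod(card) > max_cells)
    stop("state space too large to enumerate (", prod(card), " cells)")
  grid <- as.matrix(expand.grid(lapply(card, function(r) 0:(r - 1L)),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- free
  full <- matrix(0L, nrow(grid), length(vn), dimnames = list(NULL, vn))
  full[, free] <- grid
  if (length(ev)) full[, names(ev)] <- matrix(rep(as.integer(ev),
                                                  each = nrow(grid)),
                                              nrow = nrow(grid))
  p <- rep(1, nrow(grid))
  for (v in vn) {
    cpt <- network$cpts[[v]]
    pa <- attr(cpt, "parents")
    idx <- linear_index_rows(cpt, full[, v], full[, pa, drop = FALSE])
    p <- p * cpt[idx]
  }
  tgt <- full[, target]
  r <- length(str$vars[[target]])
  marg <- vapply(0:(r - 1L), function(s) sum(p[tgt == s]), 1)
  z <- sum(marg)
  if (!is.finite(z) || z <= 0) stop("impossible evidence: P(evidence) = 0")
  new_posterior(target, marg / z, str)
}

#' @rdname posterior
#' @export
map_predict <- function(network, target, evidence = NULL) {
  pr <- posterior(network, target, evidence)$prob
  unname(which.max(pr) - 1L)  # first max: ties break toward the lower state
}

new_posterior <- function(target, prob, structure) {
  structure(list(variable = target,
                 prob = stats::setNames(as.numeric(prob),
                                        structure$vars[[target]])),
            class = "bn_posterior")
}

#' @export
print.bn_posterior <- function(x, ...) {
  cat("Posterior for", x$variable, "\n")
  print(round(x$prob, 6))
  invisible(x)
}

check_evidence <- function(network, target, evidence) {
  str <- network$structure
  vn <- variable_names(str)
  if (!(target %in% vn)) stop("unknown variable: ", target)
  if (is.null(evidence) || !length(evidence))
    return(stats::setNames(integer(0), character(0)))
  if (is.null(names(evidence)) || any(!nzchar(names(evidence))))
    stop("evidence must be a named vector")
  unknown <- setdiff(names(evidence), vn)
  if (length(unknown)) stop("unknown variable: ", paste(unknown, collapse = ", "))
  if (target %in% names(evidence))
    stop("target '", target, "' must not appear in its own evidence")
  if (anyDuplicated(names(evidence))) stop("variable assigned twice in evidence")
  ev <- vapply(evidence, as.integer, 1L)
  for (v in names(ev)) check_state_range(str, v, ev[[v]])
  ev
}

## ---- factor algebra (column-major, vars[1] fastest) ----------------------

cpt_factor <- function(cpt) {
  list(vars = c(attr(cpt, "variable"), attr(cpt, "parents")),
       card = as.integer(dim(cpt)),
       val = as.numeric(cpt))
}

reduce_factor <- function(f, ev) {
  hit <- intersect(f$vars, names(ev))
  if (!length(hit)) return(f)
  idx <- lapply(seq_along(f$vars), function(i) {
    v <- f$vars[[i]]
    if (v %in% hit) ev[[v]] + 1L else seq_len(f$card[[i]])
  })
  a <- array(f$val, dim = f$card)
  val <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  keep <- !(f$vars %in% hit)
  list(vars = f$vars[keep], card = f$card[keep], val = as.numeric(val))
}

factor_product <- function(f1, f2) {
  if (!length(f1$vars)) return(list(vars = f2$vars, card = f2$card,
                                    val = f2$val * prod(f1$val, 1)))
  if (!length(f2$vars)) return(list(vars = f1$vars, card = f1$card,
                                    val = f1$val * prod(f2$val, 1)))
  vars <- union(f1$vars, f2$vars)
  card <- integer(length(vars))
  card[match(f1$vars, vars)] <- f1$card
  card[match(f2$vars, vars)] <- f2$card
  val <- expand_to(f1, vars, card) * expand_to(f2, vars, card)
  list(vars = vars, card = card, val = val)
}

# values of factor f laid out on the full grid over 'vars' (column-major)
expand_to <- function(f, vars, card) {
  n <- prod(card)
  if (!length(f$vars)) return(rep(prod(f$val, 1), n))
  cell <- 0:(n - 1)
  idx <- numeric(n)
  stride <- 1
  pos <- match(f$vars, vars)
  fstride <- cumprod(c(1, f$card[-length(f$card)]))
  lin <- rep(1, n)
  pre <- cumprod(c(1, card[-length(card)]))
  for (j in seq_along(f$vars)) {
    k <- pos[[j]]
    digit <- (cell %/% pre[[k]]) %% card[[k]]
    lin <- lin + digit * fstride[[j]]
  }
  f$val[lin]
}

marginalize_out <- function(f, v) {
  i <- match(v, f$vars)
  if (is.na(i)) return(f)
  a <- array(f$val, dim = f$card)
  keep <- setdiff(seq_along(f$vars), i)
  if (!length(keep)) {
    return(list(vars = character(0), card = integer(0), val = sum(a)))
  }
  val <- apply(a, keep, sum)
  list(vars = f$vars[keep], card = f$card[keep], val = as.numeric(val))
}

# eliminate the given variables, choosing at each step the variable whose
# elimination adds the fewest fill edges to the interaction graph (min-fill)
eliminate_all <- function(factors, elim, structure) {
  while (length(elim)) {
    v <- pick_min_fill(factors, elim)
    involved <- vapply(factors, function(f) v %in% f$vars, TRUE)
    prod_f <- Reduce(factor_product, factors[involved])
    factors <- c(factors[!involved], list(marginalize_out(prod_f, v)))
    elim <- setdiff(elim, v)
  }
  factors
}

pick_min_fill <- function(factors, elim) {
  scopes <- lapply(factors, `[[`, "vars")
  best <- elim[[1L]]; best_fill <- Inf
  for (v in elim) {
    nb <- setdiff(unique(unlist(scopes[vapply(scopes, function(s) v %in% s, TRUE)])), v)
    # fill edges = pairs of neighbours not already sharing a factor
    fill <- 0L
    if (length(nb) > 1L) {
      for (i in seq_len(length(nb) - 1L)) for (j in (i + 1L):length(nb)) {
        together <- any(vapply(scopes, function(s)
          nb[[i]] %in% s && nb[[j]] %in% s, TRUE))
        if (!together) fill <- fill + 1L
      }
    }
    if (fill < best_fill) { best_fill <- fill; best <- v }
  }
  best
}

## ---- vectorised full-evidence prediction ---------------------------------

# 1-based linear indices into a CPT for row-wise (child state, parent states)
linear_index_rows <- function(cpt, child0, parents0) {
  d <- dim(cpt)
  idx <- as.numeric(child0)
  mult <- d[1L]
  if (length(d) > 1L) {
    for (j in seq_len(ncol(parents0))) {
      idx <- idx + as.numeric(parents0[, j]) * mult
      mult <- mult * d[j + 1L]
    }
  }
  as.integer(idx + 1)
}

#' Posterior of one variable given complete evidence, for many records
#'
#' Computes, for every row of a complete data table, the exact posterior of
#' `target` given all remaining variables as evidence. Because the evidence
#' covers the target's whole Markov blanket, the posterior reduces to the
#' product of the target's own CPT entry and its children's CPT entries,
#' which is evaluated vectorised over rows; the result is identical to
#' calling [posterior()] row by row.
#'
#' @param network a [bn].
#' @param target the predicted variable.
#' @param data a data.frame of 0-based integer state columns including every
#'   network variable (the `target` column, if present, is ignored as
#'   evidence).
#' @return A numeric matrix, rows = records, columns = target states.
#' @export
posterior_given_rest <- function(network, target, data) {
  str <- network$structure
  vn <- variable_names(str)
  miss <- setdiff(vn, names(data))
  if (length(miss)) stop("data is missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(data)
  r <- length(str$vars[[target]])
  ch <- bn_children(str, target)
  logp <- matrix(0, n, r)
  for (s in 0:(r - 1L)) {
    acc <- rep(0, n)
    for (v in c(target, ch)) {
      cpt <- network$cpts[[v]]
      pa <- attr(cpt, "parents")
      child0 <- if (v == target) rep(s, n) else data[[v]]
      pmat <- matrix(0L, n, length(pa))
      for (j in seq_along(pa))
        pmat[, j] <- if (pa[[j]] == target) rep(s, n) else data[[pa[[j]]]]
      acc <- acc + log(cpt[linear_index_rows(cpt, child0, pmat)])
    }
    logp[, s + 1L] <- acc
  }
  m <- apply(logp, 1L, max)
  if (any(!is.finite(m))) stop("impossible evidence: P(evidence) = 0 for some row")
  w <- exp(logp - m)
  out <- w / rowSums(w)
  colnames(out) <- str$vars[[target]]
  out
}
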