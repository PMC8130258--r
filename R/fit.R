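#' Cross-tabulated state counts for one variable
#'
#' Exact counts n_jk of variable state j under each parent configuration k,
#' with configurations absent from the data kept as zeros.
#'
#' @param data a data.frame of 0-based integer state columns.
#' @param variable the child variable name.
#' @param parents ordered character vector of parent names (may be empty).
#' @param cardinalities named integer vector giving each column's number of
#'   states; defaults to `max(column) + 1` observed per column.
#' @return An array of counts with the child's states on the first dimension
#'   and one dimension per parent, plus attributes `variable`, `parents` and
#'   `margins` (the per-configuration totals n_k).
#' @export
state_counts <- function(data, variable, parents = character(0),
                         cardinalities = NULL) {
  cols <- c(variable, parents)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  card <- integer(length(cols))
  for (i in seq_along(cols)) {
    v <- cols[[i]]
    x <- data[[v]]
    if (anyNA(x)) stop("missing value in column '", v, "' at row ",
                       which(is.na(x))[1L])
    if (length(x) && (any(x != floor(x)) || any(x < 0)))
      stop("column '", v, "' must hold non-negative integer state indices (row ",
           which(x != floor(x) | x < 0)[1L], ")")
    r <- if (!is.null(cardinalities)) {
      if (is.na(cardinalities[v])) stop("no cardinality given for '", v, "'")
      as.integer(cardinalities[[v]])
    } else max(2L, if (length(x)) as.integer(max(x)) + 1L else 2L)
    bad <- which(x >= r)
    if (length(bad))
      stop("value ", x[bad[1L]], " out of range for column '", v,
           "' at row ", bad[1L])
    card[[i]] <- r
  }
  n <- nrow(data)
  counts <- if (n == 0L) integer(prod(card)) else {
    idx <- rep(0, n)
    mult <- 1
    for (i in seq_along(cols)) {
      idx <- idx + as.numeric(data[[cols[[i]]]]) * mult
      mult <- mult * card[[i]]
    }
    tabulate(as.integer(idx) + 1L, nbins = prod(card))
  }
  dim(counts) <- unname(card)
  margins <- if (length(card) > 1L) apply(counts, seq_along(card)[-1L], sum)
             else sum(counts)
  attr(counts, "variable") <- variable
  attr(counts, "parents") <- parents
  attr(counts, "margins") <- margins
  counts
}

#' Fit all conditional probability tables by MAP with add-one smoothing
#'
#' Estimates each variable's CPT as the maximum a posteriori value under a
#' multinomial likelihood with a Dirichlet prior equivalent to add-one
#' smoothing:
#' \deqn{\hat\theta_i^{jk} = (n_{jk} + c) / (n_k + r_i c),}
#' with pseudocount `c` (default 1, i.e. add-one) and `r_i` the cardinality
#' of variable i. Smoothing keeps every CPT entry strictly positive even for
#' parent configurations never observed.
#'
#' @param structure a valid [bn_structure].
#' @param data a complete data.frame of 0-based integer state columns
#'   covering every structure variable.
#' @param pseudocount Dirichlet pseudocount, > 0.
#' @return A fitted [bn].
#' @examples
#' s <- bn_structure(c(A = 2))
#' fit_cpts(s, data.frame(A = c(0, 0, 0, 1)))$cpts$A  # (4/6, 2/6)
#' @export
fit_cpts <- function(structure, data, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  vn <- variable_names(structure)
  miss <- setdiff(vn, names(data))
  if (length(miss))
    stop("data is missing structure variables: ", paste(miss, collapse = ", "))
  card <- vapply(structure$vars, length, 1L)
  cpts <- vector("list", length(vn))
  names(cpts) <- vn
  for (v in vn) {
    pa <- bn_parents(structure, v)
    cnt <- state_counts(data, v, pa, cardinalities = card)
    r <- card[[v]]
    d <- dim(cnt)
    nk <- attr(cnt, "margins")
    denom <- if (length(d) > 1L) rep(as.numeric(nk), each = r)
             else rep(sum(cnt), r)
    theta <- (as.numeric(cnt) + pseudocount) / (denom + r * pseudocount)
    cpts[[v]] <- check_cpt(theta, v, pa, structure)
  }
  bn(structure, cpts)
}
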