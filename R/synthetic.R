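#' Default household variables and causal ordering
#'
#' The fifteen household variables modelled: child grant status (CGS),
#' education level (EdL), employment level (EmL), household head gender
#' (HHG), level of local vegetation (LLV), number of dependants (ND),
#' number of working-age adults (NWAA), receipt of communal aid (RCA),
#' refugee status (RS), selling of crops and livestock (SCL),
#' socio-economic status (SES), use of crops and livestock (UCL), use of
#' wild foods (UWF), water access (WA), and the binary outcome food
#' security (FS; state 0 = food secure, state 1 = food insecure).
#'
#' The default level assignment places demographic and environmental
#' background variables first, income-channel variables next, household
#' resources third, crop marketing fourth, and food security alone in the
#' last level (it causes none of the other variables). The assignment and
#' state cardinalities are plausible defaults for a rural HDSS population,
#' not a claim about any particular surveyed population, and both are
#' configurable.
#'
#' @return `agincourt_ordering()`: a [causal_ordering];
#'   `agincourt_cardinalities()`: a named integer vector of state counts.
#' @export
agincourt_ordering <- function() {
  causal_ordering(list(
    c("HHG", "RS", "EdL", "NWAA", "ND", "LLV", "WA"),
    c("EmL", "CGS", "RCA"),
    c("SES", "UCL", "UWF"),
    "SCL",
    "FS"
  ))
}

#' @rdname agincourt_ordering
#' @export
agincourt_cardinalities <- function() {
  c(HHG = 2L, RS = 2L, EdL = 4L, NWAA = 3L, ND = 4L, LLV = 3L, WA = 3L,
    EmL = 3L, CGS = 2L, RCA = 2L, SES = 4L, UCL = 3L, UWF = 2L, SCL = 2L,
    FS = 2L)
}

#' Configuration for the synthetic household-data generator
#'
#' @param n_households number of households to sample by default.
#' @param seed integer seed; the whole generated network is a deterministic
#'   function of the configuration.
#' @param cardinalities named integer state counts (2-4; outcome binary).
#' @param ordering a [causal_ordering]; outcome alone in the last level.
#' @param density probability of an edge between each earlier-level /
#'   later-level variable pair.
#' @param strength scale of the monotone ordinal effect each edge exerts on
#'   its child (log-odds units across the state range).
#' @param concentration Dirichlet concentration of CPT rows around their
#'   monotone mean; larger = less row-level noise.
#' @param insecure_rate target marginal probability of the food-insecure
#'   state, matched by tilting the outcome CPT.
#' @param max_parents cap on parents per variable, keeping CPTs estimable
#'   at census-scale sample sizes.
#' @return A list of class `fsbn_genconfig`.
#' @export
generator_config <- function(n_households = 11739L, seed = 1L,
                             cardinalities = agincourt_cardinalities(),
                             ordering = agincourt_ordering(),
                             density = 0.2, strength = 2,
                             concentration = 50, insecure_rate = 0.10,
                             max_parents = 4L) {
  if (any(cardinalities < 2L)) stop("cardinalities must be >= 2")
  if (!(density >= 0 && density <= 1)) stop("density must be in [0, 1]")
  if (!(insecure_rate > 0 && insecure_rate < 1))
    stop("insecure_rate must be in (0, 1)")
  check_ordering_covers(ordering, names(cardinalities))
  last <- ordering$levels[[length(ordering$levels)]]
  if (length(last) != 1L)
    stop("the outcome must occupy the last ordering level alone")
  if (cardinalities[[last]] != 2L) stop("the outcome must be binary")
  structure(list(n_households = as.integer(n_households),
                 seed = as.integer(seed),
                 cardinalities = cardinalities, ordering = ordering,
                 density = density, strength = strength,
                 concentration = concentration,
                 insecure_rate = insecure_rate,
                 max_parents = as.integer(max_parents),
                 outcome = last),
            class = "fsbn_genconfig")
}

#' Generate a ground-truth Agincourt-like network
#'
#' Builds a random DAG over the configured household variables respecting
#' the level-wise causal ordering (edges only run from earlier to later
#' levels; every non-root-level variable is guaranteed at least one parent,
#' so the outcome always has one), then fills the CPTs with monotone
#' ordinal-logit rows: each edge carries a signed effect, a child's row
#' mean is the softmax of base intercepts plus the summed parent effects
#' interacting with the child's ordinal score, and the realised row is a
#' Dirichlet draw around that mean. Monotone dependencies are what ordinal
#' household data exhibit and what the Jonckheere-Terpstra machinery
#' targets. Finally the outcome CPT's log-odds are tilted by root-finding
#' so the exact marginal probability of food insecurity matches the
#' configured rate.
#'
#' @param config a [generator_config()].
#' @return A ground-truth [bn], deterministic given the config.
#' @export
make_agincourt_like_network <- function(config = generator_config()) {
  with_seed(config$seed, build_truth_network(config))
}

build_truth_network <- function(config) {
  card <- config$cardinalities
  vn <- names(card)
  rk <- ordering_rank(config$ordering)
  lvl <- level_of(config$ordering)
  edges <- list()
  for (v in vn) {
    earlier <- vn[lvl[vn] < lvl[[v]]]
    if (!length(earlier)) next
    pa <- earlier[stats::runif(length(earlier)) < config$density]
    if (!length(pa)) pa <- sample(earlier, 1L)
    if (length(pa) > config$max_parents)
      pa <- sample(pa, config$max_parents)
    for (p in pa) edges[[length(edges) + 1L]] <- c(p, v)
  }
  str <- bn_structure(card, edges)
  if (!length(bn_parents(str, config$outcome)))
    stop("generated outcome has no parents")  # unreachable: parent forced
  cpts <- stats::setNames(vector("list", length(vn)), vn)
  for (v in topological_order(str)) {
    cpts[[v]] <- random_monotone_cpt(str, v, config)
  }
  net <- bn(str, cpts)
  tilt_outcome_marginal(net, config$outcome, config$insecure_rate)
}

level_of <- function(ordering) {
  lv <- integer(0)
  for (i in seq_along(ordering$levels))
    lv <- c(lv, stats::setNames(rep(i, length(ordering$levels[[i]])),
                                ordering$levels[[i]]))
  lv
}

# ordinal score of each state, spread over [-1, 1]
state_scores <- function(r) if (r == 1L) 0 else seq(-1, 1, length.out = r)

random_monotone_cpt <- function(str, v, config) {
  r <- length(str$vars[[v]])
  pa <- bn_parents(str, v)
  pcard <- vapply(str$vars[pa], length, 1L)
  a <- stats::rnorm(r, 0, 0.6)                  # base intercepts
  beta <- if (length(pa))
    sample(c(-1, 1), length(pa), replace = TRUE) * stats::runif(length(pa), 0.8, 1.6)
  else numeric(0)
  tj <- state_scores(r)
  nconf <- prod(pcard)
  vals <- numeric(r * max(1L, nconf))
  confs <- if (length(pa))
    as.matrix(expand.grid(lapply(pcard, function(q) 0:(q - 1L)),
                          KEEP.OUT.ATTRS = FALSE))
  else matrix(0L, 1L, 0L)
  for (k in seq_len(nrow(confs))) {
    eta <- 0
    for (j in seq_along(pa))
      eta <- eta + beta[[j]] * state_scores(pcard[[j]])[confs[k, j] + 1L]
    # saturating link keeps rows informative but bounded away from 0/1
    m <- exp(a + config$strength * tanh(eta) * tj)
    m <- m / sum(m)
    g <- stats::rgamma(r, shape = config$concentration * m, rate = 1)
    while (sum(g) <= 0) g <- stats::rgamma(r, shape = config$concentration * m,
                                           rate = 1)
    vals[(k - 1L) * r + seq_len(r)] <- g / sum(g)
  }
  check_cpt(vals, v, pa, str)
}

# shift the outcome CPT on the log-odds scale so that the exact marginal
# probability of state 1 equals the target rate
tilt_outcome_marginal <- function(net, outcome, rate) {
  base <- net$cpts[[outcome]]
  p1 <- as.numeric(base)[c(FALSE, TRUE)]  # P(outcome = 1 | k), binary
  p1 <- pmin(pmax(p1, 1e-9), 1 - 1e-9)
  apply_delta <- function(delta) {
    q1 <- stats::plogis(stats::qlogis(p1) + delta)
    vals <- as.numeric(rbind(1 - q1, q1))
    net$cpts[[outcome]] <- check_cpt(vals, outcome,
                                     attr(base, "parents"), net$structure)
    net
  }
  f <- function(delta) posterior(apply_delta(delta), outcome)$prob[[2L]] - rate
  sol <- stats::uniroot(f, c(-12, 12), tol = 1e-10)
  apply_delta(sol$root)
}

#' Forward-sample a table of synthetic households
#'
#' Ancestral sampling in topological order; every row is a complete
#' household record of 0-based integer state indices, columns in the
#' network's declared variable order.
#'
#' @param network a [bn].
#' @param n number of households (>= 0).
#' @param seed integer seed; identical seeds give identical tables.
#' @return A data.frame with one integer column per variable.
#' @export
sample_households <- function(network, n, seed = 1L) {
  stopifnot(n >= 0)
  vn <- variable_names(network$structure)
  out <- as.data.frame(stats::setNames(rep(list(integer(n)), length(vn)), vn))
  if (n == 0L) return(out)
  with_seed(seed, {
    for (v in topological_order(network$structure)) {
      cpt <- network$cpts[[v]]
      pa <- attr(cpt, "parents")
      r <- dim(cpt)[1L]
      pmat <- if (length(pa)) as.matrix(out[pa]) else matrix(0L, n, 0L)
      probs <- matrix(0, n, r)
      for (s in 0:(r - 1L))
        probs[, s + 1L] <- cpt[linear_index_rows(cpt, rep(s, n), pmat)]
      u <- stats::runif(n)
      cum <- probs
      for (s in 2:r) cum[, s] <- cum[, s - 1L] + probs[, s]
      cum[, r] <- 1  # guard against rounding in the last bin
      out[[v]] <- as.integer(rowSums(u > cum))
    }
  })
  out
}

#' Merge rare ordinal states
#'
#' Coarse-grains one ordinal column by iteratively merging the rarest state
#' whose frequency falls below `min_frequency` into its less-rare ordinal
#' neighbour (ties broken toward the interior of the state range), until
#' every remaining state meets the threshold or only two states remain.
#' Retained states keep their ordinal order and are relabelled 0, 1, ...
#'
#' @param data a data.frame of 0-based integer state columns.
#' @param variable the column to coarsen.
#' @param min_frequency the frequency threshold in (0, 1).
#' @param n_states optionally the column's declared cardinality (defaults
#'   to `max(column) + 1`).
#' @return A list with `data` (the recoded table) and `map` (integer
#'   vector; `map[old_state + 1] = new_state`).
#' @export
coarsen_rare_states <- function(data, variable, min_frequency,
                                n_states = NULL) {
  if (!(min_frequency > 0 && min_frequency < 1))
    stop("min_frequency must be in (0, 1)")
  x <- data[[variable]]
  if (is.null(x)) stop("missing column: ", variable)
  if (anyNA(x) || any(x != floor(x)) || any(x < 0))
    stop("column '", variable, "' is not ordinal 0-based integer")
  k0 <- if (is.null(n_states)) as.integer(max(x)) + 1L else as.integer(n_states)
  if (k0 < 2L) stop("need at least 2 states")
  map <- seq_len(k0) - 1L          # old -> current
  n <- length(x)
  repeat {
    k <- max(map) + 1L
    freq <- tabulate(map[x + 1L] + 1L, nbins = k) / n
    low <- which(freq < min_frequency)
    if (!length(low) || k <= 2L) break
    i <- low[which.min(freq[low])] - 1L          # rarest offending state
    nb <- intersect(c(i - 1L, i + 1L), 0:(k - 1L))
    if (length(nb) == 2L) {
      j <- if (freq[nb[1L] + 1L] > freq[nb[2L] + 1L]) nb[1L]
           else if (freq[nb[2L] + 1L] > freq[nb[1L] + 1L]) nb[2L]
           else nb[which.min(abs(nb - (k - 1L) / 2))]  # tie: toward interior
    } else j <- nb[[1L]]
    # merge current state i into j, then compress labels preserving order
    map[map == i] <- j
    lab <- sort(unique(map))
    map <- match(map, lab) - 1L
  }
  data[[variable]] <- map[x + 1L]
  list(data = data, map = map)
}
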