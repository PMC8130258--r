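# Shared fixtures and independently-coded oracles. Everything here is kept
# deliberately naive: brute force, explicit loops, no reuse of package
# internals beyond the public constructors.

# random DAG on n nodes: edges only from earlier to later in a random
# permutation, kept with probability p
random_dag <- function(n_nodes, p = 0.35, max_states = 3L) {
  nm <- LETTERS[seq_len(n_nodes)]
  ord <- sample(nm)
  edges <- list()
  for (i in seq_len(n_nodes - 1L)) for (j in (i + 1L):n_nodes) {
    if (runif(1) < p) edges[[length(edges) + 1L]] <- c(ord[i], ord[j])
  }
  card <- stats::setNames(sample(2:max_states, n_nodes, replace = TRUE), nm)
  bn_structure(card, edges)
}

# strictly positive random CPTs (Dirichlet rows)
random_cpts <- function(str, conc = 1) {
  vn <- names(str$vars)
  cpts <- lapply(vn, function(v) {
    pa <- bn_parents(str, v)
    card <- c(lengths(str$vars[v]), lengths(str$vars[pa]))
    r <- card[[1L]]
    vals <- numeric(prod(card))
    for (k in seq_len(prod(card) / r)) {
      g <- rgamma(r, conc) + 1e-3
      vals[(k - 1L) * r + seq_len(r)] <- g / sum(g)
    }
    make_cpt(str, v, vals)
  })
  names(cpts) <- vn
  bn(str, cpts)
}

# ---- d-separation oracle: Bayes-ball reachability ------------------------
# Returns TRUE iff a and b are d-separated given cond. Independent of the
# package's moral-ancestral-graph implementation.
bayes_ball_dsep <- function(str, a, b, cond = character(0)) {
  e <- str$edges
  pa_of <- function(v) e[e[, 2L] == v, 1L]
  ch_of <- function(v) e[e[, 1L] == v, 2L]
  anc <- cond
  frontier <- cond
  while (length(frontier)) {
    newpa <- setdiff(unique(unlist(lapply(frontier, pa_of))), anc)
    anc <- c(anc, newpa)
    frontier <- newpa
  }
  # states: (node, direction) with direction "up" (from child) / "down"
  visited <- character(0)
  queue <- list(c(a, "up"))
  while (length(queue)) {
    st <- queue[[1L]]; queue <- queue[-1L]
    key <- paste(st, collapse = "|")
    if (key %in% visited) next
    visited <- c(visited, key)
    v <- st[[1L]]; dir <- st[[2L]]
    in_cond <- v %in% cond
    if (!in_cond && v == b) return(FALSE)
    if (dir == "up" && !in_cond) {
      for (p in pa_of(v)) queue <- c(queue, list(c(p, "up")))
      for (c2 in ch_of(v)) queue <- c(queue, list(c(c2, "down")))
    } else if (dir == "down") {
      if (!in_cond) for (c2 in ch_of(v)) queue <- c(queue, list(c(c2, "down")))
      if (v %in% anc) for (p in pa_of(v)) queue <- c(queue, list(c(p, "up")))
    }
  }
  TRUE
}

# ---- exact joint and conditional mutual information ----------------------
# full joint table of a small network as a data.frame of states plus p
enumerate_joint <- function(net) {
  str <- net$structure
  vn <- names(str$vars)
  card <- vapply(str$vars, length, 1L)
  grid <- expand.grid(lapply(card, function(r) 0:(r - 1L)),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- vn
  grid$p <- apply(grid, 1L, function(row) {
    joint_probability(net, stats::setNames(as.integer(row), vn))
  })
  grid
}

# I(A;B|C) in bits from an enumerated joint
cmi_from_joint <- function(joint, a, b, cond) {
  key <- function(cols) {
    if (!length(cols)) return(rep("", nrow(joint)))
    do.call(paste, c(joint[cols], sep = "|"))
  }
  kc <- key(cond); ka <- key(c(a, cond)); kb <- key(c(b, cond))
  kab <- key(c(a, b, cond))
  pc <- tapply(joint$p, kc, sum); pa <- tapply(joint$p, ka, sum)
  pb <- tapply(joint$p, kb, sum); pab <- tapply(joint$p, kab, sum)
  cells <- !duplicated(kab)
  s <- 0
  for (i in which(cells)) {
    pj <- pab[[match(kab[i], names(pab))]]
    if (pj <= 0) next
    s <- s + pj * log2(pj * pc[[match(kc[i], names(pc))]] /
                         (pa[[match(ka[i], names(pa))]] *
                            pb[[match(kb[i], names(pb))]]))
  }
  s
}

# ---- brute-force Jonckheere-Terpstra -------------------------------------
# pairwise-comparison T over all observation pairs in groups x (no strata)
jt_brute_T <- function(x, y) {
  n <- length(x)
  t <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (x[i] < x[j]) t <- t + (y[i] < y[j]) + 0.5 * (y[i] == y[j])
  }
  t
}

# skeleton F1 between two edge matrices (unordered pairs)
skeleton_f1 <- function(learned, truth) {
  key <- function(e) if (nrow(e)) apply(e, 1L, function(r)
    paste(sort(r), collapse = "|")) else character(0)
  L <- key(learned); Tr <- key(truth)
  tp <- length(intersect(L, Tr))
  if (!length(L) || !length(Tr) || tp == 0L) return(0)
  prec <- tp / length(L); rec <- tp / length(Tr)
  2 * prec * rec / (prec + rec)
}

edge_m <- function(net_or_str) {
  s <- if (inherits(net_or_str, "bn")) net_or_str$structure else net_or_str
  s$edges
}
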