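# confounded toy network Z -> X -> Y, Z -> Y
confounder_net <- function() {
  s <- bn_structure(c(Z = 2, X = 2, Y = 2),
                    list(c("Z", "X"), c("Z", "Y"), c("X", "Y")))
  bn(s, list(
    Z = make_cpt(s, "Z", c(0.4, 0.6)),
    X = make_cpt(s, "X", c(0.8, 0.2, 0.3, 0.7)),
    Y = make_cpt(s, "Y", as.numeric(rbind(c(0.9, 0.6, 0.7, 0.2),
                                          1 - c(0.9, 0.6, 0.7, 0.2))))
  ))
}

test_that("surgery removes incoming edges and fixes the intervened state", {
  net <- confounder_net()
  cut <- do_surgery(net, c(X = 1))
  expect_false(any(cut$structure$edges[, 2] == "X"))
  expect_equal(as.numeric(cut$cpts$X), c(0, 1))
  # locality: untouched CPTs bit-identical
  expect_identical(as.numeric(cut$cpts$Z), as.numeric(net$cpts$Z))
  expect_identical(as.numeric(cut$cpts$Y), as.numeric(net$cpts$Y))
  expect_error(do_surgery(net, c(Q = 1)), "unknown variable")
  expect_error(interventional_query(net, "X", c(X = 1)), "cannot be intervened")
})

test_that("do on a confounded exposure equals the backdoor adjustment", {
  net <- confounder_net()
  for (x in 0:1) {
    got <- interventional_query(net, "Y", c(X = x))$prob
    # adjustment formula sum_z P(Y | x, z) P(z), by enumeration
    pz <- posterior(net, "Z")$prob
    adj <- Reduce(`+`, lapply(0:1, function(z)
      enumerate_posterior(net, "Y", c(X = x, Z = z))$prob * pz[[z + 1]]))
    expect_equal(got, adj, tolerance = 1e-10)
    # and differs from plain conditioning (confounding is real here)
    obs <- posterior(net, "Y", c(X = x))$prob
    expect_gt(max(abs(got - obs)), 1e-3)
  }
})

test_that("do on a parentless variable equals conditioning", {
  net <- confounder_net()
  expect_equal(interventional_query(net, "Y", c(Z = 1))$prob,
               posterior(net, "Y", c(Z = 1))$prob, tolerance = 1e-12)
})

test_that("interventions on random networks match backdoor enumeration", {
  set.seed(271)
  for (rep in 1:12) {
    net <- random_cpts(random_dag(sample(4:6, 1), p = 0.4))
    vn <- names(net$structure$vars)
    x <- sample(vn, 1)
    y <- sample(setdiff(vn, x), 1)
    xs <- sample(seq_along(net$structure$vars[[x]]) - 1L, 1)
    got <- interventional_query(net, y, stats::setNames(xs, x))$prob
    # oracle 1: enumerate the truncated factorisation directly
    cut <- do_surgery(net, stats::setNames(xs, x))
    want <- enumerate_posterior(cut, y, stats::setNames(xs, x))$prob
    expect_equal(got, want, tolerance = 1e-10)
    # oracle 2: parent-set backdoor adjustment in the ORIGINAL network,
    # sum_pa P(pa) P(y | x, pa), valid whenever y is not a parent of x
    pa <- bn_parents(net$structure, x)
    if (!(y %in% pa)) {
      joint <- enumerate_joint(net)
      if (length(pa)) {
        key <- do.call(paste, c(joint[pa], sep = "|"))
        w <- tapply(joint$p, key, sum)
        confs <- unique(joint[pa])
        adj <- 0
        for (r in seq_len(nrow(confs))) {
          ev <- c(stats::setNames(xs, x),
                  stats::setNames(as.integer(confs[r, ]), pa))
          adj <- adj + w[[paste(confs[r, ], collapse = "|")]] *
            enumerate_posterior(net, y, ev)$prob
        }
      } else {
        adj <- enumerate_posterior(net, y, stats::setNames(xs, x))$prob
      }
      expect_equal(unname(got), unname(adj), tolerance = 1e-10)
    }
    # causal irrelevance: no directed path => marginal unchanged
    desc <- character(0); frontier <- x
    while (length(frontier)) {
      nxt <- setdiff(unique(net$structure$edges[
        net$structure$edges[, 1] %in% frontier, 2]), desc)
      desc <- c(desc, nxt); frontier <- nxt
    }
    if (!(y %in% desc))
      expect_equal(got, posterior(net, y)$prob, tolerance = 1e-10)
  }
})

test_that("multi-variable interventions cut all incoming edges at once", {
  net <- confounder_net()
  got <- interventional_query(net, "Y", c(Z = 0, X = 1))$prob
  # with both parents forced, Y follows its CPT column directly
  expect_equal(unname(got), c(0.7, 0.3), tolerance = 1e-12)
})

test_that("sensitivity metrics match brute-force computation from the joint", {
  net <- confounder_net()
  joint <- enumerate_joint(net)
  for (v in c("Z", "X")) {
    mi <- mutual_information_reduction(net, "Y", v)
    expect_equal(mi$I, cmi_from_joint(joint, "Y", v, character(0)),
                 tolerance = 1e-10)
    expect_true(mi$I_over_H >= 0 && mi$I_over_H <= 1)
    # brute-force S2
    pv <- posterior(net, v)$prob
    py <- posterior(net, "Y")$prob
    s2 <- sum(vapply(seq_along(pv) - 1L, function(xx) {
      px <- posterior(net, "Y", stats::setNames(xx, v))$prob
      pv[[xx + 1]] * sum((px - py)^2)
    }, 1))
    expect_equal(expected_change_of_belief(net, "Y", v), s2, tolerance = 1e-10)
  }
})

test_that("disconnected and copying variables bracket the sensitivity range", {
  s <- bn_structure(c(A = 2, FS = 2, D = 2), list(c("A", "FS")))
  net <- bn(s, list(A = make_cpt(s, "A", c(0.5, 0.5)),
                    FS = make_cpt(s, "FS", c(1, 0, 0, 1)),  # FS copies A
                    D = make_cpt(s, "D", c(0.3, 0.7))))
  mi_d <- mutual_information_reduction(net, "FS", "D")
  expect_equal(mi_d$I, 0, tolerance = 1e-12)
  expect_equal(expected_change_of_belief(net, "FS", "D"), 0, tolerance = 1e-12)
  mi_a <- mutual_information_reduction(net, "FS", "A")
  expect_equal(mi_a$I, mi_a$H_target, tolerance = 1e-10)
  expect_equal(mi_a$I_over_H, 1, tolerance = 1e-10)
})

test_that("the sensitivity table is consistent with the individual metrics", {
  set.seed(281)
  net <- random_cpts(random_dag(5, p = 0.4))
  vn <- names(net$structure$vars)
  target <- vn[length(vn)]
  tab <- sensitivity_table(net, target)
  expect_identical(tab$variable, sort(setdiff(vn, target)))
  for (i in seq_len(nrow(tab))) {
    mi <- mutual_information_reduction(net, target, tab$variable[i])
    expect_equal(tab$I[i], mi$I)
    expect_equal(tab$I_over_H[i], mi$I_over_H)
    expect_true(tab$I_over_H[i] >= 0 && tab$I_over_H[i] <= 1)
    expect_equal(tab$S2[i],
                 expected_change_of_belief(net, target, tab$variable[i]))
  }
})
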