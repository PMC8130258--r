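test_that("joint_probability is the product of CPT entries", {
  s1 <- bn_structure(c(A = 2))
  n1 <- bn(s1, list(A = make_cpt(s1, "A", c(0.3, 0.7))))
  expect_equal(joint_probability(n1, c(A = 1)), 0.7)

  s2 <- bn_structure(c(A = 2, B = 2), list(c("A", "B")))
  n2 <- bn(s2, list(A = make_cpt(s2, "A", c(0.5, 0.5)),
                    B = make_cpt(s2, "B", rep(0.5, 4))))
  expect_equal(joint_probability(n2, c(A = 0, B = 1)), 0.25)
  expect_error(joint_probability(n2, c(A = 0)), "missing variables")
})

test_that("the joint normalises to one on random networks", {
  set.seed(71)
  for (rep in 1:5) {
    net <- random_cpts(random_dag(6, p = 0.4))
    expect_equal(sum(enumerate_joint(net)$p), 1, tolerance = 1e-10)
  }
})

test_that("posterior matches enumeration on random networks and queries", {
  set.seed(81)
  for (rep in 1:10) {
    net <- random_cpts(random_dag(sample(4:8, 1), p = 0.4))
    vn <- names(net$structure$vars)
    for (q in 1:10) {
      target <- sample(vn, 1)
      rest <- setdiff(vn, target)
      evn <- sample(rest, sample(0:length(rest), 1))
      ev <- vapply(evn, function(v)
        sample(seq_along(net$structure$vars[[v]]) - 1L, 1), 1L)
      p1 <- posterior(net, target, ev)$prob
      p2 <- enumerate_posterior(net, target, ev)$prob
      expect_equal(p1, p2, tolerance = 1e-10)
      expect_equal(sum(p1), 1, tolerance = 1e-10)
      expect_identical(map_predict(net, target, ev),
                       unname(which.max(p2) - 1L))
    }
  }
})

test_that("no-evidence posterior of a root equals its prior CPT", {
  s <- bn_structure(c(A = 3, B = 2), list(c("A", "B")))
  net <- bn(s, list(A = make_cpt(s, "A", c(0.2, 0.3, 0.5)),
                    B = make_cpt(s, "B", c(0.9, 0.1, 0.5, 0.5, 0.2, 0.8))))
  expect_equal(unname(posterior(net, "A")$prob), c(0.2, 0.3, 0.5))
  # evidence fixing the only parent reads off a CPT column
  expect_equal(unname(posterior(net, "B", c(A = 2))$prob), c(0.2, 0.8))
})

test_that("impossible evidence raises a distinct error", {
  s <- bn_structure(c(A = 2, B = 2), list(c("A", "B")))
  net <- bn(s, list(A = make_cpt(s, "A", c(1, 0)),
                    B = make_cpt(s, "B", c(1, 0, 0, 1))))
  expect_error(posterior(net, "B", c(A = 1)), "impossible evidence")
  # deterministic chain forces a point mass
  expect_equal(unname(posterior(net, "B", c(A = 0))$prob), c(1, 0))
})

test_that("MAP prediction breaks ties toward the lower state", {
  s <- bn_structure(c(A = 2))
  net <- bn(s, list(A = make_cpt(s, "A", c(0.5, 0.5))))
  expect_identical(map_predict(net, "A"), 0L)
  net2 <- bn(s, list(A = make_cpt(s, "A", c(0.1, 0.9))))
  expect_identical(map_predict(net2, "A"), 1L)
})

test_that("posteriors obey the law of total probability", {
  set.seed(91)
  net <- random_cpts(random_dag(5, p = 0.4))
  vn <- names(net$structure$vars)
  a <- vn[1]; b <- vn[2]
  pa_marg <- posterior(net, a)$prob
  pb <- posterior(net, b)$prob
  mix <- Reduce(`+`, lapply(seq_along(pb) - 1L, function(s)
    posterior(net, a, stats::setNames(s, b))$prob * pb[[s + 1L]]))
  expect_equal(mix, pa_marg, tolerance = 1e-10)
})

test_that("evidence that is already certain leaves other posteriors unchanged", {
  # B deterministically copies A, so observing B adds nothing once A is known
  s <- bn_structure(c(A = 2, B = 2, C = 2), list(c("A", "B"), c("A", "C")))
  net <- bn(s, list(A = make_cpt(s, "A", c(0.4, 0.6)),
                    B = make_cpt(s, "B", c(1, 0, 0, 1)),
                    C = make_cpt(s, "C", c(0.7, 0.3, 0.2, 0.8))))
  p1 <- posterior(net, "C", c(A = 1))$prob
  p2 <- posterior(net, "C", c(A = 1, B = 1))$prob
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("posterior_given_rest equals row-by-row posterior calls", {
  set.seed(101)
  net <- random_cpts(random_dag(6, p = 0.4))
  vn <- names(net$structure$vars)
  target <- sample(vn, 1)
  d <- sample_households(net, 25, seed = 5)
  fast <- posterior_given_rest(net, target, d)
  for (i in seq_len(nrow(d))) {
    ev <- unlist(d[i, setdiff(vn, target)])
    slow <- posterior(net, target, ev)$prob
    expect_equal(unname(fast[i, ]), unname(slow), tolerance = 1e-10)
  }
})
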