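ord_abc <- causal_ordering(list("A", "B", "C"))

# sample a strong monotone chain A -> B -> C
chain_data <- function(n, seed) {
  fsbn:::with_seed(seed, {
    a <- sample(0:2, n, replace = TRUE)
    flip <- function(z) ifelse(runif(n) < 0.75, z, sample(0:2, n, replace = TRUE))
    b <- flip(a)
    c <- flip(b)
    data.frame(A = a, B = b, C = c)
  })
}

test_that("mmpc recovers a chain skeleton and drops the indirect edge", {
  d <- chain_data(10000, seed = 151)
  sk <- mmpc_skeleton(d, ord_abc, alpha = 0.05, max_conditioning = 3)
  got <- apply(sk$edges, 1, paste, collapse = "-")
  expect_setequal(got, c("A-B", "B-C"))
})

test_that("empty and invalid inputs are rejected", {
  expect_error(mmpc_skeleton(data.frame(A = integer(0), B = integer(0),
                                        C = integer(0)), ord_abc),
               "empty data")
  d <- chain_data(100, seed = 1)
  expect_error(mmpc_skeleton(d, ord_abc, alpha = 1.5), "alpha")
})

test_that("skeleton learning is invariant to row shuffling", {
  d <- chain_data(3000, seed = 161)
  sk1 <- mmpc_skeleton(d, ord_abc)
  sk2 <- mmpc_skeleton(d[sample(nrow(d)), ], ord_abc)
  expect_identical(sk1$edges, sk2$edges)
})

test_that("orient_edges directs every edge by the ordering and yields a DAG", {
  sk <- structure(list(variables = c(A = 3L, B = 3L, FS = 2L),
                       edges = rbind(c("A", "B"), c("B", "FS"))),
                  class = "bn_skeleton")
  ord <- causal_ordering(list("A", "B", "FS"))
  s <- orient_edges(sk, ord)
  expect_true(validate_dag(s)$ok)
  expect_identical(unname(s$edges[, 1]), c("A", "B"))
  # reversed listing still orients by the ordering: FS last means B -> FS
  sk2 <- structure(list(variables = c(FS = 2L, SES = 3L),
                        edges = rbind(c("FS", "SES"))),
                   class = "bn_skeleton")
  s2 <- orient_edges(sk2, causal_ordering(list("SES", "FS")))
  expect_identical(unname(s2$edges[1, ]), c("SES", "FS"))
})

test_that("the outcome is never a candidate cause but can still gain parents", {
  # FS depends on A; mmpc must attach it through FS's own neighbour search
  d <- chain_data(5000, seed = 171)
  names(d) <- c("A", "B", "FS")
  d$FS <- as.integer(d$FS >= 1)
  ordf <- causal_ordering(list("A", "B", "FS"))
  s <- learn_structure(d, ordf)
  expect_true(validate_dag(s)$ok)
  expect_true(all(s$edges[s$edges[, 1] == "FS", 2] == character(0)))
  expect_true("FS" %in% s$edges[, 2])  # FS has at least one parent
})

test_that("an empty expert prior reproduces the no-prior result", {
  d <- chain_data(2000, seed = 181)
  s0 <- learn_structure(d, ord_abc)
  prior <- bn_structure(c(A = 3, B = 3, C = 3))
  s1 <- learn_structure(d, ord_abc, expert_prior = prior, alpha_keep = 0.2)
  expect_identical(s0$edges, s1$edges)
})

test_that("expert edges follow the lax alpha_keep retention rule", {
  prior <- bn_structure(c(A = 3, B = 3, C = 3), list(c("A", "C")))
  has_ac <- function(st) any(st$edges[, 1] == "A" & st$edges[, 2] == "C")
  # independent columns whose A-C p-value clearly exceeds alpha_keep:
  # the expert edge must be dropped
  d_null <- fsbn:::with_seed(192, data.frame(
    A = sample(0:2, 5000, TRUE), B = sample(0:2, 5000, TRUE),
    C = sample(0:2, 5000, TRUE)))
  expect_gt(jt_ci_test(d_null, "A", "C")$p_value, 0.3)
  expect_false(has_ac(learn_structure(d_null, ord_abc, expert_prior = prior,
                                      alpha_keep = 0.2)))
  # columns whose association lands between alpha and alpha_keep: the edge
  # is kept with the prior but rejected without it
  d_mid <- fsbn:::with_seed(191, data.frame(
    A = sample(0:2, 5000, TRUE), B = sample(0:2, 5000, TRUE),
    C = sample(0:2, 5000, TRUE)))
  p_mid <- jt_ci_test(d_mid, "A", "C")$p_value
  expect_true(p_mid > 0.05 && p_mid < 0.2)
  expect_true(has_ac(learn_structure(d_mid, ord_abc, expert_prior = prior,
                                     alpha_keep = 0.2)))
  expect_false(has_ac(learn_structure(d_mid, ord_abc)))
})

test_that("a prior violating the ordering is rejected before learning", {
  d <- chain_data(100, seed = 1)
  bad <- bn_structure(c(A = 3, B = 3, C = 3), list(c("C", "A")))
  expect_error(learn_structure(d, ord_abc, expert_prior = bad),
               "violates the causal ordering")
})
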