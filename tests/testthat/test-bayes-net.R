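make_chain_data <- function(n = 5000, seed = 1) {
  # a -> b -> c with strong links
  with_seed <- function(s, expr) { set.seed(s); expr }
  with_seed(seed, {
    a <- sample(1:2, n, TRUE)
    b <- ifelse(runif(n) < ifelse(a == 1, 0.9, 0.1), 1L, 2L)
    c_ <- ifelse(runif(n) < ifelse(b == 1, 0.85, 0.15), 1L, 2L)
    data.frame(a = a, b = b, c = c_)
  })
}

test_that("G2 test separates dependence, independence and conditioning", {
  set.seed(2)
  n <- 5000
  ind <- data.frame(a = sample(1:3, n, TRUE), b = sample(1:3, n, TRUE))
  expect_true(ci_test(ind, "a", "b", alpha = 0.05)$independent)

  chain <- make_chain_data()
  expect_false(ci_test(chain, "a", "c", character(0), 0.05)$independent)
  expect_true(ci_test(chain, "a", "c", "b", 0.05)$independent)

  copy <- data.frame(a = ind$a, b = ind$a)
  ct <- ci_test(copy, "a", "b")
  expect_false(ct$independent)
  expect_lt(ct$p_value, 1e-6)
  expect_error(ci_test(ind, "a", "a"), class = "dcbr_argument_error")
})

test_that("small samples default to independence instead of erroring", {
  tiny <- data.frame(a = c(1L, 2L, 1L), b = c(2L, 1L, 1L),
                     s = c(1L, 2L, 1L))
  ct <- ci_test(tiny, "a", "b", "s")
  expect_true(ct$independent)
  expect_true(ct$small_sample)
})

test_that("type-I error rate of the G2 test is near alpha", {
  set.seed(11)
  rejections <- vapply(1:60, function(i) {
    d <- data.frame(a = sample(1:2, 400, TRUE), b = sample(1:2, 400, TRUE))
    !ci_test(d, "a", "b", alpha = 0.05)$independent
  }, TRUE)
  expect_lt(mean(rejections), 0.15)
})

test_that("structure learning recovers the canonical collider", {
  set.seed(5)
  n <- 5000
  a <- sample(1:2, n, TRUE)
  b <- sample(1:2, n, TRUE)
  # noisy-AND collider a -> c <- b (both parents marginally informative)
  p1 <- ifelse(a == 1 & b == 1, 0.9, 0.15)
  c_ <- ifelse(runif(n) < p1, 1L, 2L)
  bn <- learn_structure(data.frame(a = a, b = b, c = c_), alpha = 0.01)
  expect_true(dentalcbr:::is_directed(bn$amat, "a", "c"))
  expect_true(dentalcbr:::is_directed(bn$amat, "b", "c"))
  expect_equal(bn$amat["a", "b"] + bn$amat["b", "a"], 0L)
  expect_true(dentalcbr:::directed_acyclic(bn$amat))
})

test_that("independent variables give an empty graph; one variable a trivial DAG", {
  set.seed(6)
  d <- data.frame(a = sample(1:2, 5000, TRUE), b = sample(1:3, 5000, TRUE),
                  c = sample(1:2, 5000, TRUE))
  bn <- learn_structure(d, alpha = 0.01)
  expect_equal(sum(bn$amat), 0L)
  single <- learn_structure(data.frame(a = c(1L, 2L, 1L)), alpha = 0.05)
  expect_equal(single$nodes, "a")
  expect_equal(sum(single$amat), 0L)
})

test_that("CPTs are Laplace-smoothed conditional frequencies", {
  d <- data.frame(a = c(rep(2L, 30), rep(1L, 70)))
  dag <- learn_structure(d, alpha = 0.05)
  bn0 <- fit_cpts(dag, d, laplace_alpha = 0)
  expect_equal(bn0$cpts$a$prob[1, 2], 0.30)
  bn1 <- fit_cpts(dag, d, laplace_alpha = 1)
  expect_equal(bn1$cpts$a$prob[1, 2], 31 / 102)
  # rows of every CPT sum to one on arbitrary structures
  chain <- make_chain_data(n = 800, seed = 3)
  bn <- bn_fit(chain, alpha = 0.05, max_cond = 2)
  for (node in bn$nodes)
    expect_equal(unname(rowSums(bn$cpts[[node]]$prob)),
                 rep(1, nrow(bn$cpts[[node]]$prob)), tolerance = 1e-10)
})

test_that("posteriors by enumeration match the joint-table oracle", {
  chain <- make_chain_data(n = 2000, seed = 9)
  chain$d <- ifelse(runif(2000) < ifelse(chain$c == 1, 0.7, 0.3), 1L, 2L)
  bn <- bn_fit(chain, alpha = 0.05, max_cond = 2)
  # brute-force joint over all configurations
  grid <- expand.grid(a = 1:2, b = 1:2, c = 1:2, d = 1:2)
  joint <- rep(1, nrow(grid))
  for (node in bn$nodes) {
    cpt <- bn$cpts[[node]]
    cfg <- dentalcbr:::config_index(grid[cpt$parents], cpt$parent_cards)
    joint <- joint * cpt$prob[cbind(cfg, grid[[node]])]
  }
  for (target in c("a", "c", "d")) {
    ev <- list(b = 2L)
    post <- bn_posterior(bn, ev, target)
    keep <- grid$b == 2L
    oracle <- tapply(joint[keep], grid[[target]][keep], sum)
    oracle <- oracle / sum(oracle)
    expect_equal(as.numeric(post), as.numeric(oracle), tolerance = 1e-10)
  }
  expect_error(bn_posterior(bn, list(b = 5L), "a"),
               class = "dcbr_domain_error")
  expect_error(bn_posterior(bn, list(a = 1L), "a"),
               class = "dcbr_argument_error")
})

test_that("an edgeless network returns the marginal whatever the evidence", {
  set.seed(12)
  d <- data.frame(a = sample(1:2, 3000, TRUE),
                  t = sample(1:3, 3000, TRUE, prob = c(0.5, 0.3, 0.2)))
  bn <- bn_fit(d, alpha = 0.01)
  expect_equal(sum(bn$amat), 0L)
  marg <- bn_posterior(bn, list(), "t")
  with_ev <- bn_posterior(bn, list(a = 1L), "t")
  expect_equal(marg, with_ev, tolerance = 1e-12)
})

test_that("two-node posterior equals hand-computed Bayes arithmetic", {
  # a -> t with known CPTs
  bn <- structure(list(
    nodes = c("a", "t"),
    amat = matrix(c(0L, 0L, 1L, 0L), 2, 2,
                  dimnames = list(c("a", "t"), c("a", "t"))),
    cards = c(a = 2L, t = 2L),
    cpts = list(
      a = list(prob = matrix(c(0.6, 0.4), 1), parents = character(0),
               parent_cards = integer(0)),
      t = list(prob = rbind(c(0.9, 0.1), c(0.2, 0.8)), parents = "a",
               parent_cards = c(a = 2L)))), class = "bayes_net")
  post <- bn_posterior(bn, list(a = 1L), "t")
  expect_equal(as.numeric(post), c(0.9, 0.1), tolerance = 1e-12)
  post2 <- bn_posterior(bn, list(), "t")
  expect_equal(as.numeric(post2), c(0.6 * 0.9 + 0.4 * 0.2,
                                    0.6 * 0.1 + 0.4 * 0.8), tolerance = 1e-12)
})

test_that("expected longevity is the posterior-weighted bin midpoint", {
  bins <- c(seq(0, 20, 2), Inf)
  mids <- dentalcbr:::bin_midpoints(bins)
  expect_equal(mids[6], 11)        # [10, 12) -> 11
  expect_equal(mids[11], 21)       # [20, Inf) -> lower edge + half width
  # uniform posterior over [0,10) and [10,20) -> 10
  bn <- structure(list(
    nodes = "longevity_bin",
    amat = matrix(0L, 1, 1, dimnames = list("longevity_bin",
                                            "longevity_bin")),
    cards = c(longevity_bin = 2L),
    cpts = list(longevity_bin = list(prob = matrix(c(0.5, 0.5), 1),
                                     parents = character(0),
                                     parent_cards = integer(0)))),
    class = "bayes_net")
  expect_equal(bn_expected_longevity(bn, list(), c(0, 10, 20)), 10)
  expect_error(bn_expected_longevity(bn, list(), c(0, 10)),
               class = "dcbr_binning_error")
  # arbitrary posterior: dot product with midpoints
  set.seed(1)
  p <- runif(2); p <- p / sum(p)
  bn$cpts$longevity_bin$prob <- matrix(p, 1)
  expect_equal(bn_expected_longevity(bn, list(), c(0, 10, 20)),
               sum(p * c(5, 15)), tolerance = 1e-12)
})
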