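test_that("single-component fit equals the marginal ML estimates", {
  set.seed(4)
  cat <- matrix(sample(1:3, 100, TRUE), ncol = 1)
  num <- matrix(rnorm(100, 5, 2), ncol = 1)
  data <- encoded_records(cat = cat, num = num)
  fit <- em_fit(data, K = 1, alpha = 0, seed = 1, restarts = 1)
  expect_equal(fit$pi, 1)
  expect_equal(as.numeric(fit$cat_params[[1]]),
               as.numeric(table(cat) / 100))
  expect_equal(unname(fit$num_mean[1, 1]), mean(num))
  expect_equal(unname(fit$num_var[1, 1]), mean((num - mean(num))^2))
})

test_that("EM recovers separated Bernoulli clusters up to label permutation", {
  set.seed(99)
  n <- 2000
  z <- sample(1:2, n, TRUE)
  p_yes <- c(0.9, 0.1)
  cat <- sapply(1:5, function(j) ifelse(runif(n) < p_yes[z], 2L, 1L))
  data <- encoded_records(cat = cat)
  fit <- em_fit(data, K = 2, seed = 7)
  # per-attribute P(yes) per cluster, best label permutation
  est <- sapply(fit$cat_params, function(tab) tab[2, ])
  err_id <- max(abs(est - rbind(rep(0.9, 5), rep(0.1, 5))))
  err_sw <- max(abs(est - rbind(rep(0.1, 5), rep(0.9, 5))))
  expect_lt(min(err_id, err_sw), 0.03)
})

test_that("training log-likelihood trace is monotone non-decreasing", {
  gen <- small_casebase(seed = 2, n = 300)
  enc <- encode_cases(gen$casebase, "em")
  for (s in 1:5) {
    fit <- em_fit(enc, K = 3, seed = s, restarts = 2)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9 *
                      pmax(1, abs(fit$loglik_trace[-1]))))
  }
})

test_that("responsibilities are Bayes posteriors that sum to one", {
  gen <- small_casebase(seed = 6, n = 250)
  enc <- encode_cases(gen$casebase, "em")
  fit <- em_fit(enc, K = 3, seed = 2, restarts = 2)
  r <- responsibilities(fit, enc)
  expect_equal(rowSums(r), rep(1, nrow(enc$cat)), tolerance = 1e-12)
  expect_true(all(r >= 0))
  # K = 1 trivially gives [1]
  fit1 <- em_fit(enc, K = 1, seed = 1, restarts = 1)
  expect_equal(as.numeric(responsibilities(fit1, enc)), rep(1, nrow(enc$cat)))
})

test_that("responsibilities match closed forms on hand-built models", {
  # mirror-image clusters: a record equally typical of both -> [0.5, 0.5]
  m2 <- manual_em_model(
    pi = c(0.5, 0.5),
    cat_params = list(matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2),
                      matrix(c(0.2, 0.8, 0.8, 0.2), 2, 2)))
  r2 <- responsibilities(m2, encoded_records(cat = matrix(c(1L, 1L), 1)))
  expect_equal(as.numeric(r2), c(0.5, 0.5), tolerance = 1e-12)
  # two Gaussian clusters N(0,1) vs N(10,1), record at 0
  m3 <- manual_em_model(pi = c(0.5, 0.5), cat_params = list(),
                        num_mean = matrix(c(0, 10), 2, 1),
                        num_var = matrix(1, 2, 1))
  r3 <- responsibilities(m3, encoded_records(num = matrix(0, 1, 1)))
  expect_gt(r3[1, 1], 1 - 1e-10)
})

test_that("held-out log-likelihood matches enumeration oracles", {
  m <- manual_em_model(pi = 1,
                       cat_params = list(matrix(c(0.5, 0.5), 2, 1)))
  rec <- encoded_records(cat = matrix(2L, 1, 1))
  expect_equal(heldout_loglik(m, rec), log(0.5), tolerance = 1e-12)
  # 2-cluster, 2-attribute toy: brute-force mixture sum
  set.seed(8)
  t1 <- matrix(runif(6), 3, 2); t1 <- sweep(t1, 2, colSums(t1), "/")
  t2 <- matrix(runif(4), 2, 2); t2 <- sweep(t2, 2, colSums(t2), "/")
  m2 <- manual_em_model(pi = c(0.4, 0.6), cat_params = list(t1, t2))
  recs <- encoded_records(cat = cbind(c(1L, 3L, 2L), c(2L, 1L, 2L)))
  brute <- mean(log(
    0.4 * t1[recs$cat[, 1], 1] * t2[recs$cat[, 2], 1] +
    0.6 * t1[recs$cat[, 1], 2] * t2[recs$cat[, 2], 2]))
  expect_equal(heldout_loglik(m2, recs), brute, tolerance = 1e-10)
  # purely categorical data can never exceed log(1)
  expect_lt(heldout_loglik(m2, recs), 0)
})

test_that("the C++ M-step agrees with the reference R M-step", {
  gen <- small_casebase(seed = 12, n = 150)
  enc <- encode_cases(gen$casebase, "em")
  n <- nrow(enc$cat)
  set.seed(3)
  resp <- matrix(runif(n * 2), n, 2)
  resp <- resp / rowSums(resp)
  cards <- dentalcbr:::cat_cardinalities(enc)
  ref <- dentalcbr:::em_mstep(enc, resp, alpha = 1, var_floor = 1e-6, cards)
  cpp <- dentalcbr:::em_run_cpp(enc$cat, enc$num, cards, resp, 1, 1e-6,
                                1e300, 1L)
  expect_equal(as.numeric(cpp$pi), ref$pi, tolerance = 1e-12)
  for (j in seq_along(ref$cat_params))
    expect_equal(unname(cpp$cat_params[[j]]), unname(ref$cat_params[[j]]),
                 tolerance = 1e-12)
  expect_equal(unname(cpp$num_mean), unname(ref$num_mean), tolerance = 1e-9)
  expect_equal(unname(cpp$num_var), unname(ref$num_var), tolerance = 1e-9)
})

test_that("select_k stops by the relative-improvement rule", {
  # data from one cluster -> K* = 1
  set.seed(10)
  cat <- matrix(sample(1:2, 600, TRUE, prob = c(0.6, 0.4)), ncol = 2)
  one <- encoded_records(cat = cat)
  sel <- select_k(one, k_max = 4, seed = 3, restarts = 2)
  expect_equal(sel$K, 1L)
  expect_true(all(c("k", "fold", "loglik") %in% names(sel$cv_table)))
  # an infinite threshold rejects any improvement
  gen <- small_casebase(seed = 4, n = 300)
  enc <- encode_cases(gen$casebase, "em")
  sel_inf <- select_k(enc, k_max = 4, threshold = Inf, seed = 1,
                      restarts = 1, max_iter = 20)
  expect_equal(sel_inf$K, 1L)
  expect_error(select_k(enc, k_max = 0), class = "dcbr_argument_error")
  expect_error(em_fit(enc, K = 1e6), class = "dcbr_data_size_error")
})

test_that("EM fits are deterministic given the seed", {
  gen <- small_casebase(seed = 15, n = 200)
  enc <- encode_cases(gen$casebase, "em")
  f1 <- em_fit(enc, 2, seed = 5, restarts = 2)
  f2 <- em_fit(enc, 2, seed = 5, restarts = 2)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
  expect_identical(f1$pi, f2$pi)
})
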