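test_that("exact Mann-Whitney matches closed-form toy cases", {
  r <- mann_whitney_exact(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 6, tolerance = 1e-12)
  # complete separation of 5 vs 5 gives 1 / C(10, 5)
  r2 <- mann_whitney_exact(1:5, 11:15)
  expect_equal(r2$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_error(mann_whitney_exact(numeric(0), 1),
               class = "dcbr_argument_error")
  expect_error(mann_whitney_exact(1:13, 14:26),
               class = "dcbr_argument_error")
})

test_that("exact p-values agree with brute-force enumeration (pooled <= 12)", {
  set.seed(14)
  for (sizes in list(c(2, 2), c(3, 4), c(5, 5), c(6, 6), c(2, 9))) {
    for (rep in 1:3) {
      x <- round(runif(sizes[1]), 6)
      y <- round(runif(sizes[2]) + 0.001, 6)
      if (length(intersect(x, y)) > 0) next
      r <- mann_whitney_exact(x, y)
      expect_equal(r$p, brute_mw_p(x, y), tolerance = 1e-12,
                   info = paste(sizes, collapse = "x"))
    }
  }
})

test_that("exact p-values agree with the independent reference implementation", {
  set.seed(15)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6) + 0.5
    r <- mann_whitney_exact(x, y)
    ref <- suppressWarnings(
      wilcox.test(x, y, alternative = "less", exact = TRUE)$p.value)
    expect_equal(r$p, ref, tolerance = 1e-12)
  }
})

test_that("cross-sample ties error by default and fall back to permutation", {
  expect_error(mann_whitney_exact(c(1, 2, 3), c(3, 4)),
               class = "dcbr_tie_error")
  r <- mann_whitney_exact(c(1, 2, 3), c(3, 4), ties = "permutation",
                          seed = 5)
  expect_true(r$p > 0 && r$p <= 1)
  expect_equal(r$method, "permutation")
  # ties within one sample are harmless (the study's own error table has one)
  r2 <- mann_whitney_exact(c(0.38, 0.38, 0.41), c(0.63, 0.72))
  expect_equal(r2$method, "exact")
})

test_that("pairwise identity P(A,B) + P(B,A) = 1 + Pr(U = U_obs)", {
  set.seed(16)
  for (i in 1:8) {
    x <- rnorm(5); y <- rnorm(5)
    pab <- mann_whitney_exact(x, y)$p
    pba <- mann_whitney_exact(y, x)$p
    U <- sum(outer(x, y, ">"))
    counts <- dentalcbr:::mw_null_counts(5, 5)
    expect_equal(pab + pba, 1 + counts[U + 1] / choose(10, 5),
                 tolerance = 1e-12)
  }
})

test_that("compare_methods fills every ordered pair", {
  tab <- benchmark_error_table()[1:3, ]
  cm <- compare_methods(tab)
  expect_true(all(is.na(diag(cm))))
  expect_equal(sum(is.na(cm)), 3L)
  expect_true(all(cm[!is.na(cm)] > 0 & cm[!is.na(cm)] <= 1))
  expect_error(compare_methods(tab[1, , drop = FALSE]),
               class = "dcbr_argument_error")
})

test_that("5x2 cross-validation scores methods on year-stratified halves", {
  gen <- small_casebase(seed = 18, n = 400)
  cb <- gen$casebase
  oracle <- function(train_cb) function(cases) cases$restoration_longevity
  tab <- five_by_two_cv(cb, list(oracle = oracle), seed = 3)
  expect_equal(dim(tab), c(1L, 5L))
  expect_true(all(tab == 0))
  # deterministic given the seed
  tab2 <- five_by_two_cv(cb, list(oracle = oracle,
                                  mean = method_constant_mean()), seed = 7)
  tab3 <- five_by_two_cv(cb, list(oracle = oracle,
                                  mean = method_constant_mean()), seed = 7)
  expect_identical(tab2, tab3)
  expect_true(all(tab2["mean", ] > 0))
})

test_that("a constant-mean predictor scores sigma * sqrt(2/pi) on Normal noise", {
  cfg <- default_casebase_config(seed = 19, n_cases = 2000L)
  cfg$longevity_mean[] <- 10
  cfg$longevity_sd[] <- 1
  gen <- generate_casebase(cfg)
  tab <- five_by_two_cv(gen$casebase, list(mean = method_constant_mean()),
                        seed = 4)
  expect_true(all(abs(tab - sqrt(2 / pi)) < 0.1))
})

test_that("leave-one-out error matches hand computation on degenerate bases", {
  gen <- small_casebase(seed = 20, n = 120)
  cb <- gen$casebase
  cb$cases$restoration_longevity <- 10
  mae <- leave_one_out_error(cb, config = fast_config(), seed = 1, K = 2)
  expect_equal(mae, 0)
  expect_error(leave_one_out_error(cb, type = "nope",
                                   config = fast_config(), seed = 1, K = 2),
               class = "dcbr_empty_selection_error")
  # two cases of one type: each is predicted as the other
  two <- cb$cases[1:2, ]
  two$restoration_type <- "composite"
  two$prior_restoration_type <- "composite"
  two$restoration_longevity <- c(8, 12)
  two$patient_number <- 1:2
  cb2 <- casebase(two, cb$reference_date, validate = FALSE)
  kb2 <- build_knowledge_base(cb2, fast_config(min_cluster_cases = 1e6),
                              seed = 1, K = 1)
  mae2 <- leave_one_out_error(cb2, config = fast_config(), kb = kb2)
  expect_equal(mae2, 4)
})

test_that("yearly reports match brute-force group-by recomputation", {
  gen <- small_casebase(seed = 22, n = 500)
  cb <- gen$casebase
  year <- as.integer(format(cb$cases$restoration_date, "%Y"))

  usage <- report_yearly_usage(cb)
  expect_true(all(abs(usage$composite_pct + usage$amalgam_pct - 100) < 1e-9))
  for (r in seq_len(nrow(usage))) {
    sel <- year == usage$year[r]
    expect_equal(usage$composite_pct[r],
                 100 * mean(cb$cases$restoration_type[sel] == "composite"))
  }

  dur <- report_average_duration(cb)
  for (r in seq_len(nrow(dur))) {
    sel <- year == dur$year[r] & cb$cases$restoration_type == "amalgam"
    expected <- if (any(sel)) mean(cb$cases$restoration_longevity[sel])
                else NA_real_
    expect_equal(dur$amalgam_years[r], expected)
  }

  fail <- report_failure_rates(cb)
  type_mean <- tapply(cb$cases$restoration_longevity,
                      cb$cases$restoration_type, mean)
  is_fail <- cb$cases$restoration_longevity <
    0.5 * type_mean[cb$cases$restoration_type]
  for (r in seq_len(nrow(fail))) {
    sel <- year == fail$year[r] & cb$cases$restoration_type == "composite"
    expected <- if (any(sel)) 100 * mean(is_fail[sel]) else NA_real_
    expect_equal(fail$composite_pct[r], expected)
  }
})

test_that("the failure threshold is strict: exactly half the mean survives", {
  gen <- small_casebase(seed = 23, n = 40)
  cc <- gen$casebase$cases
  cc$restoration_type <- "composite"
  cc$prior_restoration_type <- "composite"
  # construct longevities with known mean 16: one case at exactly 8, one below
  cc <- cc[1:4, ]
  cc$patient_number <- 1:4
  cc$restoration_longevity <- c(8, 7, 24.5, 24.5)
  cc$restoration_date <- as.Date(c("2000-03-01", "2000-06-01",
                                   "2000-08-01", "2000-09-01"))
  cb <- casebase(cc, gen$casebase$reference_date, validate = FALSE)
  fr <- report_failure_rates(cb)
  # mean 16 -> threshold 8; 7 fails (7 < 8), 8 does not (8 is not < 8)
  expect_equal(fr$composite_pct, 25)
})

test_that("single-case and single-type usage reports are exact", {
  gen <- small_casebase(seed = 24, n = 30)
  one <- gen$casebase$cases[1, , drop = FALSE]
  one$restoration_type <- "composite"
  cb1 <- casebase(one, gen$casebase$reference_date, validate = FALSE)
  u <- report_yearly_usage(cb1)
  expect_equal(u$composite_pct, 100)
  expect_equal(u$amalgam_pct, 0)
  d <- report_average_duration(cb1)
  expect_equal(d$composite_years, one$restoration_longevity)
  expect_true(is.na(d$amalgam_years))
})
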