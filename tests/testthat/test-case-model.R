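test_that("schema covers 43 attributes with problem/solution roles", {
  sch <- restoration_schema()
  expect_equal(nrow(sch), 43L)
  expect_equal(sch$index, 1:43)
  expect_true(all(sch$role[1:41] == "problem"))
  expect_true(all(sch$role[42:43] == "solution"))
  expect_false(anyDuplicated(sch$name) > 0)
})

test_that("longevity is day-count arithmetic over a 365.25-day year", {
  expect_equal(
    compute_longevity("2000-01-01", "2000-01-01", TRUE),
    data.frame(longevity_years = 0, censored = FALSE))
  lv <- compute_longevity("2000-01-01", "2010-01-01", TRUE)
  expect_equal(lv$longevity_years, 3653 / 365.25)
  expect_false(lv$censored)
  lv2 <- compute_longevity("1993-06-01", "2014-06-01", FALSE)
  expect_equal(lv2$longevity_years, 7670 / 365.25)
  expect_equal(round(lv2$longevity_years), 21)
  expect_true(lv2$censored)
  expect_error(compute_longevity("2010-01-01", "2000-01-01", TRUE),
               class = "dcbr_date_order_error")
})

test_that("longevity is invariant under a common date shift", {
  d0 <- as.Date("1997-03-05"); d1 <- as.Date("2005-11-20")
  base <- compute_longevity(d0, d1, TRUE)$longevity_years
  for (shift in c(-400, 1, 97, 3650)) {
    expect_equal(compute_longevity(d0 + shift, d1 + shift, TRUE)$longevity_years,
                 base)
  }
})

test_that("save/load round-trips a generated case-base field by field", {
  gen <- small_casebase(seed = 11, n = 50)
  path <- withr::local_tempfile(fileext = ".csv")
  save_casebase(gen$casebase, path)
  cb2 <- load_casebase(path, gen$casebase$reference_date)
  expect_equal(cb2$cases, gen$casebase$cases, ignore_attr = TRUE)
  expect_equal(cb2$reference_date, gen$casebase$reference_date)
})

test_that("empty case-base saves to a header-only file and loads back", {
  cb <- casebase(dentalcbr:::empty_cases(), "2014-06-30")
  path <- withr::local_tempfile(fileext = ".csv")
  save_casebase(cb, path)
  expect_length(readLines(path), 1L)
  cb2 <- load_casebase(path, "2014-06-30")
  expect_equal(nrow(cb2$cases), 0L)
  gen1 <- small_casebase(seed = 2, n = 1)
  save_casebase(gen1$casebase, path)
  expect_length(readLines(path), 2L)
})

test_that("schema and cell-level errors carry row/column diagnostics", {
  gen <- small_casebase(seed = 3, n = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  save_casebase(gen$casebase, path)
  expect_equal(nrow(load_casebase(path, gen$casebase$reference_date)$cases), 3L)

  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  bad <- raw; bad$tooth_number[1] <- "33"
  write.csv(bad, path, row.names = FALSE, quote = FALSE)
  err <- tryCatch(load_casebase(path, gen$casebase$reference_date),
                  error = identity)
  expect_s3_class(err, "dcbr_validation_error")
  expect_match(conditionMessage(err), "tooth_number")
  expect_match(conditionMessage(err), "row 1")

  bad2 <- raw[, -which(names(raw) == "sex")]
  write.csv(bad2, path, row.names = FALSE, quote = FALSE)
  err2 <- tryCatch(load_casebase(path, gen$casebase$reference_date),
                   error = identity)
  expect_s3_class(err2, "dcbr_schema_error")
  expect_match(conditionMessage(err2), "sex")

  expect_error(load_casebase("no/such/file.csv", "2014-06-30"),
               class = "dcbr_io_error")
})

test_that("encodings are deterministic, total, and mlp-bounded", {
  gen <- small_casebase(seed = 7, n = 20)
  cb <- gen$casebase
  e1 <- encode_cases(cb, "em")
  e2 <- encode_cases(cb, "em")
  expect_identical(e1, e2)
  expect_false("patient_number" %in% c(colnames(e1$cat), colnames(e1$num)))
  # identical cases encode identically
  two <- cb$cases[c(1, 1), , drop = FALSE]
  em2 <- dentalcbr:::encode_mixed(two)
  expect_identical(em2$cat[1, ], em2$cat[2, ])
  expect_identical(em2$num[1, ], em2$num[2, ])
  # boolean yes encodes as category 2 (levels no/yes)
  smoke_code <- em2$cat[1, "smoke"]
  expect_equal(unname(smoke_code), if (two$smoke[1]) 2L else 1L)
  # mlp encoding bounded in the working range
  m <- encode_cases(cb, "mlp")
  expect_true(all(m >= 0.2 - 1e-12 & m <= 0.8 + 1e-12))
  expect_s3_class(attr(m, "scaler"), "range_scaler")
  # dates are never emitted raw: every column is a code or a duration
  expect_true(all(c("age_at_restoration", "prior_restoration_longevity")
                  %in% colnames(e1$num)))
  expect_error(encode_cases(cb, "nope"))
})

test_that("bn encoding discretizes reals with reusable edges", {
  gen <- small_casebase(seed = 9, n = 120)
  d <- encode_cases(gen$casebase, "bn", bins = 4L)
  edges <- attr(d, "bin_edges")
  expect_true(all(vapply(d, is.integer, TRUE)))
  expect_equal(sort(unique(d$age_at_restoration)),
               seq_len(max(d$age_at_restoration)))
  # same edges reproduce the same codes on the same cases
  d2 <- dentalcbr:::encode_discrete(gen$casebase, bins = 4L, edges = edges)
  expect_equal(d$age_at_restoration, d2$age_at_restoration)
})

test_that("validation rejects out-of-domain and duplicate cases", {
  gen <- small_casebase(seed = 13, n = 10)
  cc <- gen$casebase$cases
  cc$restoration_level[4] <- 11L
  expect_error(casebase(cc, gen$casebase$reference_date),
               class = "dcbr_validation_error")
  cc <- gen$casebase$cases
  cc[2, ] <- cc[1, ]
  expect_error(casebase(cc, gen$casebase$reference_date),
               class = "dcbr_validation_error")
})
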