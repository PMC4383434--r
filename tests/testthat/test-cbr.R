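# Knowledge-base cycle contracts.  A moderately sized synthetic case-base
# with a fixed cluster count keeps these fast; cluster-count selection
# itself is exercised in the EM tests and the acceptance suite.

kb_fixture <- function(n = 600, seed = 8, K = 3, ...) {
  gen <- small_casebase(seed = seed, n = n)
  kb <- build_knowledge_base(gen$casebase, fast_config(...), seed = 21, K = K)
  list(kb = kb, gen = gen)
}

test_that("knowledge base organizes the memory and classifies consistently", {
  fx <- kb_fixture()
  kb <- fx$kb
  expect_equal(kb$K, 3L)
  expect_length(kb$labels, nrow(kb$casebase$cases))
  # classifier hard labels agree with the EM hard labels on most cases
  post <- predict(kb$classifier, kb$casebase)
  agree <- mean(max.col(post) == kb$labels)
  expect_gte(agree, 0.9)
  # deterministic rebuild
  kb2 <- build_knowledge_base(fx$gen$casebase, fast_config(), seed = 21, K = 3)
  expect_identical(kb$labels, kb2$labels)
  expect_error(build_knowledge_base(casebase(dentalcbr:::empty_cases(),
                                             "2014-06-30")),
               class = "dcbr_argument_error")
})

test_that("retrieval ranks an identical stored case first and respects m", {
  fx <- kb_fixture()
  kb <- fx$kb
  # probe with a case whose classifier cluster matches its memory cluster
  post <- predict(kb$classifier, kb$casebase$cases[1:60, ])
  i <- which(max.col(post) == kb$labels[1:60])[1]
  probe <- kb$casebase$cases[i, , drop = FALSE]
  ret <- cbr_retrieve(kb, probe, m = 5)
  expect_equal(ret$case_ids[1], i)
  expect_equal(ret$similarity[1], 1)
  expect_length(ret$case_ids, 5L)
  # m beyond the cluster size returns the full cluster
  csize <- sum(kb$labels == ret$cluster)
  big <- cbr_retrieve(kb, probe, m = csize + 100)
  expect_length(big$case_ids, csize)
  expect_error(cbr_retrieve(kb, probe, m = 0), class = "dcbr_argument_error")
})

test_that("retrieval equals the exhaustive-scan similarity oracle", {
  fx <- kb_fixture(n = 300)
  kb <- fx$kb
  for (i in c(3, 50, 120)) {
    probe <- fx$gen$casebase$cases[i, , drop = FALSE]
    ret <- cbr_retrieve(kb, probe, m = 8)
    member <- which(kb$labels == ret$cluster)
    sims <- dentalcbr:::similarity_scores(
      kb, dentalcbr:::encode_mixed(probe), member)
    ord <- order(-sims, member)
    expect_equal(ret$case_ids, member[ord[1:8]])
  }
})

test_that("reuse trains one mixture per cluster lazily and caches it", {
  fx <- kb_fixture(n = 400)
  kb <- fx$kb
  probe <- kb$casebase$cases[5, , drop = FALSE]
  cl <- cbr_retrieve(kb, probe, m = 3)$cluster
  expect_equal(kb$counters$mixture_trainings, 0L)
  r1 <- cbr_reuse(kb, cl, probe)
  expect_equal(kb$counters$mixture_trainings, 1L)
  r2 <- cbr_reuse(kb, cl, probe)
  expect_equal(kb$counters$mixture_trainings, 1L)     # cache hit
  expect_equal(r1$estimates, r2$estimates)
  expect_equal(r1$method, "mixture")
  expect_error(cbr_reuse(kb, 99L, probe), class = "dcbr_argument_error")
})

test_that("clusters below the floor fall back to per-type averages, flagged", {
  fx <- kb_fixture(n = 200, min_cluster_cases = 1e6)
  kb <- fx$kb
  probe <- kb$casebase$cases[1, , drop = FALSE]
  cl <- cbr_retrieve(kb, probe, m = 3)$cluster
  r <- cbr_reuse(kb, cl, probe)
  expect_equal(r$method, "average")
  cc <- kb$casebase$cases[kb$labels == cl, ]
  for (tp in c("amalgam", "composite")) {
    y <- cc$restoration_longevity[cc$restoration_type == tp]
    if (length(y) > 0)
      expect_equal(unname(r$estimates[[tp]]), mean(y))
  }
})

test_that("revision clamps into mean +/- z sd with hand-checked bounds", {
  fx <- kb_fixture(n = 300)
  kb <- fx$kb
  lim <- kb$limits$per_cluster[[1]]$composite
  inside <- lim$mean + 0.5 * lim$sd
  r_in <- cbr_revise(kb, 1, inside, "composite")
  expect_equal(r_in$value, inside)
  r_hi <- cbr_revise(kb, 1, lim$mean + 10 * lim$sd, "composite")
  expect_equal(r_hi$value, lim$mean + 2 * lim$sd)
  r_lo <- cbr_revise(kb, 1, -100, "composite")
  expect_equal(r_lo$value, lim$mean - 2 * lim$sd)
  # bounds equal hand-computed mean +/- 2 sd of the cluster's same-type cases
  cc <- kb$casebase$cases
  y <- cc$restoration_longevity[kb$labels == 1 &
                                  cc$restoration_type == "composite"]
  expect_equal(r_hi$interval, c(mean(y) - 2 * sd(y), mean(y) + 2 * sd(y)))
})

test_that("retain appends, invalidates caches, and refreshes on schedule", {
  fx <- kb_fixture(n = 250, refresh_threshold = 3)
  kb <- fx$kb
  probe <- kb$casebase$cases[10, , drop = FALSE]
  cl <- cbr_retrieve(kb, probe, m = 2)$cluster
  invisible(cbr_reuse(kb, cl, probe))
  expect_equal(kb$counters$mixture_trainings, 1L)

  new_case <- kb$casebase$cases[11, , drop = FALSE]
  new_case$patient_number <- 888888L
  n0 <- nrow(kb$casebase$cases)
  kb <- cbr_retain(kb, new_case)
  expect_equal(nrow(kb$casebase$cases), n0 + 1L)
  expect_error(cbr_retain(kb, new_case), class = "dcbr_duplicate_error")

  # retained case is retrievable by an identical probe
  ret <- cbr_retrieve(kb, new_case, m = 2)
  expect_true((n0 + 1L) %in% ret$case_ids)

  # the affected cluster's mixture cache was invalidated: next reuse retrains
  cl_new <- ret$cluster
  invisible(cbr_reuse(kb, cl_new, new_case))
  trainings_after <- kb$counters$mixture_trainings
  expect_gte(trainings_after, 2L)

  # below the refresh threshold the EM model is untouched; at it, rebuilt
  expect_equal(kb$counters$em_rebuilds, 0L)
  for (i in 1:2) {
    nc <- kb$casebase$cases[12 + i, , drop = FALSE]
    nc$patient_number <- 888888L + i
    kb <- cbr_retain(kb, nc)
  }
  expect_equal(kb$counters$em_rebuilds, 1L)        # third retain triggers
  expect_equal(kb$counters$retains_since_build, 0L)
})

test_that("predictions average retrieved same-type cases and pick the type", {
  fx <- kb_fixture(n = 300)
  kb <- fx$kb
  probe <- kb$casebase$cases[8, , drop = FALSE]
  pred <- predict_restoration(kb, probe, m = 10)
  retrieved <- kb$casebase$cases[pred$retrieved, ]
  for (tp in c("amalgam", "composite")) {
    y <- retrieved$restoration_longevity[retrieved$restoration_type == tp]
    if (length(y) > 0)
      expect_equal(unname(pred$average_by_type[[tp]]), mean(y))
  }
  expect_equal(pred$recommended_type,
               names(which.max(pred$longevity_by_type)))
  # degenerate retrieved sets give the exact average
  kb3 <- kb
  kb3$casebase$cases$restoration_longevity[pred$retrieved] <- 10
  pred3 <- predict_restoration(kb3, probe, m = 10)
  tp <- kb3$casebase$cases$restoration_type[pred3$retrieved]
  if (all(c("amalgam", "composite") %in% tp) == FALSE) {
    # at least the probe's own type average must be exactly 10
    expect_equal(unname(pred3$average_by_type[[tp[1]]]), 10)
  } else {
    expect_equal(unname(pred3$average_by_type[["amalgam"]]), 10)
    expect_equal(unname(pred3$average_by_type[["composite"]]), 10)
  }
  # predict() on the knowledge base dispatches per case
  p2 <- predict(kb, kb$casebase$cases[2, , drop = FALSE], m = 5)
  expect_s3_class(p2, "restoration_prediction")
})

test_that("print methods summarize without error", {
  fx <- kb_fixture(n = 200)
  expect_output(print(fx$kb), "CBR knowledge base")
  expect_output(print(summary(fx$kb)), "clusters")
  expect_output(print(fx$gen$casebase), "case-base")
  pred <- predict_restoration(fx$kb, fx$gen$casebase$cases[1, , drop = FALSE])
  expect_output(print(pred), "Recommended restoration")
})
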