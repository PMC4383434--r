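# The CBR cycle: retrieve (EM cluster via a Bayesian-network classifier +
# within-cluster similarity), reuse (lazily trained per-cluster mixture of
# experts), revise (confidence limits), retain (store + cache invalidation).

# Classifier over the hard EM labels: screened descriptor attributes plus a
# `cluster` node, learned and parameterized like any other network here.
fit_cluster_classifier <- function(cases, labels, K, config) {
  enc <- encode_discrete(cases, include_type = FALSE, bins = config$bn_bins)
  edges <- attr(enc, "bin_edges")
  n_levels <- attr(enc, "n_levels")
  stat <- vapply(names(enc), function(a)
    assoc_stat(enc[[a]], labels, n_levels[[a]], K), 0)
  keep <- names(sort(stat, decreasing = TRUE))[
    seq_len(min(config$bn_screen, length(stat)))]
  df <- enc[keep]
  attr(df, "n_levels") <- n_levels[keep]
  bn <- class_augmented_bn(df, labels, K, "cluster",
                           alpha = config$bn_alpha,
                           max_cond = config$bn_max_cond,
                           laplace_alpha = config$bn_laplace)
  structure(list(bn = bn, screen = keep, edges = edges, K = K,
                 bn_bins = config$bn_bins), class = "cluster_classifier")
}

#' @export
predict.cluster_classifier <- function(object, newdata, ...) {
  cases <- if (inherits(newdata, "casebase")) newdata$cases else newdata
  enc <- encode_discrete(cases, include_type = FALSE,
                         bins = object$bn_bins, edges = object$edges)
  t(vapply(seq_len(nrow(enc)), function(i)
    bn_posterior(object$bn, as.list(enc[i, object$screen, drop = FALSE]),
                 "cluster"),
    numeric(object$K)))
}

confidence_limits <- function(cases, labels, K, z) {
  global <- lapply(TYPE_LEVELS, function(tp) {
    y <- cases$restoration_longevity[cases$restoration_type == tp]
    list(n = length(y), mean = mean(y), sd = stats::sd(y))
  })
  names(global) <- TYPE_LEVELS
  per <- list()
  for (k in seq_len(K)) {
    per[[k]] <- lapply(TYPE_LEVELS, function(tp) {
      y <- cases$restoration_longevity[labels == k &
                                         cases$restoration_type == tp]
      if (length(y) < 2L)
        c(global[[tp]], list(global_fallback = TRUE))
      else list(n = length(y), mean = mean(y), sd = stats::sd(y),
                global_fallback = FALSE)
    })
    names(per[[k]]) <- TYPE_LEVELS
  }
  list(per_cluster = per, global = global, z = z)
}

#' Build the CBR knowledge base from a case-base
#'
#' Organizes the case memory by expectation-maximization: [select_k()]
#' picks the number of clusters by 10-fold cross-validated log-likelihood
#' (unless `K` is given), [em_fit()] fits the mixture, a Bayesian-network
#' classifier is trained on the hard cluster labels for retrieval, and
#' per-cluster, per-type confidence limits (mean +/- z sd of longevity)
#' are computed.  Per-cluster mixtures of experts are trained lazily on
#' first reuse and cached.
#'
#' @param cb a nonempty [casebase()].
#' @param config a [cbr_config()].
#' @param seed integer master seed.
#' @param K fixed cluster count, or `NULL` to select it automatically.
#' @return A `cbr_knowledge_base`.
#' @export
build_knowledge_base <- function(cb, config = cbr_config(), seed = 1L,
                                 K = NULL) {
  stopifnot(inherits(cb, "casebase"))
  if (nrow(cb$cases) == 0L)
    abort_dcbr("empty case-base", "dcbr_argument_error")
  enc <- encode_cases(cb, "em")
  selection <- NULL
  if (is.null(K)) {
    selection <- select_k(enc, k_max = config$k_max,
                          threshold = config$threshold,
                          folds = config$folds,
                          seed = derive_seed(seed, "select_k"),
                          restarts = config$em_restarts,
                          max_iter = config$em_max_iter,
                          tol = config$em_tol, alpha = config$em_alpha,
                          var_floor = config$var_floor)
    K <- selection$K
  }
  em <- em_fit(enc, K, tol = config$em_tol, max_iter = config$em_max_iter,
               seed = derive_seed(seed, "em"), restarts = config$em_restarts,
               alpha = config$em_alpha, var_floor = config$var_floor)
  resp <- responsibilities(em, enc)
  labels <- max.col(resp, ties.method = "first")
  classifier <- fit_cluster_classifier(cb$cases, labels, K, config)
  limits <- confidence_limits(cb$cases, labels, K, config$z)
  num_range <- apply(enc$num, 2L, range)

  kb <- structure(list(
    casebase = cb, em = em, K = K, labels = labels,
    classifier = classifier, limits = limits, selection = selection,
    num_range = num_range, config = config, seed = seed,
    cache = new.env(parent = emptyenv()),
    counters = new.env(parent = emptyenv())),
    class = "cbr_knowledge_base")
  kb$counters$mixture_trainings <- 0L
  kb$counters$retains_since_build <- 0L
  kb$counters$em_rebuilds <- 0L
  kb
}

#' @export
print.cbr_knowledge_base <- function(x, ...) {
  cat(sprintf("CBR knowledge base: %d cases organized into %d clusters\n",
              nrow(x$casebase$cases), x$K))
  cat("Cluster sizes:", paste(tabulate(x$labels, x$K), collapse = ", "), "\n")
  trained <- ls(x$cache)
  cat(sprintf("Trained mixtures: %s\n",
              if (length(trained) == 0L) "none (lazy)"
              else paste(trained, collapse = ", ")))
  invisible(x)
}

#' @export
summary.cbr_knowledge_base <- function(object, ...) {
  lim <- object$limits$per_cluster
  tab <- do.call(rbind, lapply(seq_along(lim), function(k)
    do.call(rbind, lapply(TYPE_LEVELS, function(tp)
      data.frame(cluster = k, type = tp, n = lim[[k]][[tp]]$n,
                 mean = lim[[k]][[tp]]$mean, sd = lim[[k]][[tp]]$sd)))))
  structure(list(K = object$K, limits = tab,
                 sizes = tabulate(object$labels, object$K)),
            class = "summary.cbr_knowledge_base")
}

#' @export
print.summary.cbr_knowledge_base <- function(x, ...) {
  cat(sprintf("Knowledge base with %d clusters (sizes %s)\n", x$K,
              paste(x$sizes, collapse = ", ")))
  print(x$limits, row.names = FALSE, digits = 3)
  invisible(x)
}

# Per-attribute match score between a probe and stored cases: equality
# indicator for categoricals, 1 - |delta| / range for reals, equally
# weighted.  Returns a similarity in [0, 1] per stored case.
similarity_scores <- function(kb, probe_enc, idx) {
  enc <- encode_cases(subset_cb(kb$casebase, idx), "em")
  n <- length(idx)
  n_cat <- ncol(enc$cat)
  n_num <- ncol(enc$num)
  s_cat <- rowSums(enc$cat == matrix(probe_enc$cat, n, n_cat, byrow = TRUE))
  rng <- pmax(kb$num_range[2L, ] - kb$num_range[1L, ], 1e-12)
  d <- abs(enc$num - matrix(probe_enc$num, n, n_num, byrow = TRUE))
  s_num <- rowSums(pmax(1 - sweep(d, 2L, rng, "/"), 0))
  (s_cat + s_num) / (n_cat + n_num)
}

subset_cb <- function(cb, idx)
  casebase(cb$cases[idx, , drop = FALSE], cb$reference_date, validate = FALSE)

#' Retrieve the most similar stored cases
#'
#' The probe's cluster is the argmax of the Bayesian-network classifier
#' posterior (ties broken by the higher EM responsibility, then the lower
#' cluster index); within the cluster, cases are ranked by the
#' per-attribute match score and the top `m` returned (the whole cluster
#' when it holds fewer than `m`).
#'
#' @param kb a [build_knowledge_base()] knowledge base.
#' @param case a single case (1-row [casebase()] or cases data.frame).
#' @param m number of cases to retrieve.
#' @param exclude case indices to ignore (used by leave-one-out
#'   evaluation).
#' @return List with `cluster`, `case_ids` (row indices into the
#'   case-base), `similarity`, and a `global_fallback` flag.
#' @export
cbr_retrieve <- function(kb, case, m = kb$config$m, exclude = integer(0)) {
  if (m < 1L) abort_dcbr("m must be >= 1", "dcbr_argument_error")
  probe <- as_single_case(case)
  post <- predict(kb$classifier, probe)[1L, ]
  top <- which(post == max(post))
  if (length(top) > 1L) {
    r <- responsibilities(kb$em, encode_mixed(probe))[1L, top]
    top <- top[r == max(r)]
  }
  cluster <- min(top)
  member <- setdiff(which(kb$labels == cluster), exclude)
  fallback <- FALSE
  if (length(member) == 0L) {
    member <- setdiff(seq_along(kb$labels), exclude)
    fallback <- TRUE
  }
  probe_enc <- encode_mixed(probe)
  sim <- similarity_scores(kb, probe_enc, member)
  ord <- order(-sim, member)
  take <- ord[seq_len(min(m, length(ord)))]
  list(cluster = cluster, case_ids = member[take],
       similarity = sim[take], global_fallback = fallback)
}

as_single_case <- function(case) {
  cases <- if (inherits(case, "casebase")) case$cases else case
  if (nrow(cases) != 1L)
    abort_dcbr("expected exactly one probe case", "dcbr_argument_error")
  cases
}

cluster_mixture <- function(kb, cluster) {
  key <- as.character(cluster)
  if (!is.null(kb$cache[[key]])) return(kb$cache[[key]])
  cases <- subset_cb(kb$casebase, which(kb$labels == cluster))
  mx <- train_mixture(cases, kb$config,
                      seed = derive_seed(kb$seed, paste0("mixture", cluster)))
  kb$cache[[key]] <- mx
  kb$counters$mixture_trainings <- kb$counters$mixture_trainings + 1L
  mx
}

#' Reuse: raw longevity estimate per candidate restoration type
#'
#' The cluster's mixture of experts is trained on first use and cached;
#' the case is then evaluated under each candidate restoration type.
#' Clusters below the training-size floor fall back to the per-type
#' average of the cluster's cases, flagged `method = "average"`.
#'
#' @param kb knowledge base.
#' @param cluster cluster id from [cbr_retrieve()].
#' @param case the probe case.
#' @param exclude case indices excluded from an average-based fallback.
#' @return List with per-type estimates (`amalgam`, `composite`) and the
#'   `method` used (`"mixture"` or `"average"`).
#' @export
cbr_reuse <- function(kb, cluster, case, exclude = integer(0)) {
  if (cluster < 1L || cluster > kb$K)
    abort_dcbr("no such cluster", "dcbr_argument_error")
  probe <- as_single_case(case)
  member <- setdiff(which(kb$labels == cluster), exclude)
  if (length(member) >= kb$config$min_cluster_cases) {
    mx <- cluster_mixture(kb, cluster)
    est <- vapply(TYPE_LEVELS, function(tp)
      mixture_predict(mx, probe, type = tp), 0)
    method <- "mixture"
  } else {
    cc <- kb$casebase$cases[member, , drop = FALSE]
    est <- vapply(TYPE_LEVELS, function(tp) {
      y <- cc$restoration_longevity[cc$restoration_type == tp]
      if (length(y) > 0L) mean(y) else kb$limits$global[[tp]]$mean
    }, 0)
    method <- "average"
  }
  list(estimates = est, method = method)
}

#' Revise a raw estimate with the knowledge base's confidence limits
#'
#' Clamps the raw longevity into `mean +/- z * sd` of the cluster's
#' same-type longevities (the global type distribution, flagged, when the
#' cluster has no same-type cases).
#'
#' @param kb knowledge base.
#' @param cluster cluster id.
#' @param raw raw longevity estimate in years.
#' @param type restoration type the estimate refers to.
#' @return List with the clamped `value`, the `interval`, and a
#'   `global_fallback` flag.
#' @export
cbr_revise <- function(kb, cluster, raw, type) {
  lim <- kb$limits$per_cluster[[cluster]][[type]]
  z <- kb$limits$z
  sd_ <- if (is.na(lim$sd)) 0 else lim$sd
  interval <- c(lim$mean - z * sd_, lim$mean + z * sd_)
  list(value = min(max(raw, interval[1L]), interval[2L]),
       interval = interval,
       global_fallback = isTRUE(lim$global_fallback))
}

#' Retain a solved case in the knowledge base
#'
#' Appends the case, invalidates the affected cluster's mixture cache and
#' recomputes the confidence limits.  The EM model and cluster classifier
#' are rebuilt only once the number of retained cases since the last build
#' reaches `refresh_threshold`.
#'
#' @param kb knowledge base.
#' @param case a single solved case (solution attributes present).
#' @return The updated knowledge base.
#' @export
cbr_retain <- function(kb, case) {
  probe <- as_single_case(case)
  cc <- kb$casebase$cases
  key_new <- paste(probe$patient_number, probe$tooth_number,
                   probe$restoration_date)
  if (key_new %in% paste(cc$patient_number, cc$tooth_number,
                         cc$restoration_date))
    abort_dcbr("case key already present", "dcbr_duplicate_error")
  if (is.na(probe$restoration_longevity) || is.na(probe$restoration_type))
    abort_dcbr("retained case needs a solution", "dcbr_argument_error")

  cluster <- cbr_retrieve(kb, probe, m = 1L)$cluster
  new_cases <- rbind(cc, probe[names(cc)])
  kb$casebase <- casebase(new_cases, kb$casebase$reference_date,
                          validate = FALSE)
  kb$labels <- c(kb$labels, cluster)
  kb$counters$retains_since_build <- kb$counters$retains_since_build + 1L

  if (kb$counters$retains_since_build >= kb$config$refresh_threshold) {
    enc <- encode_cases(kb$casebase, "em")
    kb$em <- em_fit(enc, kb$K, tol = kb$config$em_tol,
                    max_iter = kb$config$em_max_iter,
                    seed = derive_seed(kb$seed, "em_refresh"),
                    restarts = kb$config$em_restarts,
                    alpha = kb$config$em_alpha,
                    var_floor = kb$config$var_floor)
    kb$labels <- max.col(responsibilities(kb$em, enc), ties.method = "first")
    kb$classifier <- fit_cluster_classifier(kb$casebase$cases, kb$labels,
                                            kb$K, kb$config)
    kb$num_range <- apply(enc$num, 2L, range)
    kb$counters$retains_since_build <- 0L
    kb$counters$em_rebuilds <- kb$counters$em_rebuilds + 1L
    for (key in ls(kb$cache)) rm(list = key, envir = kb$cache)
  } else {
    key <- as.character(cluster)
    if (!is.null(kb$cache[[key]])) rm(list = key, envir = kb$cache)
  }
  kb$limits <- confidence_limits(kb$casebase$cases, kb$labels, kb$K,
                                 kb$config$z)
  kb
}

#' Full CBR prediction for a new case
#'
#' Runs retrieve, reuse and revise for both candidate restoration types.
#' The expected longevity per type is reported both as the retrieved-case
#' same-type average and as the revised mixture output; the recommended
#' type maximizes the configured headline estimate (retrieved-case average
#' by default).
#'
#' @param kb knowledge base.
#' @param case the probe case.
#' @param m retrieval size.
#' @param exclude case indices to ignore (leave-one-out support).
#' @return A `restoration_prediction`: `recommended_type`,
#'   `longevity_by_type` (headline), `average_by_type`, `mixture_by_type`,
#'   `interval_by_type`, `cluster`, `retrieved`, provenance flags.
#' @export
predict_restoration <- function(kb, case, m = kb$config$m,
                                exclude = integer(0)) {
  probe <- as_single_case(case)
  ret <- cbr_retrieve(kb, probe, m = m, exclude = exclude)
  retrieved <- kb$casebase$cases[ret$case_ids, , drop = FALSE]
  avg <- vapply(TYPE_LEVELS, function(tp) {
    y <- retrieved$restoration_longevity[retrieved$restoration_type == tp]
    if (length(y) > 0L) mean(y)
    else kb$limits$per_cluster[[ret$cluster]][[tp]]$mean
  }, 0)
  reused <- cbr_reuse(kb, ret$cluster, probe, exclude = exclude)
  revised <- lapply(TYPE_LEVELS, function(tp)
    cbr_revise(kb, ret$cluster, reused$estimates[[tp]], tp))
  names(revised) <- TYPE_LEVELS
  mix <- vapply(revised, `[[`, 0, "value")
  headline <- if (kb$config$headline == "average") avg else mix
  structure(list(
    recommended_type = TYPE_LEVELS[which.max(headline)],
    longevity_by_type = headline,
    average_by_type = avg,
    mixture_by_type = mix,
    interval_by_type = lapply(revised, `[[`, "interval"),
    cluster = ret$cluster,
    retrieved = ret$case_ids,
    provenance = list(headline = kb$config$headline,
                      reuse_method = reused$method,
                      retrieval_global_fallback = ret$global_fallback)),
    class = "restoration_prediction")
}

#' @export
print.restoration_prediction <- function(x, ...) {
  cat(sprintf("Recommended restoration: %s\n", x$recommended_type))
  for (tp in names(x$longevity_by_type))
    cat(sprintf(
      "  %-9s expected longevity %.1f y (retrieved-case average %.1f, mixture %.1f, interval [%.1f, %.1f])\n",
      tp, x$longevity_by_type[[tp]], x$average_by_type[[tp]],
      x$mixture_by_type[[tp]], x$interval_by_type[[tp]][1L],
      x$interval_by_type[[tp]][2L]))
  cat(sprintf("  cluster %d, %d retrieved cases, reuse by %s\n",
              x$cluster, length(x$retrieved), x$provenance$reuse_method))
  invisible(x)
}

#' @export
predict.cbr_knowledge_base <- function(object, newdata, ...) {
  cases <- if (inherits(newdata, "casebase")) newdata$cases else newdata
  if (nrow(cases) == 1L) return(predict_restoration(object, cases, ...))
  lapply(seq_len(nrow(cases)), function(i)
    predict_restoration(object, cases[i, , drop = FALSE], ...))
}
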