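# Evaluation machinery: exact small-sample Mann-Whitney comparison of
# methods, 5x2 cross-validation error tables, leave-one-out error, and the
# yearly usage / duration / failure-rate reports.

# Number of rank arrangements of n x-values among n + m pooled values with
# Mann-Whitney statistic (number of x > y pairs) equal to u, for
# u = 0..n*m.  Classic recursion N(n, m, u) = N(n-1, m, u-m) + N(n, m-1, u).
mw_null_counts <- function(n, m) {
  memo <- new.env(parent = emptyenv())
  rec <- function(n, m) {
    key <- paste(n, m)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- if (n == 0L || m == 0L) 1 else {
      a <- rec(n - 1L, m)                 # largest pooled value is an x
      b <- rec(n, m - 1L)                 # largest pooled value is a y
      res <- numeric(n * m + 1L)
      res[seq_along(a) + m] <- a
      res[seq_along(b)] <- res[seq_along(b)] + b
      res
    }
    memo[[key]] <- out
    out
  }
  rec(as.integer(n), as.integer(m))
}

#' Exact one-sided Mann-Whitney U test for small samples
#'
#' Tests whether `x` ranks lower than `y`.  The statistic is the number of
#' pairs with `x_i > y_j`; the p-value is the exact probability
#' `P(U <= U_obs)` under the null, obtained from the full distribution of
#' rank arrangements (all `choose(n+m, n)` of them).  Ties between the two
#' samples break the exact null; they raise a tie error unless
#' `ties = "permutation"`, which switches to mid-rank scoring with a
#' seeded Monte-Carlo permutation p-value.  Ties within one sample are
#' harmless and allowed.
#'
#' @param x,y nonempty numeric samples (combined size <= 25 for the exact
#'   enumeration regime).
#' @param alternative only `"x_lower"` (x stochastically smaller).
#' @param ties `"error"` (default) or `"permutation"`.
#' @param n_perm,seed Monte-Carlo settings for the permutation fallback.
#' @return List of class `mw_test`: `U`, `p`, sample sizes, and the method
#'   used.
#' @export
#' @examples
#' mann_whitney_exact(c(1, 2), c(3, 4))$p  # 1/6
mann_whitney_exact <- function(x, y, alternative = "x_lower",
                               ties = c("error", "permutation"),
                               n_perm = 20000L, seed = 1L) {
  ties <- match.arg(ties)
  if (length(x) == 0L || length(y) == 0L)
    abort_dcbr("both samples must be nonempty", "dcbr_argument_error")
  if (!identical(alternative, "x_lower"))
    abort_dcbr("only the 'x_lower' alternative is implemented",
               "dcbr_argument_error")
  n <- length(x); m <- length(y)
  cross_ties <- length(intersect(x, y)) > 0L
  if (cross_ties && ties == "error")
    abort_dcbr(paste("ties across the two samples break the exact null;",
                     "rerun with ties = 'permutation'"), "dcbr_tie_error")

  if (!cross_ties) {
    if (n + m > 25L)
      abort_dcbr("combined sample too large for exact enumeration (> 25)",
                 "dcbr_argument_error")
    U <- sum(outer(x, y, ">"))
    counts <- mw_null_counts(n, m)
    p <- sum(counts[seq_len(U + 1L)]) / choose(n + m, n)
    method <- "exact"
  } else {
    U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    pooled <- c(x, y)
    U_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n + m, n)
      xs <- pooled[idx]; ys <- pooled[-idx]
      sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    }, 0))
    p <- (1 + sum(U_perm <= U + 1e-12)) / (n_perm + 1)
    method <- "permutation"
  }
  structure(list(U = U, p = p, n_x = n, n_y = m, method = method,
                 alternative = alternative), class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney (%s, H1: x ranks lower): U = %g, p = %.4f\n",
              x$method, x$U, x$p))
  invisible(x)
}

#' Pairwise one-sided comparison of methods
#'
#' Applies [mann_whitney_exact()] to every ordered pair of rows of an
#' error table; entry (row, col) tests "row method's errors rank lower
#' than column method's".
#'
#' @param table matrix or data.frame: one row per method (rownames = method
#'   names), one column per repetition, entries mean absolute longevity
#'   errors in years.
#' @param ... passed to [mann_whitney_exact()].
#' @return A square matrix of one-sided p-values with an empty (NA)
#'   diagonal, of class `comparison_matrix`.
#' @export
compare_methods <- function(table, ...) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2L)
    abort_dcbr("need at least two methods", "dcbr_argument_error")
  if (any(tab < 0)) abort_dcbr("errors must be >= 0", "dcbr_argument_error")
  methods <- rownames(tab) %||% paste0("method", seq_len(nrow(tab)))
  P <- matrix(NA_real_, nrow(tab), nrow(tab),
              dimnames = list(methods, methods))
  for (i in seq_len(nrow(tab))) for (j in seq_len(nrow(tab))) {
    if (i == j) next
    P[i, j] <- mann_whitney_exact(tab[i, ], tab[j, ], ...)$p
  }
  structure(P, class = c("comparison_matrix", "matrix"))
}

#' @export
print.comparison_matrix <- function(x, digits = 4, ...) {
  cat("One-sided Mann-Whitney p-values (row ranks lower than column):\n")
  y <- unclass(x)
  print(round(y, digits), na.print = "")
  invisible(x)
}

merge_small_years <- function(year, min_n = 2L) {
  grp <- year
  tab <- sort(unique(grp))
  counts <- table(factor(grp, levels = tab))
  small <- tab[counts < min_n]
  if (length(small) > 0L) {
    warning(sprintf("year strata with < %d cases merged into a neighbor: %s",
                    min_n, paste(small, collapse = ", ")), call. = FALSE)
    for (yv in small) {
      others <- setdiff(sort(unique(grp)), yv)
      if (length(others) == 0L) break
      nearest <- others[which.min(abs(others - yv))]
      grp[grp == yv] <- nearest
    }
  }
  grp
}

restoration_year <- function(cases)
  as.integer(format(cases$restoration_date, "%Y"))

#' 5x2 cross-validation error table
#'
#' Five repetitions; in each, a random half of the cases of every
#' restoration year goes to one side of the split and the rest to the
#' other.  Each method is trained on one half and tested on the other and
#' vice versa; the repetition's value is the mean absolute longevity error
#' pooled over both directions.
#'
#' @param cb a [casebase()].
#' @param methods named list of factories; each factory is called as
#'   `factory(train_cb)` and must return a prediction function
#'   `function(cases_df) -> numeric` (longevity in years).
#' @param seed integer seed.
#' @param reps number of repetitions.
#' @return A methods x reps matrix of mean absolute errors (years), class
#'   `error_table`.
#' @export
five_by_two_cv <- function(cb, methods, seed = 1L, reps = 5L) {
  stopifnot(inherits(cb, "casebase"), length(methods) >= 1L)
  cases <- cb$cases
  year <- merge_small_years(restoration_year(cases))
  out <- matrix(NA_real_, length(methods), reps,
                dimnames = list(names(methods),
                                paste0("step", seq_len(reps))))
  for (r in seq_len(reps)) {
    half <- with_seed(derive_seed(seed, paste0("rep", r)), {
      h <- logical(nrow(cases))
      for (yv in unique(year)) {
        idx <- which(year == yv)
        h[sample(idx, floor(length(idx) / 2))] <- TRUE
      }
      h
    })
    for (mi in seq_along(methods)) {
      errs <- c()
      for (dir in 1:2) {
        tr <- if (dir == 1L) half else !half
        train <- subset_cb(cb, which(tr))
        test <- cases[!tr, , drop = FALSE]
        predictor <- methods[[mi]](train)
        pred <- predictor(test)
        errs <- c(errs, abs(pred - test$restoration_longevity))
      }
      out[mi, r] <- mean(errs)
    }
  }
  structure(out, class = c("error_table", "matrix"))
}

#' Leave-one-out mean absolute longevity error
#'
#' The knowledge base (EM model and cluster classifier) is built once on
#' the full case-base; each case is then predicted with itself excluded
#' from retrieval, via the retrieved-case average estimate for its own
#' restoration type, and the absolute errors are averaged.
#'
#' @param cb a [casebase()].
#' @param type optional filter (`"amalgam"`/`"composite"`).
#' @param config a [cbr_config()].
#' @param seed integer seed.
#' @param K fixed cluster count (`NULL` selects it by cross-validation).
#' @param kb optionally, a prebuilt knowledge base to reuse.
#' @return The mean absolute error in years.
#' @export
leave_one_out_error <- function(cb, type = NULL, config = cbr_config(),
                                seed = 1L, K = NULL, kb = NULL) {
  if (is.null(kb)) kb <- build_knowledge_base(cb, config, seed = seed, K = K)
  idx <- seq_len(nrow(cb$cases))
  if (!is.null(type)) idx <- idx[cb$cases$restoration_type == type]
  if (length(idx) == 0L)
    abort_dcbr("type filter matches no cases", "dcbr_empty_selection_error")
  errs <- vapply(idx, function(i) {
    case <- cb$cases[i, , drop = FALSE]
    pred <- predict_restoration(kb, case, exclude = i)
    abs(pred$average_by_type[[case$restoration_type]] -
          case$restoration_longevity)
  }, 0)
  mean(errs)
}

#' Yearly restoration-type usage report
#'
#' @param cb a [casebase()].
#' @return data.frame with one row per restoration year and the percentage
#'   of composite and amalgam restorations (full precision; percentages
#'   are conventionally displayed rounded to integers, and each row sums
#'   to 100 up to that rounding).
#' @export
report_yearly_usage <- function(cb) {
  cases <- cb$cases
  year <- restoration_year(cases)
  ys <- sort(unique(year))
  out <- do.call(rbind, lapply(ys, function(yv) {
    tp <- cases$restoration_type[year == yv]
    data.frame(year = yv,
               composite_pct = 100 * mean(tp == "composite"),
               amalgam_pct = 100 * mean(tp == "amalgam"))
  }))
  rownames(out) <- NULL
  out
}

#' Yearly average restoration duration by type
#'
#' Arithmetic mean longevity (censored durations included at their
#' duration-to-present value) per calendar year and restoration type.
#'
#' @param cb a [casebase()].
#' @return data.frame with columns `year`, `composite_years`,
#'   `amalgam_years` (NA when a year has no case of that type).
#' @export
report_average_duration <- function(cb) {
  cases <- cb$cases
  year <- restoration_year(cases)
  ys <- sort(unique(year))
  mean_or_na <- function(v) if (length(v) == 0L) NA_real_ else mean(v)
  out <- do.call(rbind, lapply(ys, function(yv) {
    sel <- year == yv
    data.frame(
      year = yv,
      composite_years = mean_or_na(
        cases$restoration_longevity[sel & cases$restoration_type == "composite"]),
      amalgam_years = mean_or_na(
        cases$restoration_longevity[sel & cases$restoration_type == "amalgam"]))
  }))
  rownames(out) <- NULL
  out
}

#' Yearly restoration failure-rate report
#'
#' A restoration counts as a failure when it lasted strictly less than 50%
#' of the overall average duration of its restoration type.
#'
#' @param cb a [casebase()].
#' @return data.frame with columns `year`, `composite_pct`, `amalgam_pct`
#'   (failure percentages; NA when a year has no case of that type).
#' @export
report_failure_rates <- function(cb) {
  cases <- cb$cases
  type_mean <- tapply(cases$restoration_longevity, cases$restoration_type,
                      mean)
  is_fail <- cases$restoration_longevity <
    0.5 * type_mean[cases$restoration_type]
  year <- restoration_year(cases)
  ys <- sort(unique(year))
  pct_or_na <- function(v) if (length(v) == 0L) NA_real_ else 100 * mean(v)
  out <- do.call(rbind, lapply(ys, function(yv) {
    sel <- year == yv
    data.frame(
      year = yv,
      composite_pct = pct_or_na(
        is_fail[sel & cases$restoration_type == "composite"]),
      amalgam_pct = pct_or_na(
        is_fail[sel & cases$restoration_type == "amalgam"]))
  }))
  rownames(out) <- NULL
  out
}

# -- method factories for five_by_two_cv / compare workflows ------------------

#' Built-in method factories for cross-validated comparisons
#'
#' `method_constant_mean()` predicts the training mean longevity;
#' `method_type_mean()` the training per-type mean; `method_mlp()` a plain
#' perceptron regressor on the one-hot descriptor; `method_cbr()` the full
#' knowledge-base pipeline using the retrieved-case average estimate.
#' Each returns a factory suitable for [five_by_two_cv()].
#'
#' @param config,seed,K,m tuning passed through to the underlying models.
#' @return A factory `function(train_cb) -> function(cases_df) -> numeric`.
#' @name method_factories
NULL

#' @rdname method_factories
#' @export
method_constant_mean <- function() function(train_cb) {
  mu <- mean(train_cb$cases$restoration_longevity)
  function(cases) rep(mu, nrow(cases))
}

#' @rdname method_factories
#' @export
method_type_mean <- function() function(train_cb) {
  mu <- tapply(train_cb$cases$restoration_longevity,
               train_cb$cases$restoration_type, mean)
  overall <- mean(train_cb$cases$restoration_longevity)
  function(cases) {
    out <- mu[cases$restoration_type]
    out[is.na(out)] <- overall
    as.numeric(out)
  }
}

#' @rdname method_factories
#' @export
method_mlp <- function(config = cbr_config(), seed = 1L) function(train_cb) {
  X <- encode_onehot(train_cb$cases, include_type = TRUE)
  fit <- fit_mlp_regressor(X, train_cb$cases$restoration_longevity,
                           seed = seed, eta = config$eta, mu = config$mu,
                           epochs = config$epochs,
                           validation_fraction = config$validation_fraction,
                           patience = config$patience)
  function(cases) pmax(predict(fit, encode_onehot(cases, include_type = TRUE)), 0)
}

#' @rdname method_factories
#' @export
method_cbr <- function(config = cbr_config(), seed = 1L, K = NULL,
                       m = NULL) function(train_cb) {
  kb <- build_knowledge_base(train_cb, config, seed = seed, K = K)
  mm <- m %||% config$m
  function(cases) vapply(seq_len(nrow(cases)), function(i) {
    case <- cases[i, , drop = FALSE]
    pred <- predict_restoration(kb, case, m = mm)
    pred$average_by_type[[case$restoration_type]]
  }, 0)
}
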