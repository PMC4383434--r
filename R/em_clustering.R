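#' Construct an encoded-record set for the mixture models
#'
#' Thin container pairing an integer-coded categorical matrix with a
#' numeric matrix, the shape produced by [encode_cases()] with
#' `target = "em"` and consumed by [em_fit()].
#'
#' @param cat integer matrix (codes start at 1) or `NULL`.
#' @param num numeric matrix or `NULL`.
#' @param cat_levels optional named list of level labels per categorical
#'   column; defaults to observed code ranges.
#' @return An `encoded_cases` object.
#' @export
encoded_records <- function(cat = NULL, num = NULL, cat_levels = NULL) {
  if (is.null(cat)) cat <- matrix(integer(0), nrow = NROW(num), ncol = 0L)
  if (is.null(num)) num <- matrix(numeric(0), nrow = NROW(cat), ncol = 0L)
  cat <- as.matrix(cat); storage.mode(cat) <- "integer"
  num <- as.matrix(num); storage.mode(num) <- "double"
  if (nrow(cat) != nrow(num))
    abort_dcbr("cat and num must have the same number of records",
               "dcbr_argument_error")
  if (is.null(colnames(cat)) && ncol(cat) > 0L)
    colnames(cat) <- paste0("c", seq_len(ncol(cat)))
  if (is.null(colnames(num)) && ncol(num) > 0L)
    colnames(num) <- paste0("x", seq_len(ncol(num)))
  if (is.null(cat_levels))
    cat_levels <- lapply(seq_len(ncol(cat)), function(j)
      as.character(seq_len(max(1L, cat[, j]))))
  if (ncol(cat) > 0L) names(cat_levels) <- colnames(cat)
  structure(list(cat = cat, num = num, cat_levels = cat_levels),
            class = "encoded_cases")
}

n_records <- function(data) nrow(data$cat)

cat_cardinalities <- function(data)
  vapply(seq_len(ncol(data$cat)), function(j)
    max(length(data$cat_levels[[j]]), max(data$cat[, j], 1L)), 1L)

# Per-record, per-cluster complete log-likelihood matrix (n x K) including
# the mixing weights; everything downstream (responsibilities, held-out
# log-likelihood, training loop) derives from it.
em_log_joint <- function(model, data) {
  n <- n_records(data)
  K <- model$K
  lp <- matrix(rep(log(model$pi), each = n), n, K)
  for (j in seq_along(model$cat_params))
    lp <- lp + log(model$cat_params[[j]])[data$cat[, j], , drop = FALSE]
  if (length(model$num_mean) > 0L)
    for (j in seq_len(ncol(model$num_mean))) {
      x <- data$num[, j]
      mu <- model$num_mean[, j]
      v <- model$num_var[, j]
      lp <- lp - 0.5 * (outer(x, mu, "-")^2 / rep(v, each = n) +
                          rep(log(2 * pi * v), each = n))
    }
  dimnames(lp) <- NULL
  lp
}

em_mstep <- function(data, resp, alpha, var_floor, cards) {
  n <- nrow(resp); K <- ncol(resp)
  Nk <- colSums(resp)
  pi_k <- Nk / n
  cat_params <- vector("list", ncol(data$cat))
  names(cat_params) <- colnames(data$cat)
  for (j in seq_len(ncol(data$cat))) {
    C <- cards[j]
    counts <- matrix(0, C, K)
    agg <- rowsum(resp, group = data$cat[, j])
    counts[as.integer(rownames(agg)), ] <- agg
    th <- counts + alpha
    cat_params[[j]] <- sweep(th, 2L, colSums(th), "/")
  }
  if (ncol(data$num) > 0L) {
    W <- t(resp)                                   # K x n
    num_mean <- (W %*% data$num) / Nk
    ex2 <- (W %*% data$num^2) / Nk
    num_var <- pmax(ex2 - num_mean^2, var_floor)
  } else {
    num_mean <- num_var <- matrix(0, K, 0L)
  }
  list(pi = pi_k, cat_params = cat_params,
       num_mean = num_mean, num_var = num_var)
}

#' Fit a mixture model over mixed-type records by expectation-maximization
#'
#' Alternates the E-step (posterior cluster responsibilities under the
#' current parameters) and the M-step (responsibility-weighted maximum
#' likelihood re-estimation) until the change in training log-likelihood
#' falls below `tol` or `max_iter` is reached.  Each cluster factorizes
#' naively across attributes: category probability tables (Laplace
#' smoothing `alpha`) for categorical columns and univariate Gaussians
#' (variance floored at `var_floor`) for numeric columns.  `restarts`
#' random initializations (hard random assignment of records to clusters)
#' are run and the best training log-likelihood kept; all randomness flows
#' from `seed`.
#'
#' @param data an `encoded_cases` object ([encode_cases()] /
#'   [encoded_records()]).
#' @param K number of clusters (1 <= K <= number of records).
#' @param tol absolute convergence tolerance on the mean per-record
#'   log-likelihood.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed.
#' @param restarts number of random restarts.
#' @param alpha Laplace smoothing for category tables.
#' @param var_floor lower bound for Gaussian variances.
#' @return An object of class `em_model`: mixing weights `pi`, per-cluster
#'   category tables `cat_params`, Gaussian `num_mean`/`num_var`, and the
#'   per-iteration `loglik_trace`.  The trace records the training
#'   objective the M-step maximizes -- the total log-likelihood plus the
#'   Laplace-smoothing log-prior -- which is non-decreasing by the EM
#'   guarantee and reduces to the plain log-likelihood when `alpha = 0`.
#' @export
em_fit <- function(data, K, tol = 1e-6, max_iter = 200L, seed = 1L,
                   restarts = 5L, alpha = 1, var_floor = 1e-6) {
  stopifnot(inherits(data, "encoded_cases"))
  n <- n_records(data)
  if (K < 1L) abort_dcbr("K must be >= 1", "dcbr_argument_error")
  if (K > n) abort_dcbr(sprintf("K = %d exceeds the %d records", K, n),
                        "dcbr_data_size_error")
  if (tol <= 0) abort_dcbr("tol must be > 0", "dcbr_argument_error")
  cards <- cat_cardinalities(data)

  # Forgy-style start: each restart seeds the clusters from K random
  # records (categorical tables smoothed toward the seed's categories,
  # Gaussians centred on the seed with the global variance), then one
  # E-step yields the initial responsibilities.  A uniform random hard
  # assignment makes every cluster start at the marginal distribution --
  # a symmetric saddle EM cannot leave.
  init_resp <- function() {
    seeds <- sample.int(n, K)
    cat_params <- lapply(seq_len(ncol(data$cat)), function(j) {
      tab <- matrix(1, cards[j], K)
      tab[cbind(data$cat[seeds, j], seq_len(K))] <- 1 + cards[j]
      sweep(tab, 2L, colSums(tab), "/")
    })
    names(cat_params) <- colnames(data$cat)
    if (ncol(data$num) > 0L) {
      gv <- pmax(apply(data$num, 2L, stats::var), var_floor)
      num_mean <- data$num[seeds, , drop = FALSE]
      num_var <- matrix(gv, K, ncol(data$num), byrow = TRUE)
    } else {
      num_mean <- num_var <- matrix(0, K, 0L)
    }
    m0 <- structure(list(K = K, pi = rep(1 / K, K), cat_params = cat_params,
                         num_mean = num_mean, num_var = num_var),
                    class = "em_model")
    responsibilities(m0, data)
  }

  # Short-run restart strategy: every restart runs a burn-in of EM cycles,
  # the best training log-likelihood wins, and only the winner is iterated
  # to convergence.
  burn_iter <- min(15L, max_iter)
  best <- with_seed(seed, {
    fits <- lapply(seq_len(max(1L, restarts)), function(r)
      em_run_cpp(data$cat, data$num, cards, init_resp(), alpha, var_floor,
                 tol, burn_iter))
    lls <- vapply(fits, function(f) f$trace[length(f$trace)], 0)
    win <- fits[[which.max(lls)]]
    if (max_iter > burn_iter) {
      cont <- em_run_cpp(data$cat, data$num, cards, win$resp, alpha,
                         var_floor, tol, max_iter - burn_iter)
      cont$trace <- c(win$trace, cont$trace)
      cont
    } else win
  })
  names(best$cat_params) <- colnames(data$cat)
  for (j in seq_along(best$cat_params))
    if (nrow(best$cat_params[[j]]) == length(data$cat_levels[[j]]))
      rownames(best$cat_params[[j]]) <- data$cat_levels[[j]]
  colnames(best$num_mean) <- colnames(best$num_var) <- colnames(data$num)
  structure(list(pi = as.numeric(best$pi), cat_params = best$cat_params,
                 num_mean = best$num_mean, num_var = best$num_var,
                 K = K, loglik_trace = best$trace, n = n,
                 cat_levels = data$cat_levels, alpha = alpha,
                 var_floor = var_floor, seed = seed),
            class = "em_model")
}

#' @export
print.em_model <- function(x, ...) {
  cat(sprintf(
    "EM mixture model: K = %d clusters over %d categorical + %d numeric attributes\n",
    x$K, length(x$cat_params), ncol(x$num_mean)))
  cat("Mixing weights:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat(sprintf("Final training log-likelihood: %.2f (%d iterations)\n",
              x$loglik_trace[length(x$loglik_trace)], length(x$loglik_trace)))
  invisible(x)
}

#' Posterior cluster membership probabilities
#'
#' Bayes-rule responsibilities: component `k` is proportional to the mixing
#' weight times the cluster's attribute likelihoods, computed in log space
#' and normalized to sum to one per record.
#'
#' @param model an [em_fit()] model.
#' @param data encoded records with the model's schema.
#' @return An `n x K` matrix of probabilities; rows sum to 1.
#' @export
responsibilities <- function(model, data) {
  stopifnot(inherits(model, "em_model"))
  lp <- em_log_joint(model, data)
  exp(lp - row_logsumexp(lp))
}

#' Mean held-out log-likelihood of records under a fitted mixture
#'
#' @param model an [em_fit()] model.
#' @param data nonempty encoded records.
#' @return Mean per-record log of the mixture density/mass.
#' @export
heldout_loglik <- function(model, data) {
  if (n_records(data) == 0L)
    abort_dcbr("no records", "dcbr_argument_error")
  mean(row_logsumexp(em_log_joint(model, data)))
}

subset_records <- function(data, idx)
  encoded_records(data$cat[idx, , drop = FALSE],
                  data$num[idx, , drop = FALSE], data$cat_levels)

#' Choose the number of clusters by cross-validated log-likelihood
#'
#' For k = 1, 2, ... the mean `folds`-fold held-out log-likelihood is
#' computed; k stops growing when the relative improvement
#' `(L_k - L_(k-1)) / |L_(k-1)|` no longer exceeds `threshold` (default
#' 1e-6), and the previous k is returned.
#'
#' @param data encoded records (at least `folds` of them).
#' @param k_max largest k to consider.
#' @param threshold relative-improvement stopping threshold.
#' @param folds number of cross-validation folds.
#' @param seed integer seed (controls fold assignment and all restarts).
#' @param ... passed to [em_fit()] (e.g. `restarts`, `max_iter`).
#' @return A list with `K` (the selected count) and `cv_table`, a
#'   data.frame of per-k, per-fold held-out log-likelihoods.
#' @export
select_k <- function(data, k_max = 6L, threshold = 1e-6, folds = 10L,
                     seed = 1L, ...) {
  if (k_max < 1L) abort_dcbr("k_max must be >= 1", "dcbr_argument_error")
  n <- n_records(data)
  if (n < folds)
    abort_dcbr(sprintf("%d records cannot form %d folds", n, folds),
               "dcbr_data_size_error")
  fold_id <- with_seed(derive_seed(seed, "folds"),
                       sample(rep_len(seq_len(folds), n)))
  rows <- list()
  mean_ll <- numeric(0)
  K_star <- k_max
  for (k in seq_len(k_max)) {
    fold_ll <- vapply(seq_len(folds), function(f) {
      train <- subset_records(data, fold_id != f)
      test <- subset_records(data, fold_id == f)
      fit <- em_fit(train, k, seed = derive_seed(seed, paste0("k", k, "f", f)),
                    ...)
      heldout_loglik(fit, test)
    }, 0)
    rows[[k]] <- data.frame(k = k, fold = seq_len(folds), loglik = fold_ll)
    mean_ll[k] <- mean(fold_ll)
    if (k >= 2L) {
      rel_gain <- (mean_ll[k] - mean_ll[k - 1L]) / abs(mean_ll[k - 1L])
      if (!(rel_gain > threshold)) { K_star <- k - 1L; break }
    }
  }
  list(K = K_star, cv_table = do.call(rbind, rows))
}
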