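#' Default configuration for the CBR system
#'
#' Collects every tunable of the pipeline in one validated list: retrieval
#' (`m` cases, confidence-limit width `z`), cluster-count selection
#' (`k_max`, relative-improvement `threshold`, `folds`), EM fitting
#' (`em_restarts`, `em_max_iter`, `em_tol`, Laplace `em_alpha`,
#' `var_floor`), Bayesian-network learning (`bn_alpha`, `bn_max_cond`,
#' Laplace `bn_laplace`, `bn_screen` attributes kept after
#' mutual-information screening, `bn_bins` discretization levels,
#' `longevity_bins` break points), perceptron training (`eta`, `mu`,
#' `epochs`, `patience`, `validation_fraction`), mixture stacking
#' (`oof_folds`, `min_cluster_cases`), retention (`refresh_threshold`) and
#' the `headline` estimate (`"average"` per retrieved-case averaging, or
#' `"mixture"`).
#'
#' @param ... overrides of the defaults.
#' @return A `cbr_config` list.
#' @export
cbr_config <- function(...) {
  defaults <- list(
    m = 20L, z = 2, k_max = 6L, threshold = 1e-6, folds = 10L,
    em_restarts = 5L, em_max_iter = 100L, em_tol = 1e-6, em_alpha = 1,
    var_floor = 1e-6,
    bn_alpha = 0.05, bn_max_cond = 3L, bn_laplace = 1, bn_screen = 10L,
    bn_bins = 4L, longevity_bins = c(seq(0, 20, by = 2), Inf),
    eta = 0.1, mu = 0.9, epochs = 200L, patience = 20L,
    validation_fraction = 0.2,
    oof_folds = 5L, min_cluster_cases = 20L,
    refresh_threshold = 50L, headline = "average")
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L)
    abort_dcbr(paste("unknown config keys:", paste(unknown, collapse = ", ")),
               "dcbr_config_error")
  defaults[names(over)] <- over
  if (!defaults$headline %in% c("average", "mixture"))
    abort_dcbr("headline must be 'average' or 'mixture'", "dcbr_config_error")
  structure(defaults, class = "cbr_config")
}

# G2 association statistic used only to rank attributes for screening.
assoc_stat <- function(x, y, rx, ry) {
  O <- table(factor(x, levels = seq_len(rx)), factor(y, levels = seq_len(ry)))
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  pos <- O > 0
  2 * sum(O[pos] * log(O[pos] / E[pos]))
}

bin_longevity <- function(y, bins) {
  b <- discretize_with_edges(y, bins)
  if (anyNA(b))
    abort_dcbr("longevity bins do not cover the observed longevities",
               "dcbr_binning_error")
  b
}

# Bayesian-network longevity expert: screen descriptor attributes by
# association with the binned longevity, learn a DAG over the survivors
# plus the longevity node, fit CPTs, and predict by posterior expectation.
fit_bn_longevity_expert <- function(cases, config) {
  enc <- encode_discrete(cases, include_type = TRUE, bins = config$bn_bins)
  edges <- attr(enc, "bin_edges")
  n_levels <- attr(enc, "n_levels")
  ybin <- bin_longevity(cases$restoration_longevity, config$longevity_bins)
  ry <- length(config$longevity_bins) - 1L
  stat <- vapply(names(enc), function(a)
    assoc_stat(enc[[a]], ybin, n_levels[[a]], ry), 0)
  keep <- names(sort(stat, decreasing = TRUE))[
    seq_len(min(config$bn_screen, length(stat)))]
  keep <- union(keep, "restoration_type")
  df <- enc[keep]
  attr(df, "n_levels") <- n_levels[keep]
  bn <- class_augmented_bn(df, ybin, ry, "longevity_bin",
                           alpha = config$bn_alpha,
                           max_cond = config$bn_max_cond,
                           laplace_alpha = config$bn_laplace)
  structure(list(bn = bn, screen = keep, edges = edges,
                 bins = config$longevity_bins, bn_bins = config$bn_bins),
            class = "bn_longevity_expert")
}

#' @export
predict.bn_longevity_expert <- function(object, newdata, ...) {
  cases <- if (inherits(newdata, "casebase")) newdata$cases else newdata
  enc <- encode_discrete(cases, include_type = TRUE,
                         bins = object$bn_bins, edges = object$edges)
  vapply(seq_len(nrow(enc)), function(i) {
    ev <- as.list(enc[i, object$screen, drop = FALSE])
    bn_expected_longevity(object$bn, ev, object$bins)
  }, 0)
}

#' Train the per-cluster mixture of experts
#'
#' Two experts predict restoration longevity from the 41-attribute problem
#' descriptor plus the candidate restoration type: a discretized-longevity
#' Bayesian network and a one-hidden-layer perceptron.  Their outputs feed
#' a second perceptron (2 inputs, 5 hidden neurons, 1 output) that
#' produces the final estimate.  The combiner is trained on out-of-fold
#' expert predictions from an internal `oof_folds`-fold split, so it never
#' sees resubstitution outputs; the final experts are then refit on all
#' cases.  Everything runs in the \[0.2, 0.8\] working range and is
#' deterministic given `seed`.
#'
#' @param cb a [casebase()] (typically one cluster's cases).
#' @param config a [cbr_config()].
#' @param seed integer seed.
#' @return An `expert_mixture` with `bn_expert`, `mlp_expert`, `combiner`.
#' @export
train_mixture <- function(cb, config = cbr_config(), seed = 1L) {
  cases <- if (inherits(cb, "casebase")) cb$cases else cb
  n <- nrow(cases)
  if (n < config$min_cluster_cases)
    abort_dcbr(sprintf("%d cases is below the training floor of %d",
                       n, config$min_cluster_cases),
               "dcbr_training_size_error")
  y <- cases$restoration_longevity

  fit_mlp_expert <- function(df, sd) {
    X <- encode_onehot(df, include_type = TRUE)
    fit_mlp_regressor(X, df$restoration_longevity, seed = sd,
                      eta = config$eta, mu = config$mu,
                      epochs = config$epochs,
                      validation_fraction = config$validation_fraction,
                      patience = config$patience)
  }
  predict_mlp_expert <- function(fit, df)
    predict(fit, encode_onehot(df, include_type = TRUE))

  fold_id <- with_seed(derive_seed(seed, "oof"),
                       sample(rep_len(seq_len(config$oof_folds), n)))
  oof_bn <- oof_mlp <- numeric(n)
  for (f in seq_len(config$oof_folds)) {
    tr <- cases[fold_id != f, , drop = FALSE]
    te <- cases[fold_id == f, , drop = FALSE]
    bn_f <- fit_bn_longevity_expert(tr, config)
    mlp_f <- fit_mlp_expert(tr, derive_seed(seed, paste0("mlpf", f)))
    oof_bn[fold_id == f] <- predict(bn_f, te)
    oof_mlp[fold_id == f] <- predict_mlp_expert(mlp_f, te)
  }

  bn_expert <- fit_bn_longevity_expert(cases, config)
  mlp_expert <- fit_mlp_expert(cases, derive_seed(seed, "mlp_final"))
  combiner <- fit_mlp_regressor(cbind(bn = oof_bn, mlp = oof_mlp), y,
                                seed = derive_seed(seed, "combiner"),
                                eta = config$eta, mu = config$mu,
                                epochs = config$epochs,
                                validation_fraction = config$validation_fraction,
                                patience = config$patience, n_hidden = 5L)
  structure(list(bn_expert = bn_expert, mlp_expert = mlp_expert,
                 combiner = combiner, config = config, seed = seed,
                 n_cases = n,
                 oof = data.frame(bn = oof_bn, mlp = oof_mlp, y = y)),
            class = "expert_mixture")
}

#' @export
print.expert_mixture <- function(x, ...) {
  cat(sprintf(
    "Mixture of experts (BN + MLP -> combiner MLP), trained on %d cases\n",
    x$n_cases))
  cat(sprintf("  out-of-fold expert MAE: BN %.2f y, MLP %.2f y\n",
              mean(abs(x$oof$bn - x$oof$y)), mean(abs(x$oof$mlp - x$oof$y))))
  invisible(x)
}

#' Predict an expert of a trained mixture on its own
#'
#' @param model an `expert_mixture`.
#' @param cb cases to predict.
#' @param expert `"bn"` or `"mlp"`.
#' @param type optional restoration type overriding the cases' own.
#' @return Longevity predictions in years.
#' @export
predict_expert <- function(model, cb, expert = c("bn", "mlp"), type = NULL) {
  expert <- match.arg(expert)
  cases <- if (inherits(cb, "casebase")) cb$cases else cb
  if (!is.null(type)) cases$restoration_type <- type
  if (expert == "bn") predict(model$bn_expert, cases)
  else predict(model$mlp_expert, encode_onehot(cases, include_type = TRUE))
}

#' Final mixture estimate for a case
#'
#' Runs both experts on the case descriptor (with `type` substituted as
#' the candidate restoration type when given), feeds their outputs to the
#' combiner perceptron and inverse-scales the result to years, clamped at
#' zero.
#'
#' @param model a trained `expert_mixture`.
#' @param cb case(s) to predict (a [casebase()] or a cases data.frame).
#' @param type optional restoration type (`"amalgam"`/`"composite"`).
#' @return Nonnegative longevity estimate(s) in years.
#' @export
mixture_predict <- function(model, cb, type = NULL) {
  if (!inherits(model, "expert_mixture"))
    abort_dcbr("model is not a trained mixture", "dcbr_state_error")
  cases <- if (inherits(cb, "casebase")) cb$cases else cb
  if (!is.null(type)) cases$restoration_type <- type
  p_bn <- predict(model$bn_expert, cases)
  p_mlp <- predict(model$mlp_expert, encode_onehot(cases, include_type = TRUE))
  out <- predict(model$combiner, cbind(bn = p_bn, mlp = p_mlp))
  pmax(out, 0)
}
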