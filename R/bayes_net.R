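# Discrete Bayesian network: constraint-based structure learning
# (conditional-independence tests in the Verma-Pearl style), Laplace-smoothed
# conditional probability tables, and exact inference by enumeration.

# Normalize input to an integer-coded data.frame plus per-variable
# cardinalities (factor levels, an `n_levels` attribute, or observed maxima).
as_discrete_df <- function(data) {
  stopifnot(is.data.frame(data))
  card <- attr(data, "n_levels")
  out <- data
  cards <- integer(ncol(data))
  names(cards) <- names(data)
  for (j in seq_along(data)) {
    v <- data[[j]]
    if (is.factor(v)) {
      cards[j] <- nlevels(v)
      out[[j]] <- as.integer(v)
    } else if (is.logical(v)) {
      cards[j] <- 2L
      out[[j]] <- as.integer(v) + 1L
    } else {
      out[[j]] <- as.integer(v)
      cards[j] <- max(out[[j]], 1L)
    }
    if (!is.null(card) && !is.null(card[[names(data)[j]]]))
      cards[j] <- max(cards[j], as.integer(card[[names(data)[j]]]))
  }
  list(df = out, cards = cards)
}

#' G-squared conditional-independence test for discrete variables
#'
#' Likelihood-ratio (G2) test of independence of `a` and `b` within each
#' stratum of the conditioning set `S`, summed over strata, with
#' `(|a|-1)(|b|-1)` degrees of freedom per nonempty stratum (empty strata
#' are skipped and contribute no df).  When fewer than `5 * df` records are
#' available the result is flagged independent by default, the standard
#' small-sample rule of constraint-based structure learning.
#'
#' @param data data.frame of discrete records (integers or factors).
#' @param a,b column names of the tested pair.
#' @param S character vector of conditioning column names (may be empty).
#' @param alpha significance level; independence is declared when
#'   `p_value > alpha`.
#' @return A list of class `ci_test_result`: `a`, `b`, `S`, `statistic`,
#'   `df`, `p_value`, `independent`, `small_sample`.
#' @export
ci_test <- function(data, a, b, S = character(0), alpha = 0.05) {
  if (a == b || a %in% S || b %in% S)
    abort_dcbr("a, b and S must be disjoint", "dcbr_argument_error")
  dd <- as_discrete_df(data)
  df_ <- dd$df
  n <- nrow(df_)
  ra <- dd$cards[[a]]; rb <- dd$cards[[b]]
  df_per_stratum <- (ra - 1L) * (rb - 1L)
  n_strata_total <- if (length(S) == 0L) 1L else prod(dd$cards[S])

  small <- n < 5L * df_per_stratum * n_strata_total
  if (small) {
    res <- list(a = a, b = b, S = S, statistic = 0, df = 0L, p_value = 1,
                independent = TRUE, small_sample = TRUE)
    class(res) <- "ci_test_result"
    return(res)
  }

  stratum <- if (length(S) == 0L) rep(1L, n)
             else as.integer(interaction(df_[S], drop = TRUE))
  g2 <- 0
  df_total <- 0L
  for (s in unique(stratum)) {
    idx <- stratum == s
    O <- table(factor(df_[[a]][idx], levels = seq_len(ra)),
               factor(df_[[b]][idx], levels = seq_len(rb)))
    ns <- sum(O)
    if (ns == 0L) next
    E <- outer(rowSums(O), colSums(O)) / ns
    pos <- O > 0
    g2 <- g2 + 2 * sum(O[pos] * log(O[pos] / E[pos]))
    df_total <- df_total + df_per_stratum
  }
  p <- if (df_total == 0L) 1 else stats::pchisq(g2, df_total,
                                                lower.tail = FALSE)
  res <- list(a = a, b = b, S = S, statistic = g2, df = df_total,
              p_value = p, independent = p > alpha, small_sample = FALSE)
  class(res) <- "ci_test_result"
  res
}

#' @export
print.ci_test_result <- function(x, ...) {
  cat(sprintf("G2 CI test: %s _||_ %s | {%s}\n", x$a, x$b,
              paste(x$S, collapse = ", ")))
  cat(sprintf("  G2 = %.4f, df = %d, p = %.4g -> %s%s\n", x$statistic, x$df,
              x$p_value, if (x$independent) "independent" else "dependent",
              if (x$small_sample) " (small-sample default)" else ""))
  invisible(x)
}

all_subsets <- function(x, size) {
  if (size == 0L) return(list(character(0)))
  if (length(x) < size) return(list())
  out <- utils::combn(x, size, simplify = FALSE)
  out
}

#' Learn a DAG by constraint-based (PC-style) structure search
#'
#' Starts from the complete undirected graph, removes an edge (a, b)
#' whenever some conditioning set S drawn from the neighbourhoods of a or b
#' with `|S| <= max_cond` renders them conditionally independent
#' ([ci_test()]), orients the v-structures found via the separating sets,
#' propagates orientations with the Meek rules, and finally orients any
#' remaining undirected edge from the lower- to the higher-indexed
#' attribute (reproducibility tie-break), refusing orientations that would
#' close a cycle.
#'
#' @param data data.frame of discrete records.
#' @param alpha significance level for the CI tests.
#' @param max_cond largest conditioning-set size.
#' @return A `bayes_net` object without CPTs (see [fit_cpts()]): `nodes`,
#'   `amat` (adjacency with `amat[a, b] = 1` for the edge a -> b), and the
#'   separating sets.
#' @export
learn_structure <- function(data, alpha = 0.05, max_cond = 3L) {
  dd <- as_discrete_df(data)
  vars <- names(dd$df)
  p <- length(vars)
  if (p < 1L) abort_dcbr("need at least one variable", "dcbr_argument_error")
  amat <- matrix(1L, p, p, dimnames = list(vars, vars))
  diag(amat) <- 0L
  sepset <- list()

  if (p >= 2L) {
    for (l in 0:max_cond) {
      pairs <- which(upper.tri(amat) & (amat == 1L | t(amat) == 1L),
                     arr.ind = TRUE)
      if (nrow(pairs) == 0L) break
      for (r in seq_len(nrow(pairs))) {
        a <- vars[pairs[r, 1L]]; b <- vars[pairs[r, 2L]]
        if (amat[a, b] == 0L && amat[b, a] == 0L) next
        adj_a <- setdiff(vars[amat[a, ] == 1L | amat[, a] == 1L], b)
        adj_b <- setdiff(vars[amat[b, ] == 1L | amat[, b] == 1L], a)
        cand <- unique(c(all_subsets(adj_a, l), all_subsets(adj_b, l)))
        removed <- FALSE
        for (S in cand) {
          ct <- ci_test(dd$df, a, b, S, alpha)
          if (ct$independent) {
            amat[a, b] <- amat[b, a] <- 0L
            sepset[[paste(a, b, sep = "|")]] <- S
            sepset[[paste(b, a, sep = "|")]] <- S
            removed <- TRUE
            break
          }
        }
        if (removed) next
      }
    }

    # v-structures: a - c - b with a, b nonadjacent and c outside sepset(a,b)
    for (ci in seq_len(p)) {
      cvar <- vars[ci]
      nb <- vars[amat[cvar, ] == 1L | amat[, cvar] == 1L]
      if (length(nb) < 2L) next
      for (pair in all_subsets(nb, 2L)) {
        a <- pair[1L]; b <- pair[2L]
        if (amat[a, b] == 1L || amat[b, a] == 1L) next
        S <- sepset[[paste(a, b, sep = "|")]]
        if (!is.null(S) && !(cvar %in% S)) {
          amat[a, cvar] <- 1L; amat[cvar, a] <- 0L
          amat[b, cvar] <- 1L; amat[cvar, b] <- 0L
        }
      }
    }
    amat <- meek_orient(amat)
    amat <- orient_remaining(amat)
  }
  structure(list(nodes = vars, amat = amat, sepset = sepset,
                 cards = dd$cards, cpts = NULL),
            class = "bayes_net")
}

is_directed <- function(amat, a, b) amat[a, b] == 1L && amat[b, a] == 0L
is_undirected <- function(amat, a, b) amat[a, b] == 1L && amat[b, a] == 1L

directed_acyclic <- function(amat) {
  dir <- (amat == 1L) & (t(amat) == 0L)
  deg <- colSums(dir)
  remaining <- rep(TRUE, ncol(dir))
  for (i in seq_len(ncol(dir))) {
    z <- which(remaining & deg == 0L)
    if (length(z) == 0L) return(FALSE)
    z <- z[1L]
    remaining[z] <- FALSE
    deg <- deg - dir[z, ]
    deg[!remaining] <- -1L
  }
  TRUE
}

would_cycle <- function(amat, a, b) {
  # would orienting a -> b create a directed cycle? i.e. is there already a
  # directed path b ~> a
  dir <- (amat == 1L) & (t(amat) == 0L)
  reach <- dir[b, ] > 0
  repeat {
    nxt <- (colSums(dir[reach, , drop = FALSE]) > 0) | reach
    if (all(nxt == reach)) break
    reach <- nxt
  }
  reach[a]
}

meek_orient <- function(amat) {
  vars <- rownames(amat)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (a in vars) for (b in vars) {
      if (!is_undirected(amat, a, b)) next
      # R1: c -> a, c and b nonadjacent  =>  a -> b
      for (cvar in vars) {
        if (cvar %in% c(a, b)) next
        if (is_directed(amat, cvar, a) &&
            amat[cvar, b] == 0L && amat[b, cvar] == 0L) {
          amat[a, b] <- 1L; amat[b, a] <- 0L; changed <- TRUE; break
        }
      }
      if (!is_undirected(amat, a, b)) next
      # R2: a -> c -> b  =>  a -> b
      for (cvar in vars) {
        if (cvar %in% c(a, b)) next
        if (is_directed(amat, a, cvar) && is_directed(amat, cvar, b)) {
          amat[a, b] <- 1L; amat[b, a] <- 0L; changed <- TRUE; break
        }
      }
      if (!is_undirected(amat, a, b)) next
      # R3: a - c -> b and a - d -> b with c, d nonadjacent  =>  a -> b
      cand <- vars[vapply(vars, function(cvar)
        !(cvar %in% c(a, b)) && is_undirected(amat, a, cvar) &&
          is_directed(amat, cvar, b), TRUE)]
      if (length(cand) >= 2L) {
        for (pair in all_subsets(cand, 2L)) {
          if (amat[pair[1L], pair[2L]] == 0L &&
              amat[pair[2L], pair[1L]] == 0L) {
            amat[a, b] <- 1L; amat[b, a] <- 0L; changed <- TRUE; break
          }
        }
      }
    }
  }
  amat
}

orient_remaining <- function(amat) {
  vars <- rownames(amat)
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (j <= i) next
    a <- vars[i]; b <- vars[j]
    if (is_undirected(amat, a, b)) {
      if (!would_cycle(amat, a, b)) {
        amat[a, b] <- 1L; amat[b, a] <- 0L
      } else {
        amat[b, a] <- 1L; amat[a, b] <- 0L
      }
    }
  }
  amat
}

bn_parents <- function(bn, node)
  bn$nodes[bn$amat[, node] == 1L & bn$amat[node, ] == 0L]

#' Fit conditional probability tables on a learned DAG
#'
#' Each node's CPT holds the Laplace-smoothed conditional frequency of the
#' node given each configuration of its parents; parent configurations
#' never seen in the data get a uniform row.
#'
#' @param dag a `bayes_net` from [learn_structure()] (or any object with
#'   `nodes`/`amat`/`cards`).
#' @param data discrete records over the DAG's variables.
#' @param laplace_alpha Laplace smoothing count (0 for raw frequencies).
#' @return The `bayes_net` with a `cpts` field: per node, a matrix with one
#'   row per parent configuration (rows sum to 1) plus the parent
#'   cardinalities needed to index it.
#' @export
fit_cpts <- function(dag, data, laplace_alpha = 1) {
  dd <- as_discrete_df(data)
  stopifnot(all(dag$nodes %in% names(dd$df)))
  cards <- pmax(dag$cards, dd$cards[dag$nodes])
  cpts <- list()
  for (node in dag$nodes) {
    pars <- bn_parents(dag, node)
    r <- cards[[node]]
    if (length(pars) == 0L) {
      counts <- tabulate(dd$df[[node]], nbins = r)
      tab <- matrix(counts + laplace_alpha, 1L, r)
    } else {
      pc <- cards[pars]
      n_cfg <- prod(pc)
      cfg <- config_index(dd$df[pars], pc)
      tab <- matrix(laplace_alpha, n_cfg, r)
      agg <- table(factor(cfg, levels = seq_len(n_cfg)),
                   factor(dd$df[[node]], levels = seq_len(r)))
      tab <- tab + unclass(agg)
    }
    rs <- rowSums(tab)
    zero <- rs == 0
    tab[zero, ] <- 1 / r                 # unseen configuration -> uniform
    rs[zero] <- 1
    cpts[[node]] <- list(prob = tab / rs, parents = pars,
                         parent_cards = if (length(pars)) cards[pars]
                                        else integer(0))
  }
  dag$cpts <- cpts
  dag$cards <- cards
  dag$laplace_alpha <- laplace_alpha
  dag
}

# Mixed-radix row index of a parent configuration (first parent varies
# fastest), matching fit_cpts' table layout.
config_index <- function(par_df, pc) {
  if (length(pc) == 0L) return(rep(1L, nrow(as.data.frame(par_df))))
  par_df <- as.data.frame(par_df)
  idx <- rep(1L, nrow(par_df))
  mult <- 1L
  for (j in seq_along(pc)) {
    idx <- idx + (as.integer(par_df[[j]]) - 1L) * mult
    mult <- mult * pc[j]
  }
  idx
}

# Class-augmented network: the inter-attribute structure is learned by the
# constraint-based search, then the class node is attached as a parent of
# every attribute (guaranteeing the class stays informative even where the
# small-sample CI rule prunes aggressively), and CPTs are fitted on the
# joint data.  Acyclic by construction: the class has only outgoing edges.
class_augmented_bn <- function(attrs, class_values, class_card, class_name,
                               alpha = 0.05, max_cond = 3L,
                               laplace_alpha = 1) {
  skel <- learn_structure(attrs, alpha = alpha, max_cond = max_cond)
  nodes <- c(skel$nodes, class_name)
  p <- length(nodes)
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  amat[skel$nodes, skel$nodes] <- skel$amat
  amat[class_name, skel$nodes] <- 1L
  df <- attrs
  df[[class_name]] <- as.integer(class_values)
  attr(df, "n_levels") <- c(attr(attrs, "n_levels"),
                            stats::setNames(list(class_card), class_name))
  dag <- structure(list(nodes = nodes, amat = amat,
                        cards = c(skel$cards,
                                  stats::setNames(class_card, class_name)),
                        cpts = NULL), class = "bayes_net")
  fit_cpts(dag, df, laplace_alpha)
}

#' Convenience: learn structure and fit CPTs in one call
#'
#' @inheritParams learn_structure
#' @inheritParams fit_cpts
#' @return A fully parameterized `bayes_net`.
#' @export
bn_fit <- function(data, alpha = 0.05, max_cond = 3L, laplace_alpha = 1) {
  fit_cpts(learn_structure(data, alpha, max_cond), data, laplace_alpha)
}

#' @export
print.bayes_net <- function(x, ...) {
  dirs <- which((x$amat == 1L) & (t(x$amat) == 0L), arr.ind = TRUE)
  cat(sprintf("Bayesian network: %d nodes, %d directed edges%s\n",
              length(x$nodes), nrow(dirs),
              if (is.null(x$cpts)) " (structure only)" else ""))
  if (nrow(dirs) > 0L) {
    e <- apply(dirs, 1L, function(ij)
      paste(x$nodes[ij[1L]], "->", x$nodes[ij[2L]]))
    cat(" ", paste(e, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Exact posterior of a target node by enumeration
#'
#' Sums the factorized joint over every configuration of the non-evidence
#' variables; networks used here are small, so full enumeration is exact
#' and fast.
#'
#' @param bn a CPT-fitted `bayes_net`.
#' @param evidence named list/vector of observed values (integer codes).
#' @param target name of the query node (must not be in the evidence).
#' @return A probability vector over the target's levels, summing to 1.
#' @export
bn_posterior <- function(bn, evidence, target) {
  if (is.null(bn$cpts)) abort_dcbr("network has no CPTs", "dcbr_state_error")
  if (target %in% names(evidence))
    abort_dcbr("target may not be part of the evidence", "dcbr_argument_error")
  ev <- lapply(evidence, as.integer)
  for (v in names(ev)) {
    if (!v %in% bn$nodes) abort_dcbr(paste("unknown variable", v),
                                     "dcbr_argument_error")
    if (ev[[v]] < 1L || ev[[v]] > bn$cards[[v]])
      abort_dcbr(sprintf("evidence value %d outside the domain of %s",
                         ev[[v]], v), "dcbr_domain_error")
  }
  free <- setdiff(bn$nodes, names(ev))
  if (!(target %in% free)) abort_dcbr("unknown target", "dcbr_argument_error")
  sz <- prod(bn$cards[free])
  if (sz > 2e6)
    abort_dcbr("enumeration space too large", "dcbr_argument_error")
  grid <- do.call(expand.grid, lapply(bn$cards[free], seq_len))
  names(grid) <- free
  for (v in names(ev)) grid[[v]] <- ev[[v]]
  logp <- rep(0, nrow(grid))
  for (node in bn$nodes) {
    cpt <- bn$cpts[[node]]
    cfg <- config_index(grid[cpt$parents], cpt$parent_cards)
    logp <- logp + log(cpt$prob[cbind(cfg, as.integer(grid[[node]]))])
  }
  w <- exp(logp - max(logp))
  post <- vapply(seq_len(bn$cards[[target]]), function(lev)
    sum(w[grid[[target]] == lev]), 0)
  post / sum(post)
}

#' Expected longevity from a discretized-longevity network
#'
#' The network's target node indexes ordered longevity intervals; the
#' posterior over intervals is collapsed to years by the interval
#' midpoints (the top, open interval uses its lower edge plus half the
#' median bin width).
#'
#' @param bn a CPT-fitted `bayes_net` whose target node is the binned
#'   longevity variable.
#' @param evidence named evidence values (integer codes).
#' @param bins ordered numeric break points of the longevity bins (length =
#'   number of intervals + 1; the last may be `Inf`).
#' @param target name of the longevity node (default `"longevity_bin"`).
#' @return Expected longevity in years.
#' @export
bn_expected_longevity <- function(bn, evidence, bins,
                                  target = "longevity_bin") {
  if (length(bins) < 2L || is.unsorted(bins))
    abort_dcbr("bins must be ordered break points", "dcbr_binning_error")
  post <- bn_posterior(bn, evidence, target)
  if (length(post) != length(bins) - 1L)
    abort_dcbr("bins do not match the network's longevity node",
               "dcbr_binning_error")
  mids <- bin_midpoints(bins)
  sum(post * mids)
}

bin_midpoints <- function(bins) {
  lo <- bins[-length(bins)]
  hi <- bins[-1L]
  w <- hi - lo
  med_w <- stats::median(w[is.finite(w)])
  mids <- (lo + hi) / 2
  open <- !is.finite(hi)
  mids[open] <- lo[open] + med_w / 2
  low_open <- !is.finite(lo)
  mids[low_open] <- hi[low_open] - med_w / 2
  mids
}
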