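# Versioned JSON model files.  Matrices are stored with dimnames, dates as
# ISO strings; mixture caches are not persisted (they are lazy by design
# and retrain deterministically from the stored seed).

KB_FORMAT <- list(kind = "dentalcbr_knowledge_base", version = 1L)
EM_FORMAT <- list(kind = "dentalcbr_em_model", version = 1L)

mat_out <- function(m) list(data = as.vector(m), dim = dim(m),
                            rn = rownames(m) %||% character(0),
                            cn = colnames(m) %||% character(0))
mat_in <- function(x) {
  m <- matrix(unlist(x$data) %||% vector(mode = "numeric", 0L),
              x$dim[[1L]], x$dim[[2L]])
  rn <- unlist(x$rn); cn <- unlist(x$cn)
  if (length(rn) == nrow(m)) rownames(m) <- rn
  if (length(cn) == ncol(m)) colnames(m) <- cn
  m
}

em_out <- function(em) list(
  K = em$K, pi = em$pi,
  cat_params = lapply(em$cat_params, mat_out),
  num_mean = mat_out(em$num_mean), num_var = mat_out(em$num_var),
  cat_levels = em$cat_levels, loglik_trace = em$loglik_trace,
  alpha = em$alpha, var_floor = em$var_floor, n = em$n, seed = em$seed)

em_in <- function(x) {
  out <- list(K = x$K, pi = unlist(x$pi),
              cat_params = lapply(x$cat_params, mat_in),
              num_mean = mat_in(x$num_mean), num_var = mat_in(x$num_var),
              cat_levels = lapply(x$cat_levels, unlist),
              loglik_trace = unlist(x$loglik_trace),
              alpha = x$alpha, var_floor = x$var_floor, n = x$n,
              seed = x$seed)
  class(out) <- "em_model"
  out
}

bn_out <- function(bn) list(
  nodes = bn$nodes, amat = mat_out(bn$amat), cards = as.list(bn$cards),
  cpts = lapply(bn$cpts, function(cpt) list(
    prob = mat_out(cpt$prob), parents = cpt$parents,
    parent_cards = as.list(cpt$parent_cards))))

bn_in <- function(x) {
  cards <- unlist(x$cards)
  cpts <- lapply(x$cpts, function(cpt) list(
    prob = mat_in(cpt$prob), parents = unlist(cpt$parents) %||% character(0),
    parent_cards = {
      pc <- unlist(cpt$parent_cards)
      if (is.null(pc)) integer(0) else pc
    }))
  structure(list(nodes = unlist(x$nodes), amat = mat_in(x$amat),
                 cards = cards, cpts = cpts), class = "bayes_net")
}

classifier_out <- function(cl) list(
  bn = bn_out(cl$bn), screen = cl$screen, K = cl$K, bn_bins = cl$bn_bins,
  edges = lapply(cl$edges, function(e) {
    e[!is.finite(e)] <- sign(e[!is.finite(e)]) * 1e308
    e
  }))

classifier_in <- function(x) {
  edges <- lapply(x$edges, function(e) {
    e <- unlist(e)
    e[abs(e) >= 1e307] <- sign(e[abs(e) >= 1e307]) * Inf
    e
  })
  structure(list(bn = bn_in(x$bn), screen = unlist(x$screen), K = x$K,
                 bn_bins = x$bn_bins, edges = edges),
            class = "cluster_classifier")
}

#' Save / load a knowledge base as a versioned JSON model file
#'
#' The file self-describes its schema (`kind`, `version`) and loading
#' refuses a mismatched version.  The case-base is embedded; per-cluster
#' mixtures are not persisted and retrain lazily (deterministically, from
#' the stored seed) after loading.
#'
#' @param kb a [build_knowledge_base()] knowledge base.
#' @param path file path.
#' @return `kb_save` returns `path` invisibly; `kb_load` the knowledge
#'   base.
#' @export
kb_save <- function(kb, path) {
  cc <- kb$casebase$cases
  cases <- cc
  for (col in names(cases)) if (inherits(cases[[col]], "Date"))
    cases[[col]] <- format(cases[[col]], "%Y-%m-%d")
  payload <- list(
    format = KB_FORMAT,
    reference_date = format(kb$casebase$reference_date, "%Y-%m-%d"),
    cases = cases,
    em = em_out(kb$em), K = kb$K, labels = kb$labels,
    classifier = classifier_out(kb$classifier),
    num_range = mat_out(kb$num_range),
    config = unclass(kb$config), seed = kb$seed)
  payload$config$longevity_bins[!is.finite(payload$config$longevity_bins)] <- 1e308
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname kb_save
#' @export
kb_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$format$kind) || x$format$kind != KB_FORMAT$kind ||
      x$format$version != KB_FORMAT$version)
    abort_dcbr(sprintf("unsupported model file (kind %s, version %s)",
                       x$format$kind %||% "?", x$format$version %||% "?"),
               "dcbr_model_version_error")
  cases <- as.data.frame(x$cases, stringsAsFactors = FALSE)
  for (col in c("date_of_birth", "prior_restoration_date",
                "restoration_date"))
    cases[[col]] <- as.Date(cases[[col]])
  cfg <- x$config
  cfg$longevity_bins[cfg$longevity_bins >= 1e307] <- Inf
  config <- do.call(cbr_config, cfg)
  cb <- casebase(cases, as.Date(x$reference_date), validate = FALSE)
  kb <- structure(list(
    casebase = cb, em = em_in(x$em), K = x$K, labels = x$labels,
    classifier = classifier_in(x$classifier),
    limits = confidence_limits(cb$cases, x$labels, x$K, config$z),
    selection = NULL, num_range = mat_in(x$num_range),
    config = config, seed = x$seed,
    cache = new.env(parent = emptyenv()),
    counters = new.env(parent = emptyenv())),
    class = "cbr_knowledge_base")
  kb$counters$mixture_trainings <- 0L
  kb$counters$retains_since_build <- 0L
  kb$counters$em_rebuilds <- 0L
  kb
}

em_save <- function(em, path) {
  jsonlite::write_json(c(list(format = EM_FORMAT), em_out(em)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

em_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$format$kind) || x$format$kind != EM_FORMAT$kind ||
      x$format$version != EM_FORMAT$version)
    abort_dcbr("unsupported EM model file", "dcbr_model_version_error")
  em_in(x)
}
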