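#' Interaction model parameters
#'
#' Parameters of the neighbourhood-based interaction scorer. The full-scale
#' defaults of the method are 500 clusters, k = 2000 nearest neighbours,
#' scaling `nu = 7.5` and offset `gamma = 0`; at desk scale both cluster
#' count and neighbour count shrink with the vocabulary (see Details).
#'
#' @details When `clusters` or `knn` is `NULL` they are resolved against the
#' vocabulary size V at fit time as `clusters = min(500, ceiling(V/4))` and
#' `knn = min(2000, max(1, ceiling(V/2)))`. The neighbour count must stay
#' well below V for the neighbourhood distribution to be discriminative: if
#' k approaches V every component's neighbourhood degenerates to the global
#' cluster histogram and all interaction scores collapse towards 1.
#'
#' @param nu Positive scaling parameter of the exponential score.
#' @param gamma Offset parameter (score is clipped to 1 when `gamma > 0`).
#' @param clusters Number of k-means clusters C, or `NULL` to scale with the
#'   vocabulary.
#' @param knn Number of nearest neighbours k, or `NULL` to scale with the
#'   vocabulary.
#' @param nstart Number of k-means initializations (deterministic under the
#'   model seed).
#' @param seed Integer seed for clustering.
#' @return Object of class `interaction_params`.
#' @export
interaction_params <- function(nu = 7.5, gamma = 0, clusters = NULL,
                               knn = NULL, nstart = 1L, seed = 1L) {
  stopifnot(nu > 0)
  structure(list(nu = nu, gamma = gamma, clusters = clusters, knn = knn,
                 nstart = nstart, seed = seed),
            class = "interaction_params")
}

resolve_params <- function(params, vocab_size) {
  C <- params$clusters %||% min(500L, as.integer(ceiling(vocab_size / 4)))
  k <- params$knn %||% min(2000L, max(1L, as.integer(ceiling(vocab_size / 2))))
  C <- max(1L, min(C, vocab_size))
  k <- max(1L, min(k, vocab_size - 1L))
  list(C = C, k = k)
}

#' Fit the neighbourhood interaction model
#'
#' Partitions all embedding vectors into C clusters with k-means, finds each
#' component's k nearest neighbours by cosine similarity (the query itself
#' excluded), and represents every component by its neighbourhood
#' distribution: the cluster-occupancy histogram of its neighbours divided
#' by k.
#'
#' @param space An [embedding_space()].
#' @param params An [interaction_params()].
#' @return Object of class `interaction_model` with fields `neighborhoods`
#'   (V x C matrix of neighbourhood distributions, row names = vocabulary),
#'   `clusters` (integer cluster assignment), `params` (with resolved `C`,
#'   `k`), `vocabulary`.
#' @export
fit_interaction <- function(space, params = interaction_params()) {
  stopifnot(inherits(space, "embedding_space"),
            inherits(params, "interaction_params"))
  V <- length(space$vocabulary)
  if (V < 2L) stop_config("interaction model needs at least 2 components")
  rs <- resolve_params(params, V)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  km <- suppressWarnings(
    stats::kmeans(space$vectors, centers = rs$C, nstart = params$nstart,
                  iter.max = 50L)
  )
  sim <- cosine_matrix(space$vectors)
  diag(sim) <- -Inf
  nb <- matrix(0, nrow = V, ncol = rs$C,
               dimnames = list(space$vocabulary, NULL))
  for (i in seq_len(V)) {
    nn <- order(sim[i, ], decreasing = TRUE)[seq_len(rs$k)]
    occ <- tabulate(km$cluster[nn], nbins = rs$C)
    nb[i, ] <- occ / rs$k
  }
  params$clusters <- rs$C
  params$knn <- rs$k
  interaction_model(nb, params, clusters = km$cluster)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Construct an interaction model from neighbourhood distributions
#'
#' Direct constructor, used by [fit_interaction()] and available for tests
#' or externally computed distributions.
#'
#' @param neighborhoods Numeric matrix, one row per component (row names
#'   required), each row a probability distribution over clusters.
#' @param params An [interaction_params()].
#' @param clusters Optional integer cluster assignment of the components.
#' @return Object of class `interaction_model`.
#' @export
interaction_model <- function(neighborhoods, params = interaction_params(),
                              clusters = NULL) {
  stopifnot(is.matrix(neighborhoods), !is.null(rownames(neighborhoods)))
  if (any(neighborhoods < 0)) stop("neighbourhood probabilities must be >= 0")
  sums <- rowSums(neighborhoods)
  if (any(abs(sums - 1) > 1e-8)) {
    stop("neighbourhood distributions must sum to 1")
  }
  structure(list(neighborhoods = neighborhoods, params = params,
                 clusters = clusters,
                 vocabulary = rownames(neighborhoods)),
            class = "interaction_model")
}

#' @export
print.interaction_model <- function(x, ...) {
  cat(sprintf(
    "<interaction_model> %d components, %d clusters, k = %s, nu = %g, gamma = %g\n",
    length(x$vocabulary), ncol(x$neighborhoods),
    x$params$knn %||% "?", x$params$nu, x$params$gamma))
  invisible(x)
}

#' Neighbourhood distribution of a component
#'
#' @param model An `interaction_model`.
#' @param component Component name.
#' @return Numeric probability vector over the C clusters.
#' @export
neighborhood_distribution <- function(model, component) {
  stopifnot(inherits(model, "interaction_model"))
  if (!component %in% model$vocabulary) stop_oov(component)
  model$neighborhoods[component, , drop = TRUE]
}

#' Kullback-Leibler divergence between discrete distributions
#'
#' \eqn{D_{KL}(P\|Q) = \sum_i P(i) \log[P(i)/Q(i)]} with natural logarithm;
#' terms with \eqn{P(i) = 0} contribute 0. Where \eqn{P(i) > 0} but
#' \eqn{Q(i) = 0} the divergence is infinite and `Inf` is returned.
#'
#' @param p,q Numeric probability vectors of equal length.
#' @return Non-negative real (possibly `Inf`).
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("distributions must have equal length")
  pos <- p > 0
  if (any(q[pos] == 0)) return(Inf)
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Jensen-Shannon divergence
#'
#' \eqn{JSD(P\|Q) = \frac12 D_{KL}(P\|M) + \frac12 D_{KL}(Q\|M)} with
#' \eqn{M = \frac12(P+Q)}. Always finite (M dominates both arguments),
#' symmetric, and bounded by \eqn{\log 2} under the natural logarithm.
#'
#' @inheritParams kl_divergence
#' @return Real in \eqn{[0, \log 2]}.
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("distributions must have equal length")
  m <- (p + q) / 2
  0.5 * kl_divergence(p, m) + 0.5 * kl_divergence(q, m)
}

#' Interaction score between two components
#'
#' \eqn{I(w_\alpha, w_\beta) = \exp(-\nu \cdot JSD_{\alpha,\beta} + \gamma)}
#' computed on the two components' neighbourhood distributions; symmetric in
#' its arguments, in \eqn{[0, 1]} for \eqn{\gamma \le 0} and clipped to 1
#' otherwise.
#'
#' @param model An `interaction_model`.
#' @param w_alpha,w_beta Component names.
#' @return Real in \eqn{[0, 1]}.
#' @export
interaction_score <- function(model, w_alpha, w_beta) {
  p <- neighborhood_distribution(model, w_alpha)
  q <- neighborhood_distribution(model, w_beta)
  score_from_jsd(js_divergence(p, q), model$params$nu, model$params$gamma)
}

score_from_jsd <- function(jsd, nu, gamma) {
  min(1, exp(-nu * jsd + gamma))
}

#' Plain distance-based similarity (comparison scorer)
#'
#' Alternative interaction scorers built directly on embedding-space
#' distances, used to compare against the neighbourhood/JSD scorer: cosine
#' similarity mapped to \eqn{(1+\cos)/2}, Euclidean and Manhattan distances
#' mapped through \eqn{\exp(-\nu d)}.
#'
#' @param space An [embedding_space()].
#' @param w_alpha,w_beta Component names.
#' @param metric `"cosine"`, `"euclidean"` or `"manhattan"`.
#' @param nu Scaling for the distance-based variants.
#' @return Similarity in \eqn{[0, 1]}.
#' @export
baseline_distance_score <- function(space, w_alpha, w_beta,
                                    metric = c("cosine", "euclidean",
                                               "manhattan"),
                                    nu = 7.5) {
  stopifnot(inherits(space, "embedding_space"))
  metric <- tryCatch(match.arg(metric),
                     error = function(e) stop_config("unknown metric"))
  for (w in c(w_alpha, w_beta)) {
    if (!w %in% space$vocabulary) stop_oov(w)
  }
  a <- space$vectors[w_alpha, ]
  b <- space$vectors[w_beta, ]
  switch(metric,
    cosine = {
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) return(0.5)
      (1 + sum(a * b) / (na * nb)) / 2
    },
    euclidean = exp(-nu * sqrt(sum((a - b)^2))),
    manhattan = exp(-nu * sum(abs(a - b)))
  )
}

#' Read/write an interaction model as sparse TSV
#'
#' Columns `component`, `cluster`, `prob` (zero entries omitted), preceded
#' by a comment header carrying C, k, nu and gamma.
#'
#' @param model An `interaction_model`.
#' @param path File path.
#' @return `read_interaction_model()` returns an `interaction_model`.
#' @export
write_interaction_model <- function(model, path) {
  stopifnot(inherits(model, "interaction_model"))
  nb <- model$neighborhoods
  idx <- which(nb > 0, arr.ind = TRUE)
  df <- data.frame(component = rownames(nb)[idx[, 1]],
                   cluster = idx[, 2], prob = nb[idx])
  df <- df[order(match(df$component, rownames(nb)), df$cluster), ]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# C=%d k=%d nu=%.10g gamma=%.10g",
                     ncol(nb), model$params$knn %||% -1L,
                     model$params$nu, model$params$gamma), con)
  writeLines("component\tcluster\tprob", con)
  writeLines(sprintf("%s\t%d\t%.17g", df$component, df$cluster, df$prob), con)
  invisible(path)
}

#' @rdname write_interaction_model
#' @export
read_interaction_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- regmatches(lines[1],
                    gregexpr("[-+]?[0-9]*\\.?[0-9]+(e[-+]?[0-9]+)?", lines[1]))[[1]]
  C <- as.integer(hdr[1]); k <- as.integer(hdr[2])
  nu <- as.numeric(hdr[3]); gamma <- as.numeric(hdr[4])
  df <- read.delim(textConnection(lines[-1]), stringsAsFactors = FALSE)
  comps <- unique(df$component)
  nb <- matrix(0, nrow = length(comps), ncol = C,
               dimnames = list(comps, NULL))
  nb[cbind(match(df$component, comps), df$cluster)] <- df$prob
  interaction_model(nb, interaction_params(nu = nu, gamma = gamma,
                                           clusters = C,
                                           knn = if (k > 0) k else NULL))
}
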