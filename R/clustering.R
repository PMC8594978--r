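#' Convert a similarity matrix to a distance matrix
#'
#' `dist = max(0, 1 - sim)` after rescaling by the matrix maximum when that
#' maximum exceeds 1 (the Resnik case, whose similarities are IC-scaled
#' rather than bounded by 1). The diagonal maps to 0.
#'
#' @param sim Symmetric similarity matrix with unit diagonal.
#' @return Symmetric distance matrix, zero diagonal.
#' @export
similarity_to_distance <- function(sim) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim) ||
      !isTRUE(all.equal(sim, t(sim), tolerance = 1e-8, check.attributes = FALSE))) {
    stop("similarity matrix must be square and symmetric", call. = FALSE)
  }
  if (any(!is.finite(sim))) stop("similarity matrix has non-finite values", call. = FALSE)
  mx <- max(sim)
  s <- if (mx > 1) sim / mx else sim
  d <- 1 - s
  d[d < 0] <- 0
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# Normalised spectral embedding (symmetric Laplacian): top-k eigenvectors of
# D^{-1/2} A D^{-1/2}, rows normalised to unit length.
spectral_embedding <- function(affinity, k) {
  a <- affinity
  a[a < 0] <- 0
  deg <- rowSums(a)
  deg[deg <= 0] <- 1e-12
  dhalf <- 1 / sqrt(deg)
  lsym <- a * tcrossprod(dhalf) # D^{-1/2} A D^{-1/2}
  ev <- eigen(lsym, symmetric = TRUE)
  emb <- ev$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(emb^2))
  rn[rn == 0] <- 1
  emb / rn
}

#' Cluster documents from a similarity matrix
#'
#' Three algorithms operate on the document similarity:
#' * `"spectral"`: the similarity matrix is taken as a precomputed graph
#'   affinity (documents are vertices, similarities edge weights); the
#'   normalised spectral embedding is clustered with k-means.
#' * `"agglomerative"`: average-linkage hierarchical clustering on
#'   [similarity_to_distance()] of the matrix, cut at `k`.
#' * `"kmeans"`: each document is embedded as its row of the similarity
#'   matrix and k-means is run on those feature vectors.
#'
#' All stochastic steps are driven by `seed`, so results are reproducible.
#'
#' @param sim Symmetric similarity matrix, unit diagonal, doc-id dimnames.
#' @param algorithm One of `"spectral"`, `"agglomerative"`, `"kmeans"`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Integer seed for the stochastic algorithms.
#' @return Integer vector of cluster labels in `0:(k-1)`, named by doc id.
#' @export
cluster_docs <- function(sim, algorithm = c("spectral", "agglomerative", "kmeans"),
                         k, seed = 0L) {
  algorithm <- match.arg(algorithm)
  n <- nrow(sim)
  if (k > n) stop("k must not exceed the number of documents", call. = FALSE)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  labels <- if (k == 1L) {
    rep.int(0L, n)
  } else if (algorithm == "agglomerative") {
    d <- similarity_to_distance(sim)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    as.integer(stats::cutree(hc, k = k)) - 1L
  } else {
    feats <- if (algorithm == "spectral") {
      mx <- max(sim)
      spectral_embedding(if (mx > 1) sim / mx else sim, k)
    } else {
      sim
    }
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
    km <- stats::kmeans(feats, centers = k, nstart = 20L, iter.max = 100L)
    as.integer(km$cluster) - 1L
  }
  names(labels) <- rownames(sim)
  labels
}

#' Normalized mutual information between two labelings
#'
#' \deqn{NMI = \frac{\sum_{h,l} n_{h,l} \log\frac{n \cdot n_{h,l}}{n_h n_l}}
#'   {\sqrt{\left(\sum_h n_h \log\frac{n_h}{n}\right)
#'          \left(\sum_l n_l \log\frac{n_l}{n}\right)}}}
#' where `n_h`, `n_l` are the class sizes of the two labelings and `n_{h,l}`
#' the contingency counts; terms with `n_{h,l} = 0` contribute 0. Both
#' factors under the radical are negative, so their product is positive and
#' the value lies in `[0, 1]`; it is invariant to label permutation and to
#' the log base.
#'
#' When either labeling has a single class the denominator vanishes and the
#' index is undefined: `NA` is returned with a warning.
#'
#' @param true_labels,pred_labels Equal-length label vectors (any atomic
#'   type; compared as categories).
#' @return Real in `[0, 1]`, or `NA` if undefined.
#' @export
nmi <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels)) {
    stop("labelings must have equal length", call. = FALSE)
  }
  n <- length(true_labels)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  tab <- table(true_labels, pred_labels)
  nh <- rowSums(tab)
  nl <- colSums(tab)
  if (length(nh) < 2L || length(nl) < 2L) {
    warning("NMI undefined: a labeling has a single class; returning NA")
    return(NA_real_)
  }
  nz <- tab > 0
  num <- sum(tab[nz] * log(n * tab[nz] / outer(nh, nl)[nz]))
  den <- sqrt(sum(nh * log(nh / n)) * sum(nl * log(nl / n)))
  if (den == 0) {
    warning("NMI undefined: zero denominator; returning NA")
    return(NA_real_)
  }
  num / den
}
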