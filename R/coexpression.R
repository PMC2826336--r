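#' K-means co-expression clustering of upregulated genes
#'
#' Lloyd iterations on the log2-ratio profiles over the chilling time
#' course, restarted `n_restarts` times from k-means++ seedings; the fit
#' with the lowest within-cluster sum of squares wins. Empty clusters are
#' re-seeded from the globally farthest point. The within-cluster SSE is
#' asserted non-increasing across iterations.
#'
#' @param profiles numeric matrix (genes x time points) of log2 ratios,
#'   typically the upregulated non-TF genes; row names are gene ids.
#' @param k number of clusters (default 18).
#' @param seed integer seed controlling the restarts.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param n_restarts number of random restarts.
#' @param distance "euclidean" (default) or "pearson"; the latter clusters
#'   row-standardized profiles, i.e. by profile shape.
#' @param timepoints sampling hours of the profile columns (defaults to
#'   numeric column names).
#' @param up_threshold log2 threshold used to binarize cluster centroids
#'   into consensus profiles.
#' @param config a [call_config()] used to phase the consensus profiles.
#' @return object of class `coexpression_clusters`: a list with
#'   `assignment` (named integer vector), `centroids`, `wss`, and `clusters`
#'   (a data.frame with per-cluster `cluster`, `size`, `phase`,
#'   `h2o2_fraction` placeholder, `degenerate`, `tightness`, `consensus`
#'   0/1 string, plus a `members` list column).
#' @export
kmeans_cluster <- function(profiles, k = 18L, seed = 1L, max_iter = 100L,
                           n_restarts = 20L, distance = c("euclidean", "pearson"),
                           timepoints = NULL, up_threshold = 1.8,
                           config = call_config()) {
  distance <- match.arg(distance)
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (k <= 0 || k > n) stop("k must satisfy 0 < k <= number of genes")
  if (is.null(timepoints)) {
    timepoints <- suppressWarnings(as.numeric(colnames(profiles)))
    if (anyNA(timepoints)) stop("supply timepoints or numeric column names")
  }
  x <- profiles
  if (distance == "pearson") {
    mu <- rowMeans(x)
    s <- sqrt(pmax(rowSums((x - mu)^2), .Machine$double.eps))
    x <- (x - mu) / s
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- lloyd_once(x, k, max_iter)
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  assignment <- best$assignment
  names(assignment) <- rownames(profiles)
  # centroids on the raw (untransformed) profiles, for interpretability
  centroids <- t(vapply(seq_len(k), function(j) {
    colMeans(profiles[assignment == j, , drop = FALSE])
  }, numeric(ncol(profiles))))
  colnames(centroids) <- colnames(profiles)
  rownames(centroids) <- cluster_labels(k)
  clusters <- summarize_clusters(assignment, profiles, centroids, timepoints,
                                 up_threshold, config)
  structure(list(assignment = assignment, centroids = centroids,
                 wss = best$wss, clusters = clusters,
                 timepoints = timepoints, k = k, distance = distance),
            class = "coexpression_clusters")
}

cluster_labels <- function(k) sprintf("K%02d", seq_len(k))

# k-means++ seeding: subsequent centres drawn with probability
# proportional to squared distance from the nearest centre already chosen.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k)[-1L]) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    pick <- sample.int(n, 1L, prob = prob)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  centers <- kmeanspp_init(x, k)
  assignment <- integer(n)
  prev_wss <- Inf
  for (it in seq_len(max_iter)) {
    d2 <- pairwise_sqdist(x, centers)
    assignment <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters from the globally farthest point
    repeat {
      sizes <- tabulate(assignment, nbins = k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      nearest <- d2[cbind(seq_len(n), assignment)]
      far <- which.max(nearest)
      centers[empty[1L], ] <- x[far, ]
      d2[, empty[1L]] <- rowSums((x - matrix(x[far, ], n, ncol(x),
                                             byrow = TRUE))^2)
      assignment <- max.col(-d2, ties.method = "first")
    }
    wss <- sum(d2[cbind(seq_len(n), assignment)])
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[assignment == j, , drop = FALSE])
    }
    wss_after <- sum(pairwise_sqdist(x, centers)[cbind(seq_len(n), assignment)])
    if (wss_after > wss + 1e-8) {
      stop("internal error: within-cluster SSE increased during iteration")
    }
    if (prev_wss - wss_after < 1e-10) {
      prev_wss <- wss_after
      break
    }
    prev_wss <- wss_after
  }
  list(assignment = assignment, centers = centers, wss = prev_wss)
}

pairwise_sqdist <- function(x, centers) {
  # ||x||^2 + ||c||^2 - 2 x.c, clipped at zero
  cross <- x %*% t(centers)
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * cross
  pmax(d2, 0)
}

summarize_clusters <- function(assignment, profiles, centroids, timepoints,
                               up_threshold, config) {
  k <- nrow(centroids)
  members <- split(names(assignment), factor(assignment, levels = seq_len(k)))
  rows <- lapply(seq_len(k), function(j) {
    cons <- consensus_profile(centroids[j, ], up_threshold)
    degenerate <- !any(cons == 1L)
    phase <- cluster_phase_from_consensus(cons, timepoints, config)
    mem <- members[[j]]
    tight <- mean(sqrt(rowSums(
      (profiles[mem, , drop = FALSE] -
         matrix(centroids[j, ], length(mem), ncol(profiles), byrow = TRUE))^2
    )))
    data.frame(cluster = cluster_labels(k)[j], size = length(mem),
               phase = phase, degenerate = degenerate,
               tightness = tight,
               consensus = paste(cons, collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- unname(members)
  out
}

#' Binary consensus profile of a cluster centroid
#'
#' Each time point is 1 when the centroid reaches the induction threshold;
#' an all-zero profile marks the cluster degenerate.
#'
#' @param centroid numeric vector of centroid log2 ratios.
#' @param up_threshold induction threshold (default 1.8).
#' @return integer 0/1 vector.
#' @export
consensus_profile <- function(centroid, up_threshold = 1.8) {
  as.integer(centroid >= up_threshold)
}

cluster_phase_from_consensus <- function(consensus, timepoints, config) {
  on <- which(consensus == 1L)
  if (length(on) == 0L) return(NA_integer_)
  assign_phase(timepoints[min(on)], config)
}

#' Phase of a cluster from its consensus profile
#'
#' @param clusters a `coexpression_clusters` object.
#' @return integer vector of phases (NA for degenerate clusters).
#' @export
cluster_phase <- function(clusters) {
  stats::setNames(clusters$clusters$phase, clusters$clusters$cluster)
}

#' Fraction of cluster members responsive to the oxidative mimic
#'
#' @param members character vector of member gene ids.
#' @param h2o2_set character vector of H2O2-responsive gene ids.
#' @return proportion in `[0, 1]` of members in `h2o2_set`.
#' @export
h2o2_fraction <- function(members, h2o2_set) {
  if (length(members) == 0L) stop("cluster has no members")
  mean(members %in% h2o2_set)
}

#' @export
print.coexpression_clusters <- function(x, ...) {
  cat("coexpression_clusters: k =", x$k, "| WSS =", signif(x$wss, 6), "\n")
  print(x$clusters[, c("cluster", "size", "phase", "degenerate", "consensus")])
  invisible(x)
}
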