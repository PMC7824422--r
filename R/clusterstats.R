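#' Dependent-samples t map over electrodes
#'
#' Per electrode, the paired t statistic of \code{cond_a - cond_b} across
#' subjects: \code{t = mean(d) / (sd(d) / sqrt(n))}, df = n - 1.
#' Electrodes with zero variance of the difference get t = 0 and are
#' flagged (the statistic is undefined there; 0 is conservative since it
#' can never exceed the cluster-forming threshold).
#'
#' @param cond_a,cond_b subjects x electrodes matrices, matching rows
#' @return list(t, df, zero_variance): per-electrode t values, degrees of
#'   freedom, logical flag vector
#' @export
paired_t_map <- function(cond_a, cond_b) {
  stopifnot(is.matrix(cond_a), identical(dim(cond_a), dim(cond_b)))
  n <- nrow(cond_a)
  if (n < 2) stop_data("need at least 2 subjects for a paired t-test")
  d <- cond_a - cond_b
  m <- colMeans(d)
  v <- colSums(sweep(d, 2, m)^2) / (n - 1)
  zero <- v <= 0
  t <- ifelse(zero, 0, m / sqrt(v / n))
  list(t = t, df = n - 1, zero_variance = zero)
}

#' Electrode neighbourhood graph
#'
#' Builds an undirected adjacency over electrodes. The default method
#' connects electrodes whose 2-D distance is below a threshold (default
#' 1.3 times the median nearest-neighbour distance, a common sensor-space
#' heuristic); \code{method = "knn"} connects each electrode to its k
#' nearest neighbours (symmetrised).
#'
#' @param montage an \code{eeg_montage}
#' @param threshold distance threshold in normalized units; NULL = default
#' @param method "distance" or "knn"
#' @param k neighbours per electrode for \code{method = "knn"}
#' @return list(adjacency = logical matrix, method, threshold)
#' @export
build_neighbors <- function(montage, threshold = NULL,
                            method = c("distance", "knn"), k = 4) {
  method <- match.arg(method)
  stopifnot(inherits(montage, "eeg_montage"))
  pos <- montage$pos2d
  if (nrow(pos) < 2) stop_config("need at least 2 electrodes")
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  if (method == "distance") {
    threshold <- threshold %||% (1.3 * stats::median(apply(d, 1, min)))
    adj <- d < threshold
  } else {
    adj <- matrix(FALSE, nrow(pos), nrow(pos))
    for (i in seq_len(nrow(pos)))
      adj[i, order(d[i, ])[seq_len(min(k, nrow(pos) - 1))]] <- TRUE
    adj <- adj | t(adj)
    threshold <- NA_real_
  }
  diag(adj) <- FALSE
  dimnames(adj) <- list(montage$labels, montage$labels)
  if (any(rowSums(adj) == 0))
    warning("neighbour graph has isolated electrodes")
  list(adjacency = adj, method = method, threshold = threshold)
}

# connected components among 'nodes' (integer indices) under adjacency;
# returns list of integer vectors. Iterative BFS on a neighbour list.
.components <- function(nodes, adj) {
  if (!length(nodes)) return(list())
  in_set <- logical(nrow(adj))
  in_set[nodes] <- TRUE
  seen <- logical(nrow(adj))
  out <- list()
  for (v in nodes) {
    if (seen[v]) next
    comp <- integer(0)
    queue <- v
    seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, u)
      nb <- which(adj[u, ] & in_set & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    out <- c(out, list(sort(comp)))
  }
  out
}

#' Form clusters of supra-threshold electrodes
#'
#' Electrodes whose |t| exceeds the two-tailed critical value at
#' \code{alpha_cluster} (the cluster-forming threshold, p < 0.05
#' uncorrected by default) are partitioned into connected components of
#' the neighbourhood graph, separately for positive and negative t
#' (clusters are sign-homogeneous). Each cluster's mass is the sum of its
#' t values.
#'
#' @param tmap result of \code{\link{paired_t_map}}
#' @param graph result of \code{\link{build_neighbors}}
#' @param alpha_cluster two-tailed cluster-forming alpha
#' @return list of clusters, each list(electrodes, mass, sign)
#' @export
find_clusters <- function(tmap, graph, alpha_cluster = 0.05) {
  tcrit <- stats::qt(1 - alpha_cluster / 2, df = tmap$df)
  adj <- graph$adjacency
  out <- list()
  for (sgn in c(1, -1)) {
    nodes <- which(sgn * tmap$t > tcrit)
    for (comp in .components(nodes, adj))
      out <- c(out, list(list(electrodes = comp,
                              mass = sum(tmap$t[comp]),
                              sign = sgn)))
  }
  out
}

# max |cluster mass| for one t vector (internal fast path of the
# permutation loop)
.max_cluster_mass <- function(t, tcrit, adj) {
  best <- 0
  for (sgn in c(1, -1)) {
    nodes <- which(sgn * t > tcrit)
    if (!length(nodes)) next
    for (comp in .components(nodes, adj)) {
      m <- abs(sum(t[comp]))
      if (m > best) best <- m
    }
  }
  best
}

#' Cluster-based permutation test for a paired design
#'
#' Compares two subject x electrode condition maps with a dependent-samples
#' t statistic per electrode, clusters supra-threshold electrodes over the
#' neighbourhood graph, and evaluates each observed cluster's summed-t
#' mass against the permutation null distribution of the maximum absolute
#' cluster mass (max-statistic correction, two-tailed). Permutations swap
#' condition labels within subjects, i.e. sign-flip the per-subject
#' differences. When \code{n <= 12} subjects and \code{n_perm} exceeds the
#' \code{2^n} distinct sign patterns, the full enumeration is used and the
#' p-values are exact; otherwise Monte-Carlo sampling with the
#' add-one correction \code{p = (1 + #(null >= obs)) / (n_perm + 1)}.
#'
#' @param cond_a,cond_b subjects x electrodes matrices
#' @param graph result of \code{\link{build_neighbors}}
#' @param n_perm number of permutations
#' @param seed RNG seed for the permutation draw
#' @param alpha_cluster cluster-forming (uncorrected) alpha
#' @param alpha corrected significance level
#' @return object of class \code{cluster_result}: \code{clusters} (each
#'   with electrodes, mass, sign, p_corrected, significant),
#'   \code{null_max}, \code{n_permutations}, \code{exact}, \code{tmap}
#' @export
permutation_test <- function(cond_a, cond_b, graph, n_perm = 1000,
                             seed = 1L, alpha_cluster = 0.05,
                             alpha = 0.05) {
  if (n_perm < 1) stop_config("n_perm must be >= 1")
  tmap <- paired_t_map(cond_a, cond_b)
  adj <- graph$adjacency
  n <- nrow(cond_a)
  d <- cond_a - cond_b
  ss <- colSums(d^2)
  tcrit <- stats::qt(1 - alpha_cluster / 2, df = tmap$df)
  exact <- n <= 12 && n_perm > 2^n
  signs <- if (exact) {
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    set.seed(seed)
    matrix(sample(c(1, -1), n_perm * n, replace = TRUE), ncol = n)
  }
  m <- (signs %*% d) / n
  v <- sweep(-n * m^2, 2, ss, "+") / (n - 1)     # sum d^2 is flip-invariant
  tperm <- m / sqrt(pmax(v, 0) / n)
  tperm[!is.finite(tperm)] <- 0
  null_max <- vapply(seq_len(nrow(tperm)),
                     function(i) .max_cluster_mass(tperm[i, ], tcrit, adj),
                     numeric(1))
  clusters <- find_clusters(tmap, graph, alpha_cluster)
  npd <- length(null_max)
  for (i in seq_along(clusters)) {
    obs <- abs(clusters[[i]]$mass)
    p <- if (exact) {
      sum(null_max >= obs - 1e-12) / npd
    } else {
      (1 + sum(null_max >= obs - 1e-12)) / (npd + 1)
    }
    clusters[[i]]$p_corrected <- p
    clusters[[i]]$significant <- p < alpha
  }
  structure(list(clusters = clusters, null_max = null_max,
                 n_permutations = npd, exact = exact, tmap = tmap,
                 alpha = alpha, alpha_cluster = alpha_cluster,
                 labels = colnames(adj)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s); %s null, %d permutations\n",
              length(x$clusters), if (x$exact) "exact" else "Monte-Carlo",
              x$n_permutations))
  for (cl in x$clusters) {
    labs <- if (!is.null(x$labels)) paste(x$labels[cl$electrodes],
                                          collapse = ",")
            else paste(cl$electrodes, collapse = ",")
    cat(sprintf("  %s mass=%.2f p=%.4f%s {%s}\n",
                if (cl$sign > 0) "+" else "-", cl$mass, cl$p_corrected,
                if (cl$significant) " *" else "", labs))
  }
  invisible(x)
}
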