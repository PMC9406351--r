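#' Sammon mapping of a distance matrix
#'
#' Nonlinear 2-D ordination minimizing the Sammon stress
#' `E = (1/sum d_ij) * sum (d_ij - D_ij)^2 / d_ij` over embedded
#' configurations, which preserves small distances preferentially. Minimized
#' by Sammon's pseudo-Newton coordinate update with step halving, started from
#' the classical-MDS (principal coordinates) configuration, so the result is
#' deterministic; `seed` only feeds the optional random restarts.
#'
#' @param distances symmetric matrix (or `dist`) of input-space distances with
#'   zero diagonal. Zero off-diagonal entries are perturbed by `1e-12` with a
#'   warning (the 1/d weight is undefined at 0).
#' @param dims embedding dimension.
#' @param max_iter maximum accepted iterations.
#' @param tol relative stress-change convergence tolerance.
#' @param restarts number of additional randomly jittered starts; the best
#'   final stress wins.
#' @param seed seed for the restarts.
#' @return object of class `sammon_map` with `coords`, `stress`, `n_iter`,
#'   `converged`, and the per-iteration `stress_trace` (non-increasing).
#' @export
sammon_map <- function(distances, dims = 2, max_iter = 500, tol = 1e-9,
                       restarts = 0, seed = 1) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0)) {
    stop_data("distances must be a symmetric zero-diagonal matrix")
  }
  n <- nrow(d)
  if (n < 3) stop_data("need at least 3 points")
  off <- d[upper.tri(d)]
  if (any(off < 0)) stop_data("negative distances")
  if (any(off == 0)) {
    warning("zero off-diagonal distance(s) perturbed by 1e-12")
    d[d == 0] <- 1e-12
    diag(d) <- 0
  }

  init <- stats::cmdscale(d, k = dims)
  if (ncol(init) < dims) {  # degenerate input: pad with tiny spread
    init <- cbind(init, matrix(1e-6 * seq_len(n), n, dims - ncol(init)))
  }

  run_from <- function(y) {
    c_sum <- sum(d[upper.tri(d)])
    stress_of <- function(y) {
      D <- as.matrix(stats::dist(y))
      ut <- upper.tri(d)
      sum((d[ut] - D[ut])^2 / d[ut]) / c_sum
    }
    s <- stress_of(y)
    trace <- s
    iter <- 0
    converged <- FALSE
    while (iter < max_iter) {
      D <- as.matrix(stats::dist(y))
      diag(D) <- Inf
      w <- (d - D) / (d * D); diag(w) <- 0
      grad <- matrix(0, n, ncol(y))
      hess <- matrix(0, n, ncol(y))
      for (q in seq_len(ncol(y))) {
        dy <- outer(y[, q], y[, q], "-")           # y_pq - y_jq
        grad[, q] <- (-2 / c_sum) * rowSums(w * dy)
        hh <- (1 / (d * D)) *
          ((d - D) - (dy^2 / D) * (1 + (d - D) / D))
        diag(hh) <- 0
        hess[, q] <- (-2 / c_sum) * rowSums(hh)
      }
      delta <- grad / pmax(abs(hess), 1e-12)
      step <- 1
      improved <- FALSE
      for (h in 1:20) {
        y_new <- y - step * delta
        s_new <- stress_of(y_new)
        if (s_new < s) { improved <- TRUE; break }
        step <- step / 2
      }
      if (!improved) { converged <- TRUE; break }
      rel <- (s - s_new) / s
      y <- y_new; s <- s_new; iter <- iter + 1
      trace <- c(trace, s)
      if (is.nan(rel) || rel < tol) { converged <- TRUE; break }
    }
    list(coords = y, stress = s, n_iter = iter, converged = converged,
         stress_trace = trace)
  }

  best <- run_from(init)
  if (restarts > 0) {
    set.seed(seed)
    scale <- stats::sd(init)
    for (r in seq_len(restarts)) {
      cand <- run_from(init + matrix(stats::rnorm(n * dims, 0, 0.1 * scale), n, dims))
      if (cand$stress < best$stress) best <- cand
    }
  }
  rownames(best$coords) <- rownames(d)
  structure(c(best, list(init_stress = best$stress_trace[1])), class = "sammon_map")
}

#' @export
print.sammon_map <- function(x, ...) {
  cat(sprintf("Sammon mapping: %d points, stress %.6g after %d iterations (%s)\n",
              nrow(x$coords), x$stress, x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Compute the Sammon stress of a configuration
#'
#' @param distances input-space distance matrix.
#' @param coords embedded coordinates (rows = points).
#' @return the stress value.
#' @export
sammon_stress <- function(distances, coords) {
  d <- as.matrix(distances)
  D <- as.matrix(stats::dist(coords))
  ut <- upper.tri(d)
  sum((d[ut] - D[ut])^2 / d[ut]) / sum(d[ut])
}

#' Uncentered Pearson distance
#'
#' `1 - sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))`: the cosine-style
#' correlation computed without mean-centering, mapped to a distance in
#' [0, 2].
#'
#' @param x,y equal-length numeric vectors, not all zero.
#' @return distance value.
#' @export
uncentered_pearson_distance <- function(x, y) {
  if (length(x) != length(y)) stop_data("vectors differ in length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop_data("uncentered correlation undefined for an all-zero vector")
  1 - sum(x * y) / (nx * ny)
}

#' Pairwise uncentered Pearson distances between samples
#'
#' @param m numeric matrix, variables in rows, samples in columns.
#' @return symmetric distance matrix over columns.
#' @export
uncentered_pearson_dist <- function(m) {
  nrm <- sqrt(colSums(m^2))
  if (any(nrm == 0)) stop_data("uncentered correlation undefined for an all-zero sample")
  s <- crossprod(m) / tcrossprod(nrm)
  d <- 1 - s
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering with Newick export
#'
#' Deterministic agglomeration on a distance matrix (UPGMA); the merge order
#' for tied heights follows the smallest-index pair, as in the standard
#' implementation.
#'
#' @param distances symmetric distance matrix or `dist`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return object of class `radskin_dendrogram` wrapping the `hclust` result;
#'   use [export_newick()] to serialize it.
#' @export
hier_cluster <- function(distances, linkage = "average") {
  d <- stats::as.dist(distances)
  if (attr(d, "Size") < 2) stop_data("clustering needs at least 2 items")
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc), class = "radskin_dendrogram")
}

#' @export
print.radskin_dendrogram <- function(x, ...) {
  cat("hierarchical clustering of", length(x$hclust$labels), "items (",
      x$hclust$method, "linkage )\n")
  invisible(x)
}

#' @rdname hier_cluster
#' @param dendro a `radskin_dendrogram`.
#' @param path optional file path; when `NULL` the Newick string is returned.
#' @export
export_newick <- function(dendro, path = NULL) {
  stopifnot(inherits(dendro, "radskin_dendrogram"))
  phy <- ape::as.phylo(dendro$hclust)
  if (is.null(path)) ape::write.tree(phy) else {
    ape::write.tree(phy, file = path)
    invisible(path)
  }
}

#' Sample ordination of an expression matrix
#'
#' Fig.-style sample-level view: Euclidean distances on the top most-variable
#' genes' log2 values, embedded by Sammon mapping.
#'
#' @param x a `radskin_expr`.
#' @param n_top number of most-variable genes entering the distance.
#' @param ... passed to [sammon_map()].
#' @return a `sammon_map` whose coords carry the sample metadata as attribute
#'   `meta`.
#' @export
embed_samples <- function(x, n_top = 500, ...) {
  stopifnot(inherits(x, "radskin_expr"))
  v <- row_vars(x$values)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(x$values)))]
  d <- stats::dist(t(x$values[keep, , drop = FALSE]))
  out <- sammon_map(d, ...)
  attr(out, "meta") <- x$meta
  out
}
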