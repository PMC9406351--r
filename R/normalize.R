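#' Within-sample lowess detrending
#'
#' Removes a smooth intensity-dependent trend from one sample's log2 values,
#' the within-chip step of two-color array preprocessing: values are returned
#' minus a lowess fit of value on mean intensity.
#'
#' @param values per-probe log2 values of one sample.
#' @param covariate per-probe covariate the trend runs along, conventionally
#'   the across-sample mean log2 intensity.
#' @param span lowess smoother span in (0, 1].
#' @return detrended values (same length and order as `values`).
#' @export
lowess_detrend <- function(values, covariate, span = 0.3) {
  if (length(values) != length(covariate)) stop_data("values/covariate length mismatch")
  if (length(values) < 10) stop_data("refusing to fit a lowess trend on < 10 probes")
  if (span <= 0 || span > 1) stop_config("span must be in (0, 1]")
  fit <- stats::lowess(covariate, values, f = span)
  ## lowess returns the fit on sorted unique x; map back to probe order.
  trend <- stats::approx(fit$x, fit$y, xout = covariate, rule = 2, ties = mean)$y
  values - trend
}

#' Between-sample quantile normalization
#'
#' Forces every sample's value distribution onto the common reference (the
#' mean of the cross-sample order statistics); ties receive the mean of their
#' ranks' reference values. Idempotent. Wraps the standard microarray
#' implementation.
#'
#' @param x a `radskin_expr` or a plain numeric matrix (probes x samples).
#' @return object of the same type with normalized values.
#' @export
quantile_normalize <- function(x) {
  m <- if (inherits(x, "radskin_expr")) x$values else x
  if (anyNA(m)) stop_data("quantile normalization requires a complete matrix")
  if (ncol(m) < 2) {
    warning("single-sample matrix: quantile normalization is the identity")
    return(x)
  }
  dn <- dimnames(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dn
  if (inherits(x, "radskin_expr")) {
    x$values <- out
    x
  } else {
    out
  }
}

#' PCA-based sample outlier exclusion
#'
#' Flags samples whose principal-component scores sit far from their own
#' (dose, time point) group. Scores on the first two PCs of the sample-space
#' PCA are reduced to deviations from the within-group median; a sample is
#' excluded when either deviation exceeds `k_sd` robust standard deviations,
#' where the robust SD is the MAD of the pooled within-group deviations (a
#' per-group MAD over a handful of replicates is too unstable to threshold
#' on). Judging deviations within groups avoids mistaking the dose/time
#' separation itself for an artifact. Refuses to act if more than 20% of
#' samples would be lost.
#'
#' @param x a `radskin_expr`.
#' @param k_sd robust-SD multiplier; `Inf` disables filtering.
#' @return list with `expr` (filtered matrix) and `report` (a
#'   `normalization_report` listing excluded samples, their PC coordinates and
#'   the rule fired).
#' @export
pca_outlier_filter <- function(x, k_sd = 4) {
  stopifnot(inherits(x, "radskin_expr"))
  if (ncol(x$values) < 4) stop_data("PCA outlier filtering needs at least 4 samples")
  pc <- stats::prcomp(t(x$values), center = TRUE, scale. = FALSE, rank. = 2)
  sc <- pc$x[, 1:2, drop = FALSE]
  grp <- x$meta$group
  flagged <- rep(FALSE, nrow(sc))
  rule <- character(nrow(sc))
  dev <- sc
  for (g in unique(grp)) {
    i <- which(grp == g)
    dev[i, ] <- sweep(sc[i, , drop = FALSE], 2, apply(sc[i, , drop = FALSE], 2,
                                                      stats::median))
  }
  for (k in 1:2) {
    s <- stats::mad(dev[, k])
    if (s == 0) next
    hit <- abs(dev[, k]) / s > k_sd
    flagged[hit] <- TRUE
    rule[hit] <- paste0(rule[hit], sprintf("|PC%d| > %g robust SD; ", k, k_sd))
  }
  if (all(flagged)) stop_data("outlier rule would remove every sample")
  refused <- FALSE
  if (mean(flagged) > 0.20) {
    refused <- TRUE
    flagged[] <- FALSE
  }
  excluded <- data.frame(sample = x$meta$sample[flagged],
                         PC1 = sc[flagged, 1], PC2 = sc[flagged, 2],
                         rule = sub("; $", "", rule[flagged]))
  report <- structure(list(k_sd = k_sd, excluded_samples = excluded,
                           refused = refused,
                           n_in = ncol(x$values), n_out = sum(!flagged)),
                      class = "normalization_report")
  out <- if (any(flagged)) subset_samples(x, !flagged) else x
  list(expr = out, report = report)
}

#' @export
print.normalization_report <- function(x, ...) {
  cat("PCA outlier filter (k =", x$k_sd, "robust SD):",
      x$n_in, "samples in,", x$n_out, "kept\n")
  if (x$refused) cat("NOTE: rule fired on > 20% of samples; refused to exclude any\n")
  if (nrow(x$excluded_samples)) print(x$excluded_samples) else cat("no exclusions\n")
  invisible(x)
}

#' Full preprocessing for an expression matrix
#'
#' The standard order: per-sample lowess detrending against the mean-intensity
#' covariate, between-sample quantile normalization, then PCA outlier
#' exclusion.
#'
#' @param x a `radskin_expr`.
#' @param span lowess span; `NULL` (the default) skips detrending. Detrending
#'   targets intensity-dependent trends of raw array data; on trend-free
#'   log-ratio-like values the cross-sample mean covariate is contaminated by
#'   group effects and detrending against it distorts contrasts.
#' @param k_sd outlier multiplier; `Inf` skips exclusion.
#' @return list with `expr` and `report`.
#' @export
normalize_expression <- function(x, span = NULL, k_sd = 4) {
  stopifnot(inherits(x, "radskin_expr"))
  if (!is.null(span)) {
    a <- rowMeans(x$values)
    for (j in seq_len(ncol(x$values))) {
      x$values[, j] <- lowess_detrend(x$values[, j], a, span = span)
    }
  }
  x <- quantile_normalize(x)
  pca_outlier_filter(x, k_sd = k_sd)
}
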