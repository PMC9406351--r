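#' @keywords internal
"_PACKAGE"

## Canonical time-point labels, in biopsy order.
TIMEPOINTS <- c("2h", "d4", "d7", "d21", "d28")

## Time points making up the first post-exposure week; the dosimetry rules and
## the lethal arm of the study only cover these.
EARLY_TIMEPOINTS <- c("2h", "d4", "d7")

#' Order time-point labels chronologically
#'
#' @param tp character vector of time-point labels (subset of
#'   `"2h", "d4", "d7", "d21", "d28"`).
#' @return `tp` as an ordered factor.
#' @export
timepoint_factor <- function(tp) {
  bad <- setdiff(unique(tp), TIMEPOINTS)
  if (length(bad)) {
    stop("unknown time-point label(s): ", paste(bad, collapse = ", "))
  }
  factor(tp, levels = TIMEPOINTS, ordered = TRUE)
}

#' Round half away from zero
#'
#' Printed expression tables conventionally round 5 upward, unlike base R's
#' round-half-even; percentages in the crosstab reports use this rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Deterministic per-gene seed stream: a counter-based split of the master
## seed so that enlarging n_genes never reshuffles earlier genes.
gene_seed <- function(master, gene_index) {
  as.integer((as.double(master) * 48271 + gene_index * 16807) %% 2147483647)
}

## Inverse of trigamma(), by Newton iteration on 1/trigamma (monotone and
## nearly linear in x); used by the variance-moderation fit.
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif / x) < 1e-8) break
    }
    x
  }, numeric(1))
}

## Vectorized row-wise sample variance.
row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

## stop() with a condition class so callers/tests can distinguish config from
## data errors.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("radskin_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("radskin_data_error", "error")))
}
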