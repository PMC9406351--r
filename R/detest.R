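#' Significance and fold-change thresholds for SDTG calling
#'
#' @param p_adj_max adjusted-p significance level.
#' @param fc_min minimum absolute signed linear fold change for a gene to be a
#'   significantly differentially transcribed gene (SDTG).
#' @param fc_top stricter reporting threshold used for "top gene" tables.
#' @param fc_panel_mean panel-average fold-change threshold for marker tables.
#' @param use_adjusted threshold the BH-adjusted p (default); `FALSE` uses the
#'   raw p instead.
#' @return object of class `de_thresholds`.
#' @export
de_thresholds <- function(p_adj_max = 0.05, fc_min = 2, fc_top = 3.5,
                          fc_panel_mean = 3, use_adjusted = TRUE) {
  if (p_adj_max <= 0 || fc_min < 1 || fc_top <= 0 || fc_panel_mean <= 0) {
    stop_config("thresholds must be positive and fc_min >= 1")
  }
  structure(list(p_adj_max = p_adj_max, fc_min = fc_min, fc_top = fc_top,
                 fc_panel_mean = fc_panel_mean, use_adjusted = use_adjusted),
            class = "de_thresholds")
}

#' Log2 and signed linear fold change
#'
#' The log2 fold change is the mean log2 expression of the exposed group minus
#' that of the control group. The signed linear fold change maps it to
#' `2^log2fc` when non-negative and `-2^(-log2fc)` otherwise, so `|fc| >= 1`
#' always and a halving is `-2`, not `0.5`.
#'
#' @param mean_log2_exposed,mean_log2_control finite group means (vectors ok).
#' @return list with `log2fc` and `fc`.
#' @export
fold_change <- function(mean_log2_exposed, mean_log2_control) {
  lfc <- mean_log2_exposed - mean_log2_control
  if (any(!is.finite(lfc))) stop_data("non-finite group means in fold change")
  list(log2fc = lfc, fc = ifelse(lfc >= 0, 2^lfc, -(2^(-lfc))))
}

#' Estimate the variance-moderation prior
#'
#' Fits the scaled inverse chi-square prior (prior degrees of freedom `d0`,
#' prior variance `s0_sq`) of the empirical-Bayes variance model by method of
#' moments on the log gene-wise sample variances: marginally
#' `s_g^2 = s0^2 * F(d_g, d0)`, so the excess variance of `log s_g^2` over
#' `trigamma(d_g/2)` identifies `d0` through the trigamma function, and the
#' mean identifies `s0^2`. Zero variances are floored at `1e-8`.
#'
#' @param sample_vars gene-wise pooled sample variances.
#' @param df_resid residual degrees of freedom of each variance (scalar).
#' @return list with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
fit_variance_moderation <- function(sample_vars, df_resid) {
  if (df_resid < 1) stop_data("need at least 1 residual df to moderate variances")
  z <- log(pmax(sample_vars, 1e-8))
  evar <- stats::var(z) - trigamma(df_resid / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(z) - digamma(df_resid / 2) + log(df_resid / 2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(z) - digamma(df_resid / 2) + log(df_resid / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

## Posterior (shrunken) variance; lies between s0_sq and sg_sq.
squeeze_variance <- function(sg_sq, dg, d0, s0_sq) {
  if (is.infinite(d0)) rep(s0_sq, length(sg_sq))
  else if (d0 == 0) sg_sq
  else (d0 * s0_sq + dg * sg_sq) / (d0 + dg)
}

#' Moderated t contrast of one (dose, time point) group against control
#'
#' Two-sample comparison of an exposed group with the 0 Gy control at the same
#' time point using a moderated t-statistic: gene-wise pooled variances are
#' shrunk toward the prior estimated by [fit_variance_moderation()], t is
#' referred to a t distribution with `d0 + dg` degrees of freedom, and
#' Benjamini-Hochberg adjustment is applied within this contrast's gene list.
#'
#' @param x a `radskin_expr`.
#' @param dose_gy exposed dose (Gy).
#' @param timepoint time-point label.
#' @param control_dose control dose, normally 0 Gy.
#' @param params optional list `(d0, s0_sq)`; estimated from this contrast's
#'   variances when `NULL`. `d0 = 0` gives the ordinary pooled two-sample t.
#' @param thresholds a [de_thresholds()] used to set the `is_sdtg` flag.
#' @return a `radskin_contrasts` data frame (gene, log2fc, fc, t_mod, p_raw,
#'   p_adj, direction, is_sdtg) with the contrast and moderation parameters as
#'   attributes; if the exposed group does not exist at that time point (the
#'   lethal arm after day 7), an object of class `group_absent` is returned.
#' @export
moderated_t_contrast <- function(x, dose_gy, timepoint, control_dose = 0,
                                 params = NULL, thresholds = de_thresholds()) {
  stopifnot(inherits(x, "radskin_expr"))
  i1 <- group_index(x, dose_gy, timepoint)
  i0 <- group_index(x, control_dose, timepoint)
  if (!length(i1)) {
    return(structure(list(dose_gy = dose_gy, timepoint = timepoint,
                          reason = "group absent"), class = "group_absent"))
  }
  if (!length(i0)) stop_data("no control group at time point ", timepoint)
  n1 <- length(i1); n0 <- length(i0)
  if (n1 < 2 || n0 < 2) stop_data("both groups need >= 2 replicates")

  m1 <- rowMeans(x$values[, i1, drop = FALSE])
  m0 <- rowMeans(x$values[, i0, drop = FALSE])
  fc <- fold_change(m1, m0)
  v1 <- row_vars(x$values[, i1, drop = FALSE])
  v0 <- row_vars(x$values[, i0, drop = FALSE])
  dg <- n1 + n0 - 2
  sg_sq <- ((n1 - 1) * v1 + (n0 - 1) * v0) / dg
  if (is.null(params)) params <- fit_variance_moderation(sg_sq, dg)
  st_sq <- squeeze_variance(sg_sq, dg, params$d0, params$s0_sq)
  se <- sqrt(st_sq * (1 / n1 + 1 / n0))
  t_mod <- fc$log2fc / pmax(se, .Machine$double.eps)
  df_total <- params$d0 + dg
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p_adj <- stats::p.adjust(p_raw, method = "BH")

  out <- data.frame(gene = rownames(x$values), log2fc = fc$log2fc, fc = fc$fc,
                    t_mod = t_mod, p_raw = p_raw, p_adj = p_adj,
                    direction = ifelse(fc$log2fc >= 0, "up", "down"),
                    row.names = NULL)
  p_use <- if (thresholds$use_adjusted) out$p_adj else out$p_raw
  out$is_sdtg <- p_use < thresholds$p_adj_max &
    abs(out$fc) >= thresholds$fc_min - FC_EPS
  structure(out, class = c("radskin_contrasts", "data.frame"),
            dose_gy = dose_gy, timepoint = timepoint, control_dose = control_dose,
            n_exposed = n1, n_control = n0, moderation = params,
            thresholds = thresholds)
}

#' @export
print.radskin_contrasts <- function(x, ...) {
  cat(sprintf("contrast %g Gy vs %g Gy at %s: %d genes, %d SDTGs (%d up, %d down)\n",
              attr(x, "dose_gy"), attr(x, "control_dose"), attr(x, "timepoint"),
              nrow(x), sum(x$is_sdtg), sum(x$is_sdtg & x$direction == "up"),
              sum(x$is_sdtg & x$direction == "down")))
  mp <- attr(x, "moderation")
  cat(sprintf("moderation: d0 = %.3g, s0^2 = %.4g\n", mp$d0, mp$s0_sq))
  utils::head(as.data.frame(x)[order(x$p_adj), ], 5L) |> print()
  invisible(x)
}

#' Collapse probes to genes
#'
#' When several probes map to one gene symbol, keeps the probe with the
#' largest absolute moderated t per gene.
#'
#' @param rows a `radskin_contrasts` data frame.
#' @param map named character vector: probe id -> gene symbol.
#' @return the collapsed `radskin_contrasts`, with `gene` replaced by symbols.
#' @export
collapse_probes <- function(rows, map) {
  sym <- map[rows$gene]
  if (anyNA(sym)) stop_data("probe(s) missing from annotation map: ",
                            paste(utils::head(rows$gene[is.na(sym)], 3), collapse = ", "))
  keep <- unlist(lapply(split(seq_len(nrow(rows)), sym),
                        function(i) i[which.max(abs(rows$t_mod[i]))]))
  out <- rows[sort(keep), , drop = FALSE]
  out$gene <- as.character(sym[sort(keep)])
  out
}

#' Call the SDTG set of one contrast
#'
#' Applies the significance and fold-change thresholds to a contrast's rows
#' and returns the set of significantly differentially transcribed genes with
#' regulation direction.
#'
#' @param rows a `radskin_contrasts` data frame (BH already applied).
#' @param thresholds a [de_thresholds()].
#' @return object of class `sdtg_set`: dose, time point, `up` and `down` gene
#'   id sets.
#' @export
call_sdtgs <- function(rows, thresholds = de_thresholds()) {
  p_use <- if (thresholds$use_adjusted) rows$p_adj else rows$p_raw
  sig <- p_use < thresholds$p_adj_max & abs(rows$fc) >= thresholds$fc_min - FC_EPS
  sdtg_set(dose_gy = attr(rows, "dose_gy"), timepoint = attr(rows, "timepoint"),
           up = rows$gene[sig & rows$direction == "up"],
           down = rows$gene[sig & rows$direction == "down"])
}

#' Construct an SDTG set
#'
#' @param dose_gy dose in Gy.
#' @param timepoint time-point label.
#' @param up,down disjoint character vectors of gene ids by regulation
#'   direction.
#' @return object of class `sdtg_set`.
#' @export
sdtg_set <- function(dose_gy, timepoint, up, down) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down))) stop_data("a gene cannot be both up- and downregulated")
  structure(list(dose_gy = dose_gy, timepoint = timepoint, up = up, down = down),
            class = "sdtg_set")
}

#' @export
print.sdtg_set <- function(x, ...) {
  cat(sprintf("SDTG set %g Gy @ %s: %d genes (%d up, %d down)\n",
              x$dose_gy, x$timepoint, length(x$up) + length(x$down),
              length(x$up), length(x$down)))
  invisible(x)
}

## All gene ids of a set.
sdtg_genes <- function(s) c(s$up, s$down)

#' Run every (dose, time point) contrast of an experiment
#'
#' @param x a `radskin_expr`.
#' @param thresholds a [de_thresholds()].
#' @param control_dose control dose in Gy.
#' @param params optional shared moderation parameters; per-contrast estimates
#'   when `NULL`.
#' @return list with `contrasts` (named `"<dose>|<tp>"`, `group_absent`
#'   entries where the group does not exist) and `sets` (called `sdtg_set`s
#'   for present groups).
#' @export
de_all_contrasts <- function(x, thresholds = de_thresholds(), control_dose = 0,
                             params = NULL) {
  stopifnot(inherits(x, "radskin_expr"))
  doses <- sort(setdiff(unique(x$meta$dose_gy), control_dose))
  tps <- TIMEPOINTS[TIMEPOINTS %in% unique(x$meta$timepoint)]
  contrasts <- list(); sets <- list()
  for (d in doses) {
    for (tp in tps) {
      key <- paste(d, tp, sep = "|")
      ct <- moderated_t_contrast(x, d, tp, control_dose, params, thresholds)
      contrasts[[key]] <- ct
      if (!inherits(ct, "group_absent")) sets[[key]] <- call_sdtgs(ct, thresholds)
    }
  }
  list(contrasts = contrasts, sets = sets)
}

## Absolute tolerance on fold-change thresholds: group-mean arithmetic leaves
## ~1e-16 dust, and a planted FC sitting exactly on the threshold must pass.
FC_EPS <- 1e-9
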