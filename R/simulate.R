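#' Configure a synthetic dose-by-time expression experiment
#'
#' Builds the configuration for [simulate_experiment()]. The planted
#' differential-expression architecture of each dose is given as a Venn
#' skeleton over that dose's time points: a `union` size, a `common` block
#' (genes modulated at every time point of the dose), and per-time-point
#' `unique` blocks; whatever remains of the union is split evenly into blocks
#' shared by consecutive time-point pairs, which gives the sublethal doses
#' their dynamic, rolling response and the lethal dose its stationary one.
#'
#' @param n_genes number of probes/genes on the simulated array.
#' @param n_replicates biological replicates per (dose, time point) group.
#' @param doses irradiation doses in Gy (controls at 0 Gy are always added).
#' @param lethal_dose the dose whose animals exit the study after the third
#'   time point; its groups exist only at the first three time points.
#' @param timepoints ordered time-point labels.
#' @param venn named list (names = doses as character) of
#'   `list(union=, common=, unique=)`, with `unique` a vector over the dose's
#'   time points. `common + sum(unique) <= union`.
#' @param up_fraction matrix (doses x timepoints) giving the fraction of each
#'   group's planted genes that are upregulated; block signs are assigned from
#'   the mean fraction over the time points a block spans.
#' @param lfc_range range of planted absolute log2 fold changes, drawn
#'   uniformly per (gene, dose) and held constant across that dose's time
#'   points.
#' @param variance_prior `c(d0=, s0_sq=)`: gene-wise noise variances are drawn
#'   from a scaled inverse chi-square with `d0` degrees of freedom and scale
#'   `s0_sq`, the same hierarchy assumed by the moderated-t stage.
#' @param baseline `c(mean=, sd=)` of gene baseline log2 intensities.
#' @param plant_markers plant the two diagnostic panels: five marker genes
#'   upregulated in every sublethal early-time-point group and downregulated
#'   in every lethal group, and three genes upregulated only in sublethal
#'   groups.
#' @param marker_lfc,lethal_marker_lfc absolute log2FC ranges for the planted
#'   marker panel in sublethal (up) and lethal (down) groups.
#' @param seed master seed; all randomness derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20000,
                       n_replicates = 5,
                       doses = c(1, 3, 6, 20),
                       lethal_dose = 20,
                       timepoints = TIMEPOINTS,
                       venn,
                       up_fraction,
                       lfc_range = c(1.5, 4.3),
                       variance_prior = c(d0 = 4, s0_sq = 0.0625),
                       baseline = c(mean = 8, sd = 1.5),
                       plant_markers = TRUE,
                       marker_lfc = c(2, 3),
                       lethal_marker_lfc = c(2.5, 3.5),
                       seed = 1) {
  if (n_genes < 1 || n_replicates < 2) stop_config("need n_genes >= 1 and n_replicates >= 2")
  if (!lethal_dose %in% doses) stop_config("lethal_dose must be one of 'doses'")
  if (lfc_range[1] > lfc_range[2] || lfc_range[1] < 0) stop_config("bad lfc_range")
  if (variance_prior[["d0"]] <= 0 || variance_prior[["s0_sq"]] < 0) {
    stop_config("variance_prior needs d0 > 0 and s0_sq >= 0")
  }
  dose_key <- as.character(doses)
  if (!setequal(names(venn), dose_key)) stop_config("'venn' must have one entry per dose")
  if (!identical(rownames(up_fraction), dose_key) ||
      !identical(colnames(up_fraction), timepoints)) {
    stop_config("'up_fraction' must be a doses x timepoints matrix with matching dimnames")
  }
  if (any(up_fraction < 0 | up_fraction > 1, na.rm = TRUE)) {
    stop_config("up fractions must lie in [0, 1]")
  }

  blocks <- list()
  de_counts <- matrix(0L, length(doses), length(timepoints),
                      dimnames = list(dose_key, timepoints))
  for (d in dose_key) {
    tps <- if (as.numeric(d) == lethal_dose) timepoints[1:3] else timepoints
    v <- venn[[d]]
    u <- v$unique
    if (length(u) != length(tps)) {
      stop_config("dose ", d, " Gy: 'unique' must have one count per time point (",
                  length(tps), ")")
    }
    names(u) <- tps
    rest <- v$union - v$common - sum(u)
    if (v$common < 0 || any(u < 0) || rest < 0) {
      stop_config("dose ", d, " Gy: need common + sum(unique) <= union")
    }
    npair <- length(tps) - 1
    pair <- rep(rest %/% npair, npair)
    extra <- rest %% npair
    if (extra > 0) pair[npair - seq_len(extra) + 1] <- pair[npair - seq_len(extra) + 1] + 1
    names(pair) <- paste(tps[-length(tps)], tps[-1], sep = "|")
    blocks[[d]] <- list(tps = tps, common = v$common, unique = u, pair = pair,
                        union = v$union)
    for (i in seq_along(tps)) {
      de_counts[d, tps[i]] <- v$common + u[i] +
        (if (i > 1) pair[i - 1] else 0L) + (if (i < length(tps)) pair[i] else 0L)
    }
  }
  n_special <- if (plant_markers) 8L else 0L
  if (any(vapply(blocks, `[[`, 0, "union") + n_special > n_genes)) {
    stop_config("planted union exceeds n_genes")
  }
  if (any(de_counts > n_genes)) stop_config("planted per-group count exceeds n_genes")

  ## Expected upregulated count per group, used for the planted peak map.
  exp_up <- de_counts * NA
  for (d in dose_key) {
    b <- blocks[[d]]
    for (i in seq_along(b$tps)) {
      tp <- b$tps[i]
      n_up <- round(up_fraction[d, tp] * b$unique[i]) +
        round(mean(up_fraction[d, b$tps]) * b$common)
      if (i > 1) {
        n_up <- n_up + round(mean(up_fraction[d, b$tps[(i - 1):i]]) * b$pair[i - 1])
      }
      if (i < length(b$tps)) {
        n_up <- n_up + round(mean(up_fraction[d, b$tps[i:(i + 1)]]) * b$pair[i])
      }
      exp_up[d, tp] <- n_up
    }
  }
  peak_tp <- apply(exp_up, 1, function(z) colnames(exp_up)[which.max(z)])

  structure(list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    doses = doses, lethal_dose = lethal_dose, timepoints = timepoints,
    venn = venn, blocks = blocks, de_counts = de_counts,
    common_fraction = vapply(blocks, function(b) {
      if (b$union > 0) b$common / b$union else 0
    }, numeric(1)),
    up_fraction = up_fraction, expected_up = exp_up, peak_tp = peak_tp,
    lfc_range = lfc_range, variance_prior = variance_prior, baseline = baseline,
    plant_markers = plant_markers, marker_lfc = marker_lfc,
    lethal_marker_lfc = lethal_marker_lfc, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$n_replicates, "replicates/group\n")
  cat("doses (Gy):", paste(x$doses, collapse = ", "),
      "(lethal:", x$lethal_dose, "Gy, first 3 time points only)\n")
  cat("planted genes per (dose, time point):\n")
  print(x$de_counts)
  cat("common fraction per dose:",
      paste(sprintf("%sGy=%.3f", names(x$common_fraction), x$common_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' The default mouse-skin study preset
#'
#' The study conditions the generator emulates: four whole-body X-ray doses
#' (1, 3, 6 Gy sublethal; 20 Gy lethal, animals euthanized after day 7), five
#' biopsy time points (2 h, days 4/7/21/28), five replicates per group,
#' ~20,000 probes. The per-dose Venn skeletons carry the reported dose-wise
#' union / all-time-point-common / time-point-unique gene counts (619/1/...,
#' 411/0/..., 765/4/..., 1038/609/...), so the lethal response is large,
#' stationary and down-dominated while sublethal responses are smaller,
#' dynamic and up-dominated, with the upregulation peak at day 4 for 1 and
#' 3 Gy and delayed to day 7 for 6 Gy.
#'
#' @param seed master seed.
#' @param n_genes number of simulated probes.
#' @return a `sim_config`.
#' @export
sim_config_preset <- function(seed = 1, n_genes = 20000) {
  venn <- list(
    "1"  = list(union = 619,  common = 1,   unique = c(125, 101, 26, 51, 62)),
    "3"  = list(union = 411,  common = 0,   unique = c(61, 35, 20, 99, 82)),
    "6"  = list(union = 765,  common = 4,   unique = c(47, 84, 173, 52, 88)),
    "20" = list(union = 1038, common = 609, unique = c(57, 80, 89))
  )
  up <- rbind(
    "1"  = c(0.70, 0.80, 0.60, 0.40, 0.35),
    "3"  = c(0.65, 0.80, 0.60, 0.30, 0.30),
    "6"  = c(0.60, 0.65, 0.75, 0.40, 0.35),
    "20" = c(0.10, 0.10, 0.10, NA, NA)
  )
  colnames(up) <- TIMEPOINTS
  sim_config(n_genes = n_genes, venn = venn, up_fraction = up, seed = seed)
}

#' A null (no planted effect) configuration
#'
#' Same sample layout as the preset but with nothing planted; downstream
#' significance calls on it are false positives by construction.
#'
#' @inheritParams sim_config_preset
#' @export
sim_config_null <- function(seed = 1, n_genes = 20000) {
  venn <- list(
    "1"  = list(union = 0, common = 0, unique = rep(0, 5)),
    "3"  = list(union = 0, common = 0, unique = rep(0, 5)),
    "6"  = list(union = 0, common = 0, unique = rep(0, 5)),
    "20" = list(union = 0, common = 0, unique = rep(0, 3))
  )
  up <- rbind("1" = rep(0.5, 5), "3" = rep(0.5, 5), "6" = rep(0.5, 5),
              "20" = c(0.5, 0.5, 0.5, NA, NA))
  colnames(up) <- TIMEPOINTS
  sim_config(n_genes = n_genes, venn = venn, up_fraction = up,
             plant_markers = FALSE, seed = seed)
}

gene_id <- function(i) sprintf("g%05d", i)

#' Simulate a dose-by-time expression experiment with planted truth
#'
#' Generates a complete experiment under the given configuration: gene
#' baselines and gene-wise noise variances are drawn per gene from
#' seed-stable, counter-split streams (so enlarging `n_genes` never reshuffles
#' earlier genes), planted genes get their group means shifted by the true
#' log2FC in the designated (dose, time point) groups only, and the full
#' ground truth is returned for recovery testing.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (a `radskin_expr`) and `truth` (a `sim_truth`:
#'   `planted_de[["<dose>|<tp>"]]` data frames of gene/lfc, plus
#'   `marker_panel` and `sublethal_unique` gene ids).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  pool <- seq_len(n)

  marker_panel <- character(0)
  sublethal_unique <- character(0)
  if (config$plant_markers) {
    special <- sample(pool, 8)
    marker_panel <- gene_id(special[1:5])
    sublethal_unique <- gene_id(special[6:8])
    pool <- setdiff(pool, special)
  }
  if (length(intersect(marker_panel, sublethal_unique))) {
    stop_config("marker panel and sublethal-unique sets overlap")
  }

  ## Assignment phase: which genes belong to which Venn block of which dose,
  ## their sign and magnitude. All decided under the master seed before any
  ## noise is drawn.
  planted <- list()   # "<dose>|<tp>" -> data.frame(gene, lfc)
  add_cell <- function(dose, tp, gene, lfc) {
    key <- paste(dose, tp, sep = "|")
    planted[[key]] <<- rbind(planted[[key]], data.frame(gene = gene, lfc = lfc))
  }
  for (d in names(config$blocks)) {
    b <- config$blocks[[d]]
    if (b$union == 0) next
    ids <- sample(pool, b$union)
    mag <- stats::runif(b$union, config$lfc_range[1], config$lfc_range[2])
    ptr <- 0
    take <- function(k) {
      if (k == 0) return(integer(0))
      out <- (ptr + 1):(ptr + k); ptr <<- ptr + k; out
    }
    assign_block <- function(k, tps_spanned) {
      idx <- take(k)
      if (!length(idx)) return(NULL)
      frac <- mean(config$up_fraction[d, tps_spanned])
      n_up <- round(frac * k)
      sgn <- c(rep(1, n_up), rep(-1, k - n_up))
      data.frame(gene = gene_id(ids[idx]), lfc = sgn * mag[idx])
    }
    common_df <- assign_block(b$common, b$tps)
    if (!is.null(common_df)) for (tp in b$tps) add_cell(d, tp, common_df$gene, common_df$lfc)
    for (i in seq_along(b$tps)) {
      u_df <- assign_block(b$unique[i], b$tps[i])
      if (!is.null(u_df)) add_cell(d, b$tps[i], u_df$gene, u_df$lfc)
    }
    for (i in seq_along(b$pair)) {
      span <- b$tps[i:(i + 1)]
      p_df <- assign_block(b$pair[i], span)
      if (!is.null(p_df)) for (tp in span) add_cell(d, tp, p_df$gene, p_df$lfc)
    }
  }

  sublethal <- setdiff(config$doses, config$lethal_dose)
  if (config$plant_markers) {
    for (d in as.character(sublethal)) {
      m_lfc <- stats::runif(5, config$marker_lfc[1], config$marker_lfc[2])
      s_lfc <- stats::runif(3, config$marker_lfc[1], config$marker_lfc[2])
      for (tp in EARLY_TIMEPOINTS) {
        add_cell(d, tp, marker_panel, m_lfc)
        add_cell(d, tp, sublethal_unique, s_lfc)
      }
    }
    dL <- as.character(config$lethal_dose)
    mL <- stats::runif(5, config$lethal_marker_lfc[1], config$lethal_marker_lfc[2])
    for (tp in config$blocks[[dL]]$tps) add_cell(dL, tp, marker_panel, -mL)
  }

  ## Sample layout: controls at every time point, lethal dose truncated.
  meta <- do.call(rbind, lapply(c(0, config$doses), function(d) {
    tps <- if (d == config$lethal_dose) config$timepoints[1:3] else config$timepoints
    expand.grid(replicate = seq_len(config$n_replicates), timepoint = tps,
                dose_gy = d, stringsAsFactors = FALSE)
  }))
  meta$sample <- sprintf("s%gGy_%s_r%d", meta$dose_gy, meta$timepoint, meta$replicate)
  meta <- meta[c("sample", "dose_gy", "timepoint", "replicate")]

  ## Generation phase: per-gene streams.
  d0 <- config$variance_prior[["d0"]]
  s0 <- config$variance_prior[["s0_sq"]]
  vals <- matrix(0, n, nrow(meta), dimnames = list(gene_id(seq_len(n)), meta$sample))
  for (g in seq_len(n)) {
    set.seed(gene_seed(config$seed, g))
    base <- stats::rnorm(1, config$baseline[["mean"]], config$baseline[["sd"]])
    sig2 <- d0 * s0 / stats::rchisq(1, d0)
    vals[g, ] <- base + stats::rnorm(nrow(meta), 0, sqrt(sig2))
  }
  for (key in names(planted)) {
    dtp <- strsplit(key, "|", fixed = TRUE)[[1]]
    cols <- which(meta$dose_gy == as.numeric(dtp[1]) & meta$timepoint == dtp[2])
    df <- planted[[key]]
    vals[df$gene, cols] <- vals[df$gene, cols] + df$lfc
  }

  truth <- structure(list(planted_de = planted, marker_panel = marker_panel,
                          sublethal_unique = sublethal_unique),
                     class = "sim_truth")
  list(expr = expression_matrix(vals, meta), truth = truth)
}

#' Write / read simulation ground truth as JSON
#'
#' @param truth a `sim_truth` from [simulate_experiment()].
#' @param path output path.
#' @return `write_truth` returns `path` invisibly; `read_truth` returns the
#'   `sim_truth`, round-tripped losslessly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  planted <- lapply(raw$planted_de, function(df) {
    if (length(df) == 0) data.frame(gene = character(0), lfc = numeric(0))
    else data.frame(gene = as.character(df$gene), lfc = as.numeric(df$lfc))
  })
  structure(list(planted_de = planted,
                 marker_panel = as.character(unlist(raw$marker_panel)),
                 sublethal_unique = as.character(unlist(raw$sublethal_unique))),
            class = "sim_truth")
}
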