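#' Dosimetry decision rules
#'
#' Numeric cutoffs for the rule cascade of [classify_exposure()]. The defaults
#' sit midway between the lethal signature (about 90% downregulation in the
#' first post-exposure week, about 59% of the union common to all time points)
#' and the sublethal one (about 70% upregulation, at most 11% common), leaving
#' a margin on both sides.
#'
#' @param lethal_down_fraction_min minimum mean downregulated fraction over
#'   the early time points for the lethal down-dominance rule.
#' @param lethal_stationarity_min minimum stationarity index (all-common /
#'   union) for the lethal stationarity rule.
#' @param sublethal_up_fraction_min minimum mean upregulated fraction over the
#'   early time points for the sublethal rule.
#' @param panel_fc_min per-cell absolute fold-change threshold of the marker
#'   panel.
#' @param panel_mean_fc_min panel-average absolute fold-change threshold.
#' @param late_inversion_downweight optional flag: treat a late-time-point
#'   swing to down-dominance as weakening a sublethal call (reported in the
#'   evidence, default off).
#' @return object of class `dosimetry_rules`.
#' @export
dosimetry_rules <- function(lethal_down_fraction_min = 0.60,
                            lethal_stationarity_min = 0.40,
                            sublethal_up_fraction_min = 0.55,
                            panel_fc_min = 2,
                            panel_mean_fc_min = 3,
                            late_inversion_downweight = FALSE) {
  fr <- c(lethal_down_fraction_min, lethal_stationarity_min, sublethal_up_fraction_min)
  if (any(fr <= 0 | fr >= 1)) stop_config("rule fractions must lie in (0, 1)")
  structure(list(lethal_down_fraction_min = lethal_down_fraction_min,
                 lethal_stationarity_min = lethal_stationarity_min,
                 sublethal_up_fraction_min = sublethal_up_fraction_min,
                 panel_fc_min = panel_fc_min,
                 panel_mean_fc_min = panel_mean_fc_min,
                 late_inversion_downweight = late_inversion_downweight),
            class = "dosimetry_rules")
}

## Map a peak time point to an ordinal sublethal dose-class label.
peak_class <- function(peak_tp) {
  switch(peak_tp, "2h" = "low", "d4" = "low", "d7" = "mid",
         "d21" = "high", "d28" = "high", NA_character_)
}

#' Classify one dose arm as lethal or sublethal exposure
#'
#' Deterministic rule cascade on the set-dynamics evidence of a single dose
#' arm. A lethal call requires both the early down-dominance rule and the
#' stationarity rule to fire; a sublethal call requires early up-dominance and
#' low stationarity; anything else (including missing early time points or
#' empty SDTG sets) is an explicit indeterminate, never a silent default.
#' Sublethal calls carry an ordinal dose-class estimate from the upregulation
#' peak time (2h/d4 -> low, d7 -> mid, later -> high).
#'
#' @param summary a [direction_trajectory()] result for the dose arm.
#' @param partition optional [partition_sets()] over the arm's early time
#'   points; defaults to the partition embedded in `summary` (which spans all
#'   its time points).
#' @param rules a [dosimetry_rules()].
#' @return object of class `dose_call`: `call` (lethal / sublethal /
#'   indeterminate), `dose_class`, `evidence`, `reasons`.
#' @export
classify_exposure <- function(summary, partition = NULL, rules = dosimetry_rules()) {
  stopifnot(inherits(summary, "dynamics_summary"))
  stat <- if (!is.null(partition)) stationarity_stats(partition)$stationarity_index
          else summary$stationarity_index
  ucr <- if (!is.null(partition)) stationarity_stats(partition)$unique_common_ratio
         else summary$unique_common_ratio
  early <- summary$timepoints %in% EARLY_TIMEPOINTS
  pu <- summary$percent_up[early]
  pu <- pu[!is.na(pu)]
  evidence <- list(stationarity_index = stat, early_percent_up = pu,
                   peak_tp_up = summary$peak_tp_up, unique_common_ratio = ucr)
  make <- function(call, dose_class, reasons) {
    structure(list(call = call, dose_class = dose_class, evidence = evidence,
                   reasons = reasons, rules = rules, dose_gy = summary$dose_gy),
              class = "dose_call")
  }
  if (length(pu) < 2) {
    return(make("indeterminate", NA_character_,
                "fewer than 2 early time points with any SDTGs"))
  }
  if (is.na(stat)) {
    return(make("indeterminate", NA_character_, "empty union: no set statistics"))
  }
  mean_down <- mean(100 - pu) / 100
  mean_up <- mean(pu) / 100
  lethal_fires <- mean_down >= rules$lethal_down_fraction_min &&
    stat >= rules$lethal_stationarity_min
  sublethal_fires <- mean_up >= rules$sublethal_up_fraction_min &&
    stat < rules$lethal_stationarity_min
  if (lethal_fires && !sublethal_fires) {
    return(make("lethal", NA_character_,
                sprintf("early down fraction %.2f >= %.2f and stationarity %.2f >= %.2f",
                        mean_down, rules$lethal_down_fraction_min, stat,
                        rules$lethal_stationarity_min)))
  }
  if (sublethal_fires && !lethal_fires) {
    late <- !(summary$timepoints %in% EARLY_TIMEPOINTS)
    note <- sprintf("early up fraction %.2f >= %.2f and stationarity %.2f < %.2f",
                    mean_up, rules$sublethal_up_fraction_min, stat,
                    rules$lethal_stationarity_min)
    if (rules$late_inversion_downweight && any(summary$percent_up[late] < 50, na.rm = TRUE)) {
      note <- paste0(note, "; late down-dominance observed (confidence reduced)")
    }
    return(make("sublethal", peak_class(summary$peak_tp_up), note))
  }
  make("indeterminate", NA_character_,
       sprintf("rules conflict or none fired (early up %.2f, down %.2f, stationarity %.2f)",
               mean_up, mean_down, stat))
}

#' @export
print.dose_call <- function(x, ...) {
  cat(sprintf("exposure call%s: %s",
              if (!is.null(x$dose_gy)) sprintf(" (%g Gy arm)", x$dose_gy) else "",
              toupper(x$call)))
  if (!is.na(x$dose_class)) cat(" [dose class:", x$dose_class, "]")
  cat("\n  stationarity:", round(x$evidence$stationarity_index, 4),
      "| early % up:", paste(round(x$evidence$early_percent_up, 1), collapse = ", "),
      "| peak:", x$evidence$peak_tp_up, "\n")
  cat("  reason:", x$reasons, "\n")
  invisible(x)
}

#' Rank sublethal dose arms by response-peak shift
#'
#' Orders dose arms by the time point of peak upregulation (later peak =
#' higher dose class); ties are broken by the unique/common ratio, which
#' decreases with dose.
#'
#' @param summaries list of [direction_trajectory()] results, one per arm.
#' @return data.frame (dose_gy, peak_tp, unique_common_ratio, rank), ordered
#'   from lowest to highest implied dose.
#' @export
sublethal_peak_order <- function(summaries) {
  df <- data.frame(
    dose_gy = vapply(summaries, `[[`, 0, "dose_gy"),
    peak_tp = vapply(summaries, `[[`, "", "peak_tp_up"),
    unique_common_ratio = vapply(summaries, `[[`, 0, "unique_common_ratio"))
  peak_i <- match(df$peak_tp, TIMEPOINTS)
  ord <- order(peak_i, -df$unique_common_ratio)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Sign-consistency score of a marker panel
#'
#' A panel gene is consistent when its fold change is at least `panel_fc_min`
#' in every sublethal (dose, time point) cell and at most `-panel_fc_min` in
#' every lethal cell. Genes with missing cells are unevaluable and excluded
#' from the count. Invariant to gene and cell order.
#'
#' @param fc_grid numeric matrix of signed linear fold changes, genes in rows,
#'   cells in columns named `"<dose>|<tp>"`.
#' @param panel_genes gene ids to score (rows of `fc_grid`).
#' @param lethal_dose dose (Gy) whose cells must show downregulation.
#' @param rules a [dosimetry_rules()].
#' @return list with `n_consistent` and `detail` (per-gene verdict,
#'   `consistent` / `inconsistent` / `unevaluable`, plus the mean |FC|).
#' @export
panel_score <- function(fc_grid, panel_genes, lethal_dose = 20,
                        rules = dosimetry_rules()) {
  if (length(panel_genes) == 0) {
    return(list(n_consistent = 0L,
                detail = data.frame(gene = character(0), verdict = character(0),
                                    mean_abs_fc = numeric(0))))
  }
  cell_dose <- as.numeric(vapply(strsplit(colnames(fc_grid), "|", fixed = TRUE),
                                 `[[`, "", 1))
  lethal_cells <- cell_dose == lethal_dose
  verdict <- character(length(panel_genes))
  mabs <- numeric(length(panel_genes))
  for (i in seq_along(panel_genes)) {
    g <- panel_genes[i]
    if (!g %in% rownames(fc_grid) || anyNA(fc_grid[g, ])) {
      verdict[i] <- "unevaluable"; mabs[i] <- NA_real_
      next
    }
    v <- fc_grid[g, ]
    ok <- all(v[!lethal_cells] >= rules$panel_fc_min) &&
      all(v[lethal_cells] <= -rules$panel_fc_min)
    verdict[i] <- if (ok) "consistent" else "inconsistent"
    mabs[i] <- mean(abs(v))
  }
  list(n_consistent = sum(verdict == "consistent"),
       detail = data.frame(gene = panel_genes, verdict = verdict,
                           mean_abs_fc = mabs, row.names = NULL))
}

#' Screen for genes unique to the sublethal response
#'
#' Exact set algebra on a full SDTG grid: genes upregulated in every sublethal
#' (dose, early time point) cell and absent from every lethal SDTG set.
#'
#' @param sets named list (`"<dose>|<tp>"`) of [sdtg_set()]s.
#' @param lethal_dose dose (Gy) of the lethal arm.
#' @param early_timepoints time points that define the screening window.
#' @return character vector of gene ids.
#' @export
sublethal_unique_screen <- function(sets, lethal_dose = 20,
                                    early_timepoints = EARLY_TIMEPOINTS) {
  key <- do.call(rbind, strsplit(names(sets), "|", fixed = TRUE))
  doses <- as.numeric(key[, 1]); tps <- key[, 2]
  sub_cells <- which(doses != lethal_dose & tps %in% early_timepoints)
  lethal_cells <- which(doses == lethal_dose)
  if (!length(sub_cells)) return(character(0))
  up_everywhere <- Reduce(intersect, lapply(sets[sub_cells], `[[`, "up"))
  in_lethal <- unique(unlist(lapply(sets[lethal_cells], sdtg_genes)))
  sort(setdiff(up_everywhere, in_lethal))
}
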