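#' Venn partition of SDTG sets along one axis
#'
#' Decomposes a collection of SDTG sets (the time points of one dose, or the
#' doses at one time point) into exact Venn blocks. "Unique" means present in
#' exactly one set; "common" means present in all. Intermediate blocks are
#' retained in `blocks`.
#'
#' @param sets list of [sdtg_set()] objects sharing a gene universe.
#' @param labels axis labels, one per set; defaults to each set's time point
#'   (or dose when time points repeat).
#' @param axis descriptive tag stored on the result.
#' @return object of class `set_partition` with `union_count`,
#'   `common_to_all_count`, `unique_counts`, `unique_percent`,
#'   `common_percent` (half-up, 2 decimals; `NA` when the union is empty) and
#'   the full `blocks` table (membership pattern -> count).
#' @export
partition_sets <- function(sets, labels = NULL, axis = "across-TPs-within-dose") {
  if (length(sets) < 2) stop_data("need at least 2 sets to partition")
  if (is.null(labels)) {
    tps <- vapply(sets, `[[`, "", "timepoint")
    labels <- if (!anyDuplicated(tps)) tps
    else paste0(vapply(sets, function(s) as.character(s$dose_gy), ""), "Gy")
  }
  if (anyDuplicated(labels)) stop_data("duplicated axis labels in partition")
  members <- lapply(sets, sdtg_genes)
  names(members) <- labels
  universe <- unique(unlist(members))
  n_union <- length(universe)

  if (n_union == 0) {
    pattern <- character(0); block_n <- integer(0)
    n_each <- setNames(rep(0L, length(labels)), labels)
    uniq <- setNames(rep(0L, length(labels)), labels)
    common <- 0L
  } else {
    inset <- vapply(members, function(g) universe %in% g, logical(n_union))
    if (n_union == 1) inset <- matrix(inset, nrow = 1, dimnames = list(NULL, labels))
    key <- apply(inset, 1, function(r) paste(ifelse(r, "1", "0"), collapse = ""))
    tab <- table(key)
    pattern <- names(tab); block_n <- as.integer(tab)
    deg <- rowSums(inset)
    uniq <- vapply(seq_along(labels), function(j) {
      sum(inset[, j] & deg == 1L)
    }, integer(1))
    names(uniq) <- labels
    common <- sum(deg == length(labels))
    n_each <- colSums(inset)
  }
  pct <- function(k) {
    if (n_union == 0) rep(NA_real_, length(k)) else round_half_up(100 * k / n_union, 2)
  }
  structure(list(axis = axis, labels = labels,
                 union_count = n_union,
                 set_counts = n_each,
                 common_to_all_count = as.integer(common),
                 unique_counts = uniq,
                 unique_percent = pct(uniq),
                 common_percent = unname(pct(common)),
                 blocks = data.frame(pattern = pattern, count = block_n),
                 universe = universe,
                 membership = if (n_union) inset else NULL),
            class = "set_partition")
}

#' @export
print.set_partition <- function(x, ...) {
  cat("set partition (", x$axis, "): union ", x$union_count,
      ", common to all ", x$common_to_all_count, "\n", sep = "")
  df <- data.frame(label = x$labels, unique = x$unique_counts,
                   unique_pct = x$unique_percent, row.names = NULL)
  print(df)
  invisible(x)
}

#' Stationarity and unique/common statistics of a partition
#'
#' The stationarity index is the fraction of the union common to all labels
#' (high after lethal exposure). The unique/common ratio divides the first
#' label's unique count by the all-common count and decreases with dose; it is
#' flagged `Inf` when nothing is common and both statistics are `NA` when the
#' union is empty. The inverse orientation (common/unique) is also reported.
#'
#' @param partition a [partition_sets()] result.
#' @return list with `stationarity_index`, `unique_common_ratio`,
#'   `common_unique_ratio` and `undefined` flag.
#' @export
stationarity_stats <- function(partition) {
  stopifnot(inherits(partition, "set_partition"))
  u <- partition$union_count
  if (u == 0) {
    return(list(stationarity_index = NA_real_, unique_common_ratio = NA_real_,
                common_unique_ratio = NA_real_, undefined = TRUE))
  }
  common <- partition$common_to_all_count
  first_unique <- partition$unique_counts[[1]]
  list(stationarity_index = common / u,
       unique_common_ratio = if (common > 0) first_unique / common else Inf,
       common_unique_ratio = if (first_unique > 0) common / first_unique else Inf,
       undefined = FALSE)
}

#' Up/down regulation trajectory of one dose
#'
#' Longitudinal direction statistics for the SDTG sets of a single dose:
#' per-time-point up/down counts and upregulated percentage, the time point of
#' peak upregulation (ties to the earliest), early down-dominance, plus the
#' partition-derived stationarity index and unique/common ratio.
#'
#' @param sets list of [sdtg_set()]s of one dose, in time-point order.
#' @return object of class `dynamics_summary`.
#' @export
direction_trajectory <- function(sets) {
  doses <- unique(vapply(sets, `[[`, 0, "dose_gy"))
  if (length(doses) != 1) stop_data("trajectory expects the sets of a single dose")
  tps <- unname(vapply(sets, `[[`, "", "timepoint"))
  ord <- order(match(tps, TIMEPOINTS))
  sets <- sets[ord]; tps <- tps[ord]
  n_up <- vapply(sets, function(s) length(s$up), integer(1))
  n_down <- vapply(sets, function(s) length(s$down), integer(1))
  total <- n_up + n_down
  percent_up <- ifelse(total > 0, 100 * n_up / total, NA_real_)
  peak_tp_up <- if (all(total == 0)) NA_character_ else tps[which.max(n_up)]
  early <- tps %in% EARLY_TIMEPOINTS
  part <- if (length(sets) >= 2) partition_sets(sets, labels = tps) else NULL
  stats <- if (!is.null(part)) stationarity_stats(part) else
    list(stationarity_index = NA_real_, unique_common_ratio = NA_real_,
         common_unique_ratio = NA_real_, undefined = TRUE)
  structure(list(dose_gy = doses, timepoints = tps,
                 n_up = setNames(n_up, tps), n_down = setNames(n_down, tps),
                 percent_up = setNames(percent_up, tps),
                 peak_tp_up = peak_tp_up,
                 early_down_dominant = all(percent_up[early] < 50, na.rm = TRUE) &&
                   !all(is.na(percent_up[early])),
                 stationarity_index = stats$stationarity_index,
                 unique_common_ratio = stats$unique_common_ratio,
                 common_unique_ratio = stats$common_unique_ratio,
                 partition = part),
            class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf("dynamics %g Gy: peak upregulation at %s, stationarity %.3f\n",
              x$dose_gy, x$peak_tp_up, x$stationarity_index))
  print(data.frame(timepoint = x$timepoints, n_up = x$n_up, n_down = x$n_down,
                   percent_up = round_half_up(x$percent_up, 2), row.names = NULL))
  invisible(x)
}

#' Crosstab report of SDTG distributions
#'
#' Reproduces the layout of the published distribution tables: per group of
#' sets, the union, the all-common count, and per-label unique counts with
#' percentages of the union (half-up, 2 decimals; flagged `NA` when the union
#' is empty).
#'
#' @param sets named list (`"<dose>|<tp>"`) of [sdtg_set()]s — the full grid.
#' @param axis `"dose"` (one row per dose, partitioned across its time
#'   points), `"timepoint"` (one row per time point, partitioned across
#'   doses), or `"global"` (single partition across every (dose, time point)
#'   cell).
#' @return data.frame in long form: group, union, common, label, unique count
#'   and percentage.
#' @export
crosstab_report <- function(sets, axis = c("dose", "timepoint", "global")) {
  axis <- match.arg(axis)
  key <- do.call(rbind, strsplit(names(sets), "|", fixed = TRUE))
  doses <- key[, 1]; tps <- key[, 2]
  rows <- list()
  add_rows <- function(group, part) {
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, union = part$union_count, common = part$common_to_all_count,
      common_pct = part$common_percent,
      label = part$labels, unique = unname(part$unique_counts),
      unique_pct = unname(part$unique_percent), row.names = NULL)
  }
  if (axis == "dose") {
    for (d in unique(doses)) {
      idx <- which(doses == d)
      idx <- idx[order(match(tps[idx], TIMEPOINTS))]
      add_rows(paste0(d, "Gy"), partition_sets(sets[idx], labels = tps[idx],
                                               axis = "across-TPs-within-dose"))
    }
  } else if (axis == "timepoint") {
    for (tp in TIMEPOINTS[TIMEPOINTS %in% tps]) {
      idx <- which(tps == tp)
      idx <- idx[order(as.numeric(doses[idx]))]
      add_rows(tp, partition_sets(sets[idx], labels = paste0(doses[idx], "Gy"),
                                  axis = "across-doses-within-TP"))
    }
  } else {
    add_rows("global", partition_sets(sets, labels = names(sets), axis = "global"))
  }
  do.call(rbind, rows)
}
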