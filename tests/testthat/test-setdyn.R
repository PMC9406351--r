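test_that("partition handles identical and disjoint sets exactly", {
  s1 <- sdtg_set(1, "2h", up = paste0("g", 1:10), down = character(0))
  s2 <- sdtg_set(1, "d4", up = paste0("g", 1:10), down = character(0))
  p <- partition_sets(list(s1, s2))
  expect_equal(p$common_to_all_count, 10)
  expect_equal(p$union_count, 10)
  expect_equal(unname(p$unique_counts), c(0L, 0L))

  s3 <- sdtg_set(1, "d4", up = paste0("h", 1:7), down = character(0))
  p2 <- partition_sets(list(s1, s3))
  expect_equal(p2$common_to_all_count, 0)
  expect_equal(sum(p2$unique_counts), p2$union_count)
})

test_that("partition rejects duplicated labels and tiny inputs", {
  s1 <- sdtg_set(1, "2h", up = "a", down = character(0))
  expect_error(partition_sets(list(s1)), class = "radskin_data_error")
  expect_error(partition_sets(list(s1, s1), labels = c("x", "x")),
               class = "radskin_data_error")
})

test_that("partition counts match an exhaustive membership oracle", {
  set.seed(99)
  for (case in 1:12) {
    k <- sample(2:5, 1)
    genes <- paste0("g", 1:50)
    lists <- lapply(seq_len(k), function(i) sample(genes, sample(0:50, 1)))
    labels <- paste0("L", seq_len(k))
    sets <- lapply(seq_len(k), function(i) {
      sdtg_set(1, "2h", up = lists[[i]], down = character(0))
    })
    p <- partition_sets(sets, labels = labels)
    oracle <- brute_partition(setNames(lists, labels))
    expect_equal(p$union_count, oracle$union)
    expect_equal(p$common_to_all_count, oracle$common)
    expect_equal(unname(p$unique_counts), unname(oracle$unique[labels]))
    # conservation: Venn blocks tile the union exactly
    expect_equal(sum(p$blocks$count), p$union_count)
    expect_equal(sort(p$blocks$count), sort(unname(oracle$block_sizes)))
  }
})

test_that("dose-wise fixture percentages reproduce the printed arithmetic", {
  sets <- venn_sets(c("2h", "d4", "d7", "d21", "d28"), union = 619, common = 1,
                    unique_counts = c(125, 101, 26, 51, 62))
  p <- partition_sets(sets, labels = names(sets))
  expect_equal(p$union_count, 619)
  expect_equal(p$common_to_all_count, 1)
  expect_equal(p$unique_percent[["2h"]], round_half_up(100 * 125 / 619, 2))
  expect_printed_pct(p$unique_percent[["2h"]], 20.2)
})

test_that("stationarity statistics follow the exact set arithmetic", {
  lethal <- venn_sets(c("2h", "d4", "d7"), union = 1038, common = 609,
                      unique_counts = c(57, 80, 89))
  p <- partition_sets(lethal, labels = names(lethal))
  st <- stationarity_stats(p)
  expect_equal(st$stationarity_index, 609 / 1038, tolerance = 1e-15)
  expect_printed_pct(100 * st$stationarity_index, 58.6)
  expect_equal(st$unique_common_ratio, 57 / 609, tolerance = 1e-15)

  # no common genes: ratio flagged infinite, index 0
  none <- venn_sets(c("2h", "d4", "d7", "d21", "d28"), union = 411, common = 0,
                    unique_counts = c(61, 35, 20, 99, 82))
  st2 <- stationarity_stats(partition_sets(none, labels = names(none)))
  expect_identical(st2$unique_common_ratio, Inf)
  expect_equal(st2$stationarity_index, 0)

  # degenerate singleton experiment: one gene in both sets
  s <- list(sdtg_set(1, "2h", "g1", character(0)),
            sdtg_set(1, "d4", "g1", character(0)))
  st3 <- stationarity_stats(partition_sets(s))
  expect_equal(st3$stationarity_index, 1)
  expect_equal(st3$unique_common_ratio, 0)

  # empty union: everything undefined-flagged
  e <- list(sdtg_set(1, "2h", character(0), character(0)),
            sdtg_set(1, "d4", character(0), character(0)))
  st4 <- stationarity_stats(partition_sets(e))
  expect_true(st4$undefined)
  expect_true(is.na(st4$stationarity_index))
})

test_that("direction trajectories report peaks, missing values and dominance", {
  mk <- function(tp, up, down) {
    sdtg_set(6, tp, up = paste0("u", tp, seq_len(up)),
             down = if (down) paste0("d", tp, seq_len(down)) else character(0))
  }
  sets <- list(mk("2h", 10, 5), mk("d4", 30, 5), mk("d7", 30, 2))
  tr <- direction_trajectory(sets)
  expect_equal(unname(tr$n_up), c(10, 30, 30))
  # tie on n_up resolved to the earliest time point
  expect_equal(tr$peak_tp_up, "d4")
  expect_false(tr$early_down_dominant)

  # all genes up: percent_up is 100 everywhere
  all_up <- list(mk("2h", 5, 0), mk("d4", 7, 0))
  expect_true(all(direction_trajectory(all_up)$percent_up == 100))

  # an empty time point is missing, not zero
  sets2 <- list(mk("2h", 4, 2), sdtg_set(6, "d4", character(0), character(0)))
  tr2 <- direction_trajectory(sets2)
  expect_true(is.na(tr2$percent_up[["d4"]]))

  # down-dominated early course
  down_sets <- list(mk("2h", 1, 9), mk("d4", 2, 18), mk("d7", 1, 9))
  expect_true(direction_trajectory(down_sets)$early_down_dominant)
})

test_that("crosstab reports reproduce printed global and per-time-point cells", {
  glob <- read.delim(extdata("global_venn_counts.tsv"))
  labels <- paste(glob$dose_gy, glob$timepoint, sep = "|")
  sets <- venn_sets(labels, union = glob$union[1], common = glob$common[1],
                    unique_counts = glob$unique)
  names(sets) <- labels
  tab <- crosstab_report(sets, axis = "global")
  expect_equal(tab$union[1], 1665)
  cell <- tab[tab$label == "1|2h", ]
  expect_equal(cell$unique, 37)
  expect_equal(cell$unique_pct, round_half_up(100 * 37 / 1665, 2))
  expect_printed_pct(cell$unique_pct, 2.22)

  tp <- venn_sets(c("1Gy", "3Gy", "6Gy", "20Gy"), union = 1096, common = 17,
                  unique_counts = c(83, 14, 36, 702))
  p <- partition_sets(tp, labels = names(tp), axis = "across-doses-within-TP")
  expect_printed_pct(p$unique_percent[["20Gy"]], 64.05)

  # an all-empty grid yields zero counts with undefined percentages
  empty <- list("1|2h" = sdtg_set(1, "2h", character(0), character(0)),
                "1|d4" = sdtg_set(1, "d4", character(0), character(0)))
  etab <- crosstab_report(empty, axis = "dose")
  expect_true(all(etab$union == 0))
  expect_true(all(is.na(etab$unique_pct)))
})
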