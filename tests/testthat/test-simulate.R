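test_that("simulation is deterministic given the seed", {
  cfg <- small_config(seed = 11)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_experiment(small_config(seed = 12))
  expect_false(identical(a$expr$values, c_$expr$values))
})

test_that("per-gene streams are stable when n_genes grows", {
  a <- simulate_experiment(sim_config_null(seed = 5, n_genes = 80))
  b <- simulate_experiment(sim_config_null(seed = 5, n_genes = 120))
  expect_identical(a$expr$values, b$expr$values[1:80, ])
})

test_that("group layout matches the study design", {
  cfg <- sim_config_preset(seed = 2, n_genes = 1200)
  sim <- simulate_experiment(cfg)
  meta <- sim$expr$meta
  # controls at every time point, lethal arm truncated after day 7
  expect_setequal(unique(meta$timepoint[meta$dose_gy == 0]),
                  c("2h", "d4", "d7", "d21", "d28"))
  expect_setequal(unique(meta$timepoint[meta$dose_gy == 20]), c("2h", "d4", "d7"))
  tab <- table(meta$dose_gy, meta$timepoint)
  expect_true(all(tab[, ] %in% c(0, 5)))
  expect_false(anyNA(sim$expr$values))
})

test_that("the preset encodes the reported response architecture", {
  cfg <- sim_config_preset()
  # dose-wise unions and common fractions
  unions <- vapply(cfg$blocks, `[[`, 0, "union")
  expect_equal(unname(unions), c(619, 411, 765, 1038))
  expect_equal(unname(cfg$common_fraction[["20"]]), 609 / 1038, tolerance = 1e-12)
  expect_true(all(cfg$common_fraction[c("1", "3", "6")] <= 0.11))
  # up-dominance pattern: lethal < 0.5, sublethal > 0.5 in the first week
  expect_true(all(cfg$up_fraction["20", c("2h", "d4", "d7")] < 0.5))
  expect_true(all(cfg$up_fraction[c("1", "3", "6"), c("2h", "d4", "d7")] > 0.5))
  # upregulation peak: day 4 at 1 and 3 Gy, delayed to day 7 at 6 Gy
  expect_equal(unname(cfg$peak_tp[c("1", "3", "6")]), c("d4", "d4", "d7"))
})

test_that("planted effects shift group means by the true log2FC", {
  # noise-free limit: s0_sq = 0
  cfg <- small_config(seed = 3, s0_sq = 0)
  sim <- simulate_experiment(cfg)
  x <- sim$expr
  for (key in names(sim$truth$planted_de)) {
    dtp <- strsplit(key, "|", fixed = TRUE)[[1]]
    i1 <- which(x$meta$dose_gy == as.numeric(dtp[1]) & x$meta$timepoint == dtp[2])
    i0 <- which(x$meta$dose_gy == 0 & x$meta$timepoint == dtp[2])
    df <- sim$truth$planted_de[[key]]
    diff <- rowMeans(x$values[df$gene, i1, drop = FALSE]) -
      rowMeans(x$values[df$gene, i0, drop = FALSE])
    expect_equal(unname(diff), df$lfc, tolerance = 1e-10)
  }
  # non-planted genes: equal group means
  planted_all <- unique(unlist(lapply(sim$truth$planted_de, `[[`, "gene")))
  others <- setdiff(rownames(x$values), planted_all)[1:50]
  i1 <- which(x$meta$dose_gy == 1 & x$meta$timepoint == "2h")
  i0 <- which(x$meta$dose_gy == 0 & x$meta$timepoint == "2h")
  expect_equal(rowMeans(x$values[others, i1]), rowMeans(x$values[others, i0]),
               tolerance = 1e-10)
})

test_that("near-noise-free planted effects are recovered almost completely", {
  cfg <- small_config(seed = 9, lfc_range = c(1, 1), s0_sq = 0)
  sim <- simulate_experiment(cfg)
  de <- de_all_contrasts(sim$expr)
  for (key in names(sim$truth$planted_de)) {
    planted <- sim$truth$planted_de[[key]]$gene
    found <- radskin:::sdtg_genes(call_sdtgs(de$contrasts[[key]]))
    expect_gte(mean(planted %in% found), 0.99)
  }
})

test_that("null configuration plants nothing and calibrates raw p-values", {
  cfg <- sim_config_null(seed = 21, n_genes = 4000)
  sim <- simulate_experiment(cfg)
  expect_length(sim$truth$planted_de, 0)
  ct <- moderated_t_contrast(sim$expr, 20, "2h")
  frac <- mean(ct$p_raw < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(ct))
  expect_lte(abs(frac - 0.05), 3 * se)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config_preset(n_genes = 500), class = "radskin_config_error")
  venn <- list("1" = list(union = 5, common = 4, unique = c(2, 2, 2)),
               "20" = list(union = 5, common = 0, unique = c(1, 1, 1)))
  up <- rbind("1" = rep(0.5, 3), "20" = rep(0.5, 3))
  colnames(up) <- c("2h", "d4", "d7")
  expect_error(
    sim_config(n_genes = 100, doses = c(1, 20), lethal_dose = 20,
               timepoints = c("2h", "d4", "d7"), venn = venn, up_fraction = up),
    class = "radskin_config_error")
  expect_error(sim_config(n_genes = 100, venn = list(), up_fraction = up),
               class = "radskin_config_error")
})

test_that("truth JSON round-trips losslessly", {
  cfg <- small_config(seed = 4, plant_markers = TRUE)
  sim <- simulate_experiment(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back, sim$truth)
  expect_length(back$marker_panel, 5)
  expect_length(back$sublethal_unique, 3)
  expect_length(intersect(back$marker_panel, back$sublethal_unique), 0)

  empty <- structure(list(planted_de = list(), marker_panel = character(0),
                          sublethal_unique = character(0)), class = "sim_truth")
  write_truth(empty, path)
  expect_equal(read_truth(path), empty)
})
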