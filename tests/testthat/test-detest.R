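test_that("fold change maps log2 differences to signed linear FC", {
  # a published panel value: mean difference log2(2.41) is an FC of 2.41
  fc <- fold_change(8 + log2(2.41), 8)
  expect_equal(fc$fc, 2.41, tolerance = 1e-12)
  expect_equal(fc$log2fc, log2(2.41), tolerance = 1e-12)
  # identity and symmetry
  expect_equal(fold_change(5, 5), list(log2fc = 0, fc = 1))
  expect_equal(fold_change(4, 5)$fc, -2)
  # |fc| >= 1 for any log2fc, and sign follows the difference
  lfc <- seq(-5, 5, by = 0.25)
  out <- fold_change(lfc, 0)
  expect_true(all(abs(out$fc) >= 1))
  expect_true(all(sign(out$fc) == ifelse(lfc >= 0, 1, -1)))
})

test_that("moderated t with d0 = 0 equals the ordinary pooled two-sample t", {
  sim <- simulate_experiment(small_config(seed = 31, n_genes = 150))
  x <- sim$expr
  ct <- moderated_t_contrast(x, 1, "d4", params = list(d0 = 0, s0_sq = 1))
  i1 <- which(x$meta$dose_gy == 1 & x$meta$timepoint == "d4")
  i0 <- which(x$meta$dose_gy == 0 & x$meta$timepoint == "d4")
  # brute-force oracle: per-gene pooled t computed independently
  for (g in seq_len(nrow(x$values))) {
    a <- x$values[g, i1]; b <- x$values[g, i0]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    t_ref <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
    expect_lt(abs(ct$t_mod[g] - t_ref), 1e-10)
    p_ref <- 2 * pt(-abs(t_ref), df = length(a) + length(b) - 2)
    expect_lt(abs(ct$p_raw[g] - p_ref), 1e-12)
  }
})

test_that("d0 = Inf shrinks every variance fully to the prior", {
  sim <- simulate_experiment(small_config(seed = 32, n_genes = 120))
  x <- sim$expr
  s0 <- 0.2
  ct <- moderated_t_contrast(x, 1, "2h", params = list(d0 = Inf, s0_sq = s0))
  i1 <- which(x$meta$dose_gy == 1 & x$meta$timepoint == "2h")
  i0 <- which(x$meta$dose_gy == 0 & x$meta$timepoint == "2h")
  lfc <- rowMeans(x$values[, i1]) - rowMeans(x$values[, i0])
  t_expected <- lfc / sqrt(s0 * (1 / length(i1) + 1 / length(i0)))
  expect_equal(ct$t_mod, unname(t_expected), tolerance = 1e-12)
})

test_that("moderation estimates and moderated t agree with the limma oracle", {
  sim <- simulate_experiment(small_config(seed = 33, n_genes = 2000))
  x <- sim$expr
  i1 <- which(x$meta$dose_gy == 1 & x$meta$timepoint == "2h")
  i0 <- which(x$meta$dose_gy == 0 & x$meta$timepoint == "2h")
  ct <- moderated_t_contrast(x, 1, "2h")
  mp <- attr(ct, "moderation")

  m <- x$values[, c(i0, i1)]
  design <- cbind(1, rep(c(0, 1), c(length(i0), length(i1))))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(mp$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(mp$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(ct$t_mod, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(ct$p_raw, unname(fit$p.value[, 2]), tolerance = 1e-10)
  # posterior variance lies between prior and sample variance
  sg <- radskin:::row_vars(x$values[, i1]) * (length(i1) - 1) / 8 +
    radskin:::row_vars(x$values[, i0]) * (length(i0) - 1) / 8
  st <- radskin:::squeeze_variance(sg, 8, mp$d0, mp$s0_sq)
  expect_true(all(st >= pmin(sg, mp$s0_sq) - 1e-12))
  expect_true(all(st <= pmax(sg, mp$s0_sq) + 1e-12))
})

test_that("BH adjustment is monotone and never below the raw p", {
  sim <- simulate_experiment(sim_config_null(seed = 34, n_genes = 3000))
  ct <- moderated_t_contrast(sim$expr, 6, "d7")
  ord <- order(ct$p_raw)
  expect_true(all(diff(ct$p_adj[ord]) >= -1e-15))
  expect_true(all(ct$p_adj >= ct$p_raw - 1e-15))
  expect_equal(ct$p_adj, p.adjust(ct$p_raw, "BH"))
})

test_that("SDTG sets shrink as thresholds tighten", {
  sim <- simulate_experiment(small_config(seed = 35))
  ct <- moderated_t_contrast(sim$expr, 20, "2h")
  sizes <- sapply(c(1, 1.5, 2, 3, 4), function(f) {
    s <- call_sdtgs(ct, de_thresholds(fc_min = f))
    length(s$up) + length(s$down)
  })
  expect_true(all(diff(sizes) <= 0))
  sizes_p <- sapply(c(0.2, 0.05, 0.01, 0.001), function(p) {
    s <- call_sdtgs(ct, de_thresholds(p_adj_max = p))
    length(s$up) + length(s$down)
  })
  expect_true(all(diff(sizes_p) <= 0))
  # nothing survives p_adj = 1 everywhere
  ct2 <- ct
  ct2$p_adj <- rep(1, nrow(ct2))
  s <- call_sdtgs(ct2)
  expect_length(c(s$up, s$down), 0)
})

test_that("the top-gene FC threshold keeps exactly the published 1 Gy / 2 h genes", {
  tab <- read.delim(extdata("top_unique_fc_1gy_2h.tsv"))
  rows <- fc_rows(tab)
  top <- call_sdtgs(rows, de_thresholds(fc_min = 3.5))
  expect_setequal(c(top$up, top$down), c("TRIM63", "MYLK4", "MSTN", "KRT31"))
  expect_setequal(top$up, c("TRIM63", "MYLK4", "MSTN"))
  expect_equal(top$down, "KRT31")
})

test_that("a missing exposure group yields an explicit group-absent result", {
  sim <- simulate_experiment(sim_config_preset(seed = 36, n_genes = 1200))
  res <- moderated_t_contrast(sim$expr, 20, "d21")
  expect_s3_class(res, "group_absent")
  expect_match(res$reason, "absent")
  de <- de_all_contrasts(sim$expr)
  expect_s3_class(de$contrasts[["20|d21"]], "group_absent")
  expect_false("20|d21" %in% names(de$sets))
})

test_that("probe collapsing keeps the probe with the largest |t| per gene", {
  rows <- fc_rows(data.frame(gene = c("p1", "p2", "p3", "p4"),
                             fc = c(2, -3, 4, 2.5)))
  rows$t_mod <- c(3, -8, 5, 4)
  map <- c(p1 = "GENEA", p2 = "GENEA", p3 = "GENEB", p4 = "GENEB")
  out <- collapse_probes(rows, map)
  expect_equal(nrow(out), 2)
  expect_setequal(out$gene, c("GENEA", "GENEB"))
  expect_equal(out$t_mod[out$gene == "GENEA"], -8)
  expect_equal(out$t_mod[out$gene == "GENEB"], 5)
  expect_error(collapse_probes(rows, map[-1]), class = "radskin_data_error")
})
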