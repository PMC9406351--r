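# Shared fixtures, all built in code.

extdata <- function(name) {
  system.file("extdata", name, package = "radskin", mustWork = TRUE)
}

# Build SDTG sets realizing a Venn skeleton over `labels`: a common block,
# per-label unique blocks, and the remainder of the union spread over
# consecutive-label pair blocks. Gene ids are synthetic. All genes are filed
# as upregulated unless up_fraction is given.
venn_sets <- function(labels, union, common, unique_counts, dose_gy = 1,
                      up_fraction = 1, prefix = "v") {
  stopifnot(length(unique_counts) == length(labels))
  rest <- union - common - sum(unique_counts)
  stopifnot(rest >= 0)
  npair <- length(labels) - 1
  pair <- rep(rest %/% npair, npair)
  if (rest %% npair) pair[seq_len(rest %% npair)] <- pair[seq_len(rest %% npair)] + 1
  ids <- paste0(prefix, seq_len(union))
  ptr <- 0
  take <- function(k) {
    if (k == 0) return(character(0))
    out <- ids[(ptr + 1):(ptr + k)]; ptr <<- ptr + k; out
  }
  common_ids <- take(common)
  uniq_ids <- lapply(unique_counts, take)
  pair_ids <- lapply(pair, take)
  sets <- list()
  for (i in seq_along(labels)) {
    g <- c(common_ids, uniq_ids[[i]],
           if (i > 1) pair_ids[[i - 1]] else character(0),
           if (i <= npair) pair_ids[[i]] else character(0))
    n_up <- round(up_fraction * length(g))
    sets[[i]] <- sdtg_set(dose_gy = dose_gy, timepoint = if (labels[i] %in%
        c("2h", "d4", "d7", "d21", "d28")) labels[i] else "2h",
      up = g[seq_len(n_up)], down = g[setdiff(seq_along(g), seq_len(n_up))])
    attr(sets[[i]], "label") <- labels[i]
  }
  names(sets) <- labels
  sets
}

# Independent brute-force Venn oracle: per-gene membership loop using
# setdiff/intersect primitives only.
brute_partition <- function(gene_lists) {
  labs <- names(gene_lists)
  universe <- unique(unlist(gene_lists))
  uniq <- setNames(integer(length(labs)), labs)
  common <- 0L
  blocks <- list()
  for (g in universe) {
    members <- labs[vapply(gene_lists, function(s) g %in% s, TRUE)]
    key <- paste(members, collapse = "+")
    blocks[[key]] <- c(blocks[[key]], g)
    if (length(members) == 1) uniq[members] <- uniq[members] + 1L
    if (length(members) == length(labs)) common <- common + 1L
  }
  list(union = length(universe), unique = uniq, common = common,
       block_sizes = vapply(blocks, length, integer(1)))
}

# Small simulation config for unit tests: two doses, three time points.
small_config <- function(seed = 1, n_genes = 400, n_up_frac = 0.8,
                         lfc_range = c(1.5, 3), s0_sq = 0.0625,
                         plant_markers = FALSE) {
  venn <- list(
    "1"  = list(union = 40, common = 2, unique = c(10, 12, 6)),
    "20" = list(union = 60, common = 30, unique = c(6, 8, 6))
  )
  up <- rbind("1" = rep(n_up_frac, 3), "20" = rep(1 - n_up_frac, 3))
  colnames(up) <- c("2h", "d4", "d7")
  sim_config(n_genes = n_genes, n_replicates = 5, doses = c(1, 20),
             lethal_dose = 20, timepoints = c("2h", "d4", "d7"),
             venn = venn, up_fraction = up, lfc_range = lfc_range,
             variance_prior = c(d0 = 4, s0_sq = s0_sq),
             plant_markers = plant_markers, seed = seed)
}

# Contrast-row table for threshold tests, built from a gene/fc table; p-values
# are set below the significance level (the source lists only significant
# genes).
fc_rows <- function(df, dose_gy = 1, timepoint = "2h") {
  lfc <- sign(df$fc) * log2(abs(df$fc))
  structure(data.frame(gene = df$gene, log2fc = lfc, fc = df$fc,
                       t_mod = sign(lfc) * 10, p_raw = 1e-4, p_adj = 1e-3,
                       direction = ifelse(lfc >= 0, "up", "down"),
                       is_sdtg = TRUE),
            class = c("radskin_contrasts", "data.frame"),
            dose_gy = dose_gy, timepoint = timepoint, control_dose = 0)
}

read_panel_fc <- function() {
  tab <- read.delim(extdata("marker_panel_fc.tsv"), check.names = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$gene
  m
}

# Expected percentage at the precision a reference table prints it, allowing
# one unit in the last printed digit (printed tables mix half-up rounding and
# truncation).
expect_printed_pct <- function(computed, printed) {
  digits <- nchar(sub("^[^.]*\\.?", "", as.character(printed)))
  tol <- 10^(-digits) + 1e-9
  expect_lte(abs(computed - printed), tol,
             label = sprintf("|%.4f - %s|", computed, printed))
}

# Preset architecture scaled down proportionally for fast end-to-end tests.
scaled_preset <- function(seed = 1, scale = 0.1) {
  full <- list(
    "1"  = list(common = 1,   unique = c(125, 101, 26, 51, 62), union = 619),
    "3"  = list(common = 0,   unique = c(61, 35, 20, 99, 82), union = 411),
    "6"  = list(common = 4,   unique = c(47, 84, 173, 52, 88), union = 765),
    "20" = list(common = 609, unique = c(57, 80, 89), union = 1038))
  venn <- lapply(full, function(v) {
    common <- round(v$common * scale)
    u <- round(v$unique * scale)
    rest <- round((v$union - v$common - sum(v$unique)) * scale)
    list(union = common + sum(u) + rest, common = common, unique = u)
  })
  up <- rbind("1" = c(0.70, 0.80, 0.60, 0.40, 0.35),
              "3" = c(0.65, 0.80, 0.60, 0.30, 0.30),
              "6" = c(0.60, 0.65, 0.75, 0.40, 0.35),
              "20" = c(0.10, 0.10, 0.10, NA, NA))
  colnames(up) <- c("2h", "d4", "d7", "d21", "d28")
  sim_config(n_genes = round(20000 * scale), venn = venn, up_fraction = up,
             seed = seed)
}
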