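#' Expression matrix with sample metadata
#'
#' Container for a probes x samples log2 expression matrix plus the per-sample
#' annotation (dose in Gy, time point, replicate) that the whole pipeline keys
#' on. Column order of `values` and row order of `meta` must agree.
#'
#' @param values numeric matrix, probes in rows, samples in columns; rownames
#'   are probe ids, colnames are sample ids.
#' @param meta data.frame with columns `sample`, `dose_gy`, `timepoint`,
#'   `replicate`; one row per column of `values`.
#' @return an object of class `radskin_expr`.
#' @export
expression_matrix <- function(values, meta) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_data("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values))) stop_data("'values' must have probe ids as rownames")
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stop_data("duplicated probe id: ", dup)
  }
  need <- c("sample", "dose_gy", "timepoint", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop_data("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(meta) != ncol(values)) {
    stop_data("metadata has ", nrow(meta), " rows but matrix has ", ncol(values), " samples")
  }
  if (is.null(colnames(values))) colnames(values) <- meta$sample
  if (!identical(as.character(colnames(values)), as.character(meta$sample))) {
    m <- match(colnames(values), meta$sample)
    if (anyNA(m)) {
      stop_data("sample id(s) in matrix not found in metadata: ",
                paste(colnames(values)[is.na(m)], collapse = ", "))
    }
    meta <- meta[m, , drop = FALSE]
  }
  meta$timepoint <- as.character(meta$timepoint)
  meta$dose_gy <- as.numeric(meta$dose_gy)
  meta$group <- paste0(meta$dose_gy, "Gy_", meta$timepoint)
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "radskin_expr")
}

#' @export
print.radskin_expr <- function(x, ...) {
  cat("radskin expression matrix: ", nrow(x$values), " probes x ",
      ncol(x$values), " samples\n", sep = "")
  grp <- table(x$meta$dose_gy, x$meta$timepoint)
  cat("samples per (dose Gy, time point):\n")
  print(grp)
  invisible(x)
}

#' @export
dim.radskin_expr <- function(x) dim(x$values)

## Column subset keeping values/meta aligned.
subset_samples <- function(x, keep) {
  expression_matrix(x$values[, keep, drop = FALSE], x$meta[keep, , drop = FALSE])
}

## Column indices of one (dose, timepoint) group.
group_index <- function(x, dose_gy, timepoint) {
  which(x$meta$dose_gy == dose_gy & x$meta$timepoint == timepoint)
}

#' Write / read an expression matrix as TSV
#'
#' The canonical on-disk form is a pair of TSV files: the matrix (first column
#' `probe_id`, remaining columns one per sample) and the sample metadata
#' (`sample`, `dose_gy`, `timepoint`, `replicate`).
#'
#' @param x a `radskin_expr` object.
#' @param path path of the matrix TSV.
#' @param meta_path path of the metadata TSV.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns a `radskin_expr`.
#' @export
write_expression_tsv <- function(x, path, meta_path) {
  df <- data.frame(probe_id = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$meta[c("sample", "dose_gy", "timepoint", "replicate")],
                     meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, meta_path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  if (names(df)[1] != "probe_id") stop_data("first column of ", path, " must be 'probe_id'")
  if (anyDuplicated(df$probe_id)) {
    dup <- df$probe_id[duplicated(df$probe_id)][1]
    stop_data("duplicated probe id in ", path, ": ", dup)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop_data("non-numeric expression values in ", path)
  rownames(vals) <- df$probe_id
  meta <- utils::read.delim(meta_path, check.names = FALSE)
  expression_matrix(vals, meta)
}

#' Read a GEO series-matrix file
#'
#' Convenience reader for the series-matrix export format used by the Gene
#' Expression Omnibus: `!`-prefixed header lines followed by a tab-separated
#' expression table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`. Sample titles and characteristics lines are
#' kept as metadata columns; dose/time annotation must be supplied or parsed
#' downstream by the caller since submitters encode it freely.
#'
#' @param path path to an (uncompressed) series-matrix text file.
#' @return list with `values` (numeric matrix) and `header` (data.frame of
#'   per-sample header fields).
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg) {
    stop_data("no series-matrix table delimiters found in ", path)
  }
  tab <- utils::read.delim(text = lines[(beg + 1):(end - 1)], check.names = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- as.character(tab[[1]])
  if (anyDuplicated(rownames(vals))) {
    stop_data("duplicated probe id in ", path, ": ",
              rownames(vals)[duplicated(rownames(vals))][1])
  }
  hdr_lines <- grep("^!Sample_", lines[seq_len(beg - 1)], value = TRUE)
  hdr <- list()
  for (ln in hdr_lines) {
    parts <- strsplit(ln, "\t")[[1]]
    key <- sub("^!Sample_", "", parts[1])
    val <- gsub('^"|"$', "", parts[-1])
    if (length(val) == ncol(vals)) {
      nm <- key
      i <- 1
      while (nm %in% names(hdr)) { i <- i + 1; nm <- paste0(key, ".", i) }
      hdr[[nm]] <- val
    }
  }
  list(values = vals, header = as.data.frame(hdr, optional = TRUE))
}
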