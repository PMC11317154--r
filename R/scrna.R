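#' Construct a single-cell expression dataset
#'
#' Wraps a non-negative genes x cells expression matrix together with the
#' binary cell grouping used for specificity scoring: group1 holds the
#' established ciliated cells, group2 everything else.
#'
#' @param mat Numeric genes x cells matrix (counts or normalized values),
#'   with gene row names and cell column names.
#' @param groups Named character vector or 2-column data frame (cell, group)
#'   assigning every cell to "group1" or "group2".
#' @param tag Dataset tag (free text, used in reports).
#' @param log_transform Use the skew-correcting log variant when scoring
#'   (the mode used for C. elegans data, where raw percentage differences
#'   are small).
#' @return Object of class `expression_dataset`.
#' @export
expression_dataset <- function(mat, groups, tag = "dataset",
                               log_transform = FALSE) {
  mat <- as.matrix(mat)
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)),
            all(mat >= 0))
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups[[2]]), groups[[1]])
  }
  missing_cells <- setdiff(colnames(mat), names(groups))
  if (length(missing_cells) > 0L) {
    stop("cells without a group assignment: ",
         paste(utils::head(missing_cells, 5), collapse = ", "))
  }
  groups <- groups[colnames(mat)]
  if (!all(groups %in% c("group1", "group2"))) {
    stop("cell groups must be 'group1' (ciliated) or 'group2' (other)")
  }
  if (!all(c("group1", "group2") %in% groups)) {
    stop("both cell groups must be non-empty")
  }
  structure(list(mat = mat, groups = groups, tag = tag,
                 log_transform = isTRUE(log_transform)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression dataset '%s': %d genes x %d cells (%d ciliated)\n",
              x$tag, nrow(x$mat), ncol(x$mat), sum(x$groups == "group1")))
  invisible(x)
}

#' Read a cell-group assignment file
#'
#' @param path 2-column TSV (cell id, group1|group2).
#' @param header Skip the first line when TRUE.
#' @return Named character vector cell -> group.
#' @export
read_cell_groups <- function(path, header = FALSE) {
  df <- read_tsv_cols(path, 2L, c("cell", "group"), header = header)
  stats::setNames(df$group, df$cell)
}

#' Read a genes x cells expression matrix
#'
#' Dense TSV (first column gene names, header row of cell names) or
#' MatrixMarket `.mtx` with `<stem>_genes.txt` / `<stem>_cells.txt`
#' sidecar files.
#'
#' @param path Path to the matrix file.
#' @return Numeric matrix with gene row names and cell column names.
#' @export
read_expression_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, "_genes.txt"), warn = FALSE)
    colnames(m) <- readLines(paste0(stem, "_cells.txt"), warn = FALSE)
    return(m)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Fraction of a cell group expressing each gene
#'
#' A cell expresses a gene when its matrix value is strictly positive.
#'
#' @param ds An [expression_dataset()].
#' @param group `"group1"` (ciliated) or `"group2"` (other).
#' @return Named numeric vector gene -> fraction in [0, 1].
#' @export
pct_expressing <- function(ds, group = c("group1", "group2")) {
  group <- match.arg(group)
  cols <- ds$groups == group
  if (!any(cols)) stop("group '", group, "' is empty")
  rowMeans(ds$mat[, cols, drop = FALSE] > 0)
}

#' Ciliated-cell expression specificity scores
#'
#' For each gene the raw score is the difference between the fraction of
#' ciliated cells (group1) expressing it and the fraction of other cells
#' (group2) expressing it, so genes expressed exclusively in ciliated cells
#' score highest. In the log variant (used where raw differences are small
#' and the distribution is skewed) negative differences are clipped to 0 and
#' the remainder mapped through log(1+x) before normalization. Normalized
#' scores are min-max over the dataset's genes.
#'
#' @param ds An [expression_dataset()].
#' @param log_transform Override the dataset's log flag.
#' @return Tibble with columns `gene`, `raw`, `normalized` and attribute
#'   `tag`.
#' @export
diff_score <- function(ds, log_transform = ds$log_transform) {
  p1 <- pct_expressing(ds, "group1")
  p2 <- pct_expressing(ds, "group2")
  raw <- p1 - p2
  transformed <- if (isTRUE(log_transform)) log1p(pmax(raw, 0)) else raw
  out <- tibble::tibble(gene = rownames(ds$mat), raw = unname(raw),
                        normalized = minmax_normalize(unname(transformed)))
  attr(out, "tag") <- ds$tag
  out
}

#' Combine specificity scores across datasets
#'
#' `mean` mode averages the normalized scores, with genes missing from a
#' dataset contributing 0 there; `intersection-count` mode reports the
#' fraction of datasets in which the gene exceeds a candidate threshold,
#' rewarding genes recovered independently in several datasets.
#'
#' @param score_list List of tibbles from [diff_score()] (genes already
#'   harmonized to human symbols).
#' @param mode `"mean"` or `"intersection-count"`.
#' @param threshold Normalized-score cutoff defining a candidate in
#'   intersection-count mode (default 0.5).
#' @return Tibble with columns `gene` and `score` in [0, 1].
#' @export
combine_datasets <- function(score_list, mode = c("mean", "intersection-count"),
                             threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(length(score_list) >= 1L)
  genes <- sort(unique(unlist(lapply(score_list, `[[`, "gene"))))
  acc <- matrix(0, nrow = length(genes), ncol = length(score_list),
                dimnames = list(genes, NULL))
  for (i in seq_along(score_list)) {
    s <- score_list[[i]]
    acc[s$gene, i] <- s$normalized
  }
  score <- if (mode == "mean") rowMeans(acc) else rowMeans(acc >= threshold)
  tibble::tibble(gene = genes, score = unname(score))
}

#' Single-cell specificity score across one or more datasets
#'
#' Scores each dataset with [diff_score()], harmonizes gene symbols to the
#' human namespace where an ortholog map is supplied, and combines datasets
#' with [combine_datasets()].
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param maps Optional list (parallel to `datasets`) of ortholog maps for
#'   non-human datasets; NULL entries mean the genes are already human
#'   symbols.
#' @param mode,threshold Passed to [combine_datasets()].
#' @return Tibble with columns `gene` and `score`.
#' @export
score_scrna <- function(datasets, maps = NULL,
                        mode = "mean", threshold = 0.5) {
  scored <- lapply(seq_along(datasets), function(i) {
    s <- diff_score(datasets[[i]])
    map <- if (!is.null(maps)) maps[[i]] else NULL
    if (!is.null(map)) {
      targets <- harmonize_each(s$gene, map)
      n <- lengths(targets)
      s <- tibble::tibble(gene = unlist(targets),
                          raw = rep(s$raw, n),
                          normalized = rep(s$normalized, n))
      # a human gene hit by several source genes keeps its best evidence
      s <- dplyr::summarise(dplyr::group_by(s, gene),
                            raw = max(raw), normalized = max(normalized),
                            .groups = "drop")
    } else {
      s$gene <- as_symbol(s$gene)
    }
    s
  })
  combine_datasets(scored, mode = mode, threshold = threshold)
}
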