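#' Read BLAST tabular hits
#'
#' Reads an outfmt-6-style TSV with columns query, subject, organism,
#' bit score and P-value (column order configurable via `col_order`, which
#' names the positions of those five fields in the file).
#'
#' @param path Path to the hits TSV.
#' @param col_order Integer vector of length 5 giving the file columns that
#'   hold query, subject, organism, bit_score, p_value respectively.
#' @param header Skip the first line when TRUE.
#' @return Tibble with columns `query`, `subject`, `organism`, `bit_score`,
#'   `p_value`.
#' @export
read_blast_hits <- function(path, col_order = 1:5, header = FALSE) {
  stopifnot(length(col_order) == 5L)
  raw <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < max(col_order)) {
    stop("hits file has ", ncol(raw), " columns; col_order needs ", max(col_order))
  }
  tibble::tibble(
    query     = as_symbol(raw[[col_order[1]]]),
    subject   = as.character(raw[[col_order[2]]]),
    organism  = as.character(raw[[col_order[3]]]),
    bit_score = as.numeric(raw[[col_order[4]]]),
    p_value   = as.numeric(raw[[col_order[5]]])
  )
}

#' Filter BLAST hits on bit score and P-value
#'
#' Hits with bit score lower than `bit_min` or P-value higher than `p_max`
#' are removed; hits exactly at either threshold are kept.
#'
#' @param hits Tibble from [read_blast_hits()].
#' @param bit_min Minimum bit score retained (default 50).
#' @param p_max Maximum P-value retained (default 0.001).
#' @return The filtered tibble.
#' @export
filter_blast_hits <- function(hits, bit_min = 50, p_max = 0.001) {
  stopifnot(bit_min > 0, p_max > 0)
  hits[hits$bit_score >= bit_min & hits$p_value <= p_max, , drop = FALSE]
}

#' Keep the single best hit per (query, organism)
#'
#' For every query gene and organism, keeps the hit with the highest bit
#' score; ties are broken by the lexicographically smallest subject token so
#' the result is deterministic.
#'
#' @param hits Filtered hits tibble.
#' @return Tibble with one row per (query, organism) pair.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query, hits$organism, -hits$bit_score, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits[c("query", "organism")]), , drop = FALSE]
}

#' Read the organism panel
#'
#' @param path 2-column TSV: organism tag, ciliated flag (1/0, TRUE/FALSE,
#'   yes/no).
#' @param header Skip the first line when TRUE.
#' @return Tibble with columns `organism` and `ciliated` (logical).
#' @export
read_organism_panel <- function(path, header = FALSE) {
  panel <- read_tsv_cols(path, 2L, c("organism", "ciliated"), header = header)
  flag <- tolower(trimws(panel$ciliated))
  panel$ciliated <- flag %in% c("1", "true", "yes", "t")
  panel
}

#' Build a binary ortholog presence/absence matrix
#'
#' Cell (gene, organism) is 1 when a best hit exists for that pair. Genes
#' and organisms absent from the hit map get all-zero rows/columns.
#'
#' @param best Best-hit tibble from [best_hits()].
#' @param genes Character vector of gene symbols (matrix row order).
#' @param organisms Character vector of organism tags (column order).
#' @param ciliated Logical vector flagging each organism as ciliated.
#' @return Object of class `presence_matrix`: a list with the binary `cells`
#'   matrix (genes x organisms) and the `ciliated` flags.
#' @export
build_presence_matrix <- function(best, genes, organisms, ciliated) {
  genes <- as_symbol(genes)
  stopifnot(length(genes) > 0L, length(organisms) > 1L,
            length(ciliated) == length(organisms))
  unknown <- setdiff(unique(best$organism), organisms)
  if (length(unknown) > 0L) {
    stop("hits reference organisms outside the panel: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  cells <- matrix(0L, nrow = length(genes), ncol = length(organisms),
                  dimnames = list(genes, organisms))
  keep <- best$query %in% genes
  if (any(keep)) cells[cbind(best$query[keep], best$organism[keep])] <- 1L
  structure(list(cells = cells, ciliated = as.logical(ciliated)),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence matrix: %d genes x %d organisms (%d ciliated)\n",
              nrow(x$cells), ncol(x$cells), sum(x$ciliated)))
  invisible(x)
}

#' Gower dissimilarity between binary phylogenetic profiles
#'
#' On symmetric binary variables the Gower coefficient reduces to the
#' fraction of organisms in which two profiles disagree (Hamming distance
#' divided by the number of organisms).
#'
#' @param m A `presence_matrix` or a binary genes x organisms matrix.
#' @return Symmetric genes x genes matrix with values in [0, 1] and zero
#'   diagonal.
#' @export
gower_dissimilarity <- function(m) {
  cells <- if (inherits(m, "presence_matrix")) m$cells else as.matrix(m)
  if (nrow(cells) < 2L) stop("need at least 2 genes to compute dissimilarities")
  stopifnot(all(cells %in% c(0, 1)))
  d <- as.matrix(stats::dist(cells, method = "manhattan")) / ncol(cells)
  dimnames(d) <- list(rownames(cells), rownames(cells))
  d
}

#' Hierarchically cluster phylogenetic profiles
#'
#' Agglomerative clustering on a precomputed dissimilarity matrix, with the
#' tree cut into exactly `k` groups.
#'
#' @param d Symmetric dissimilarity matrix (genes x genes).
#' @param k Number of clusters (default 40).
#' @param linkage Agglomeration rule, `"complete"` or `"average"`.
#' @return Tibble with columns `gene` and `cluster` (ids in 1..k), plus an
#'   attribute `k`.
#' @export
cluster_profiles <- function(d, k = 40, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  n <- nrow(d)
  if (k > n) stop("k (", k, ") exceeds the number of genes (", n, ")")
  tree <- stats::hclust(stats::as.dist(d), method = linkage)
  assignment <- stats::cutree(tree, k = k)
  out <- tibble::tibble(gene = rownames(d), cluster = as.integer(assignment))
  attr(out, "k") <- as.integer(k)
  out
}

#' Flag ciliary clusters and assign the binary phylogenetic score
#'
#' Each cluster is scored by its fraction of members in the positive
#' (gold-standard ciliary) set. By default a cluster is flagged when that
#' fraction is at least `min_fold` times the background positive fraction
#' and the cluster has at least 2 members; alternatively `top_clusters`
#' forces exactly the highest-fraction clusters to be flagged. Genes in
#' flagged clusters score 1, all other genes 0.
#'
#' @param assignment Tibble from [cluster_profiles()].
#' @param labels A [labeled_gene_sets()] object (only positives are used).
#' @param min_fold Enrichment multiple over the background fraction
#'   required to flag a cluster (default 5).
#' @param top_clusters When non-NULL, flag exactly this many
#'   highest-fraction clusters instead of using `min_fold` (clusters with no
#'   positive member are never flagged).
#' @return List with `scores` (tibble: gene, cluster, cluster_fraction,
#'   phylo_score), `flagged` (flagged cluster ids) and `fractions`
#'   (per-cluster positive fraction).
#' @export
flag_ciliary_clusters <- function(assignment, labels, min_fold = 5,
                                  top_clusters = NULL) {
  stopifnot(inherits(labels, "labeled_gene_sets"))
  genes <- assignment$gene
  is_pos <- genes %in% labels$positives
  sizes <- c(tapply(rep(1L, length(genes)), assignment$cluster, sum))
  pos_counts <- c(tapply(as.integer(is_pos), assignment$cluster, sum))
  fractions <- pos_counts / sizes
  background <- mean(is_pos)
  if (!is.null(top_clusters)) {
    eligible <- names(fractions)[fractions > 0]
    ord <- eligible[order(-fractions[eligible], as.integer(eligible))]
    flagged <- as.integer(utils::head(ord, top_clusters))
  } else {
    flagged <- as.integer(names(fractions)[
      fractions >= min_fold * background & sizes >= 2 & fractions > 0])
  }
  if (length(flagged) == 0L) {
    warning("no cluster met the ciliary flagging rule; all phylogenetic scores are 0")
  }
  scores <- tibble::tibble(
    gene = genes,
    cluster = assignment$cluster,
    cluster_fraction = unname(fractions[as.character(assignment$cluster)]),
    phylo_score = as.integer(assignment$cluster %in% flagged)
  )
  list(scores = scores, flagged = flagged, fractions = fractions)
}

#' Phylogenetic-profile score from BLAST hits
#'
#' End-to-end wrapper: filter hits, keep best hits, build the presence
#' matrix, compute Gower dissimilarities, cluster, and flag ciliary
#' clusters.
#'
#' @param hits Tibble from [read_blast_hits()].
#' @param genes Gene universe (rows of the presence matrix).
#' @param panel Organism panel tibble (`organism`, `ciliated`).
#' @param labels [labeled_gene_sets()] used for cluster flagging.
#' @param bit_min,p_max Hit filters (see [filter_blast_hits()]).
#' @param k,linkage Clustering parameters (see [cluster_profiles()]).
#' @param min_fold,top_clusters Flagging rule (see
#'   [flag_ciliary_clusters()]).
#' @return Tibble with columns `gene` and `score` (0/1).
#' @export
score_phylo <- function(hits, genes, panel, labels, bit_min = 50,
                        p_max = 0.001, k = 40,
                        linkage = "complete", min_fold = 5,
                        top_clusters = NULL) {
  kept <- best_hits(filter_blast_hits(hits, bit_min, p_max))
  pm <- build_presence_matrix(kept, genes, panel$organism, panel$ciliated)
  d <- gower_dissimilarity(pm)
  assignment <- cluster_profiles(d, k = min(k, nrow(d)), linkage = linkage)
  flagged <- flag_ciliary_clusters(assignment, labels, min_fold = min_fold,
                                   top_clusters = top_clusters)
  tibble::tibble(gene = flagged$scores$gene,
                 score = as.numeric(flagged$scores$phylo_score))
}
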