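#' Default ciliary transcription-factor panel
#'
#' Transcription factors with established roles in ciliogenesis whose
#' target sets supply the regulatory-network evidence. FOXJ1 targets are
#' counted by binding occurrence; the others by the number of organisms in
#' which the regulation is observed.
#'
#' @return Character vector of TF names.
#' @export
default_tf_panel <- function() {
  c("RFX2", "RFX3", "MYB", "GLIS3", "JAZF1", "SOX5", "TOX", "FOXJ1")
}

#' Read TF-target regulation records
#'
#' @param path 3-column TSV: TF, target gene, support tag (organism name
#'   for most TFs, occurrence index for FOXJ1).
#' @param header Skip the first line when TRUE.
#' @return Tibble with columns `tf`, `target`, `support`.
#' @export
read_regulome <- function(path, header = FALSE) {
  df <- read_tsv_cols(path, 3L, c("tf", "target", "support"), header = header)
  df$tf <- as_symbol(df$tf)
  df$target <- as_symbol(df$target)
  df
}

#' Per-gene, per-TF regulatory support counts
#'
#' For every TF except FOXJ1 the count is the number of distinct organisms
#' in which the TF is seen to bind the gene; for FOXJ1, which may bind
#' several sites in one gene, the count is the number of binding
#' occurrences (records), duplicates included.
#'
#' @param records Tibble from [read_regulome()].
#' @param panel Allowed TF names (default [default_tf_panel()]).
#' @param map Optional ortholog map for non-human target tokens.
#' @return Tibble with one row per gene: a `gene` column, one count column
#'   per panel TF, and `n_tfs` (number of TFs with a positive count).
#' @export
tf_counts <- function(records, panel = default_tf_panel(), map = NULL) {
  unknown <- setdiff(unique(records$tf), panel)
  if (length(unknown) > 0L) {
    stop("unknown TF(s) ", paste(unknown, collapse = ", "),
         "; configured panel: ", paste(panel, collapse = ", "))
  }
  if (!is.null(map)) {
    targets <- harmonize_each(records$target, map)
    n <- lengths(targets)
    records <- tibble::tibble(tf = rep(records$tf, n),
                              target = unlist(targets),
                              support = rep(records$support, n))
  }
  genes <- sort(unique(records$target))
  counts <- matrix(0L, nrow = length(genes), ncol = length(panel),
                   dimnames = list(genes, panel))
  for (tf in unique(records$tf)) {
    sub <- records[records$tf == tf, , drop = FALSE]
    n <- if (tf == "FOXJ1") {
      table(sub$target)
    } else {
      table(unique(sub[c("target", "support")])$target)
    }
    counts[names(n), tf] <- as.integer(n)
  }
  out <- tibble::as_tibble(as.data.frame(counts))
  out <- tibble::add_column(out, gene = genes, .before = 1)
  out$n_tfs <- unname(rowSums(counts > 0))
  out
}

#' Regulatory-network (motif) score per gene
#'
#' Each TF's count c is mapped through log(1 + c), the per-TF values are
#' summed, and the motif score is log(1 + sum) (natural logs throughout).
#' The score is 0 exactly when no panel TF supports the gene.
#'
#' @param counts Tibble from [tf_counts()].
#' @return `counts` with an added `motif_score` column.
#' @export
tf_score <- function(counts) {
  tf_cols <- setdiff(names(counts), c("gene", "n_tfs", "motif_score"))
  per_tf <- log1p(as.matrix(counts[tf_cols]))
  counts$motif_score <- log1p(rowSums(per_tf))
  counts
}

#' Genes regulated by at least k panel TFs
#'
#' High-confidence targets supported by several independent ciliary TFs.
#'
#' @param counts Tibble from [tf_counts()].
#' @param k Minimum number of supporting TFs (default 3).
#' @return Character vector of gene symbols.
#' @export
regulated_by_at_least <- function(counts, k = 3) {
  stopifnot(k >= 1)
  counts$gene[counts$n_tfs >= k]
}

#' TF-network score from a regulome file
#'
#' @param path Regulome TSV (see [read_regulome()]).
#' @param panel TF panel.
#' @param map Optional ortholog map for target genes.
#' @param genes Optional gene universe; genes without records score 0.
#' @return Tibble with columns `gene` and `score` (motif score, >= 0).
#' @export
score_tfnet <- function(path, panel = default_tf_panel(), map = NULL,
                        genes = NULL) {
  scored <- tf_score(tf_counts(read_regulome(path), panel = panel, map = map))
  out <- tibble::tibble(gene = scored$gene, score = scored$motif_score)
  if (!is.null(genes)) {
    genes <- as_symbol(genes)
    full <- tibble::tibble(gene = genes, score = 0)
    idx <- match(out$gene, genes)
    full$score[idx[!is.na(idx)]] <- out$score[!is.na(idx)]
    out <- full
  }
  out
}
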