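#' Read per-gene free-text annotation entries
#'
#' @param path 2-column TSV (gene, text), one entry per row; a gene may
#'   have several entries.
#' @param header Skip the first line when TRUE.
#' @return Tibble with columns `gene` and `text`.
#' @export
read_annotations <- function(path, header = FALSE) {
  df <- read_tsv_cols(path, 2L, c("gene", "text"), header = header)
  df$gene <- as_symbol(df$gene)
  df <- df[nzchar(trimws(df$text)), , drop = FALSE]
  df
}

# case-insensitive whole-word match; `prefix` also matches longer words
# sharing the stem (stain -> staining, stained)
has_word <- function(text, word, prefix = FALSE) {
  pattern <- if (prefix) paste0("\\b", word) else paste0("\\b", word, "\\b")
  grepl(pattern, text, ignore.case = TRUE, perl = TRUE)
}

#' Keyword score of one annotation entry
#'
#' Ciliary vocabulary is weighted by how specifically it indicates ciliary
#' localization: "centrosome" contributes 0.25, "flagellum"/"flagella" 1,
#' and "cilia"/"cilium" contributes 1 when accompanied in the same entry by
#' "positivity" or a "stain" word (localization evidence) and 0.5 otherwise
#' (expression only). Contributions are summed within the entry; matching
#' is case-insensitive and whole-word, with "stain" matched as a prefix.
#'
#' @param text Character vector of entry texts.
#' @return Numeric vector of entry scores (>= 0).
#' @export
entry_raw_score <- function(text) {
  centrosome <- has_word(text, "centrosome")
  flagellum <- has_word(text, "flagellum") | has_word(text, "flagella")
  cilia <- has_word(text, "cilia") | has_word(text, "cilium")
  localization <- has_word(text, "positivity") | has_word(text, "stain", prefix = TRUE)
  0.25 * centrosome + 1 * flagellum +
    ifelse(cilia, ifelse(localization, 1, 0.5), 0)
}

#' Text-mining scores per gene
#'
#' Sums entry scores over each gene's annotation entries and min-max
#' normalizes the totals across genes.
#'
#' @param annotations Tibble from [read_annotations()].
#' @param genes Optional gene universe; genes without entries get raw 0.
#' @return Tibble with columns `gene`, `raw`, `normalized`.
#' @export
gene_text_scores <- function(annotations, genes = NULL) {
  entry <- entry_raw_score(annotations$text)
  raw_tab <- tapply(entry, annotations$gene, sum)
  if (is.null(genes)) genes <- sort(names(raw_tab))
  genes <- as_symbol(genes)
  raw <- stats::setNames(rep(0, length(genes)), genes)
  hit <- intersect(genes, names(raw_tab))
  raw[hit] <- raw_tab[hit]
  normalized <- if (length(raw) == 1L) 0 else minmax_normalize(unname(raw))
  tibble::tibble(gene = genes, raw = unname(raw), normalized = normalized)
}

#' Text-mining score from an annotation file
#'
#' @param path Annotation TSV (see [read_annotations()]).
#' @param genes Optional gene universe.
#' @return Tibble with columns `gene` and `score` (normalized, in [0, 1]).
#' @export
score_textmine <- function(path, genes = NULL) {
  scored <- gene_text_scores(read_annotations(path), genes = genes)
  tibble::tibble(gene = scored$gene, score = scored$normalized)
}
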