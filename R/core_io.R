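#' Read a gene list file
#'
#' One symbol per line; lines starting with '#' are comments. Symbols are
#' uppercased and de-duplicated, so the result is a set (order carries no
#' meaning).
#'
#' @param path Path to a plain-text gene list.
#' @return Character vector of unique uppercase gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty gene list: ", path)
  unique(as_symbol(lines))
}

#' Write a gene list file
#'
#' @param genes Character vector of gene symbols.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(unique(as_symbol(genes)), path)
  invisible(path)
}

#' Read an ortholog map
#'
#' Two-column TSV mapping source-organism gene tokens to human gene symbols.
#' A source token may map to several human genes (many-to-many maps are
#' legitimate after gene duplications); identical duplicate rows are
#' collapsed.
#'
#' @param path Path to a 2-column TSV (source, human symbol).
#' @param header Skip the first line when TRUE.
#' @return A tibble with columns `source` and `target` (uppercase symbols).
#' @export
read_ortholog_map <- function(path, header = FALSE) {
  map <- read_tsv_cols(path, 2L, c("source", "target"), header = header)
  map$source <- trimws(map$source)
  map$target <- as_symbol(map$target)
  dplyr::distinct(map)
}

#' Map gene tokens into the human symbol namespace
#'
#' Every token with at least one entry in the map contributes all of its
#' mapped human symbols (evidence fans out to every target of a one-to-many
#' mapping); tokens absent from the map are dropped and counted. With
#' `map = NULL` tokens are taken to already be human symbols and are simply
#' uppercased.
#'
#' @param tokens Character vector of source gene tokens.
#' @param map Ortholog map from [read_ortholog_map()], or NULL.
#' @return List with `symbols` (unique human symbols) and `dropped`
#'   (number of unmapped tokens).
#' @export
harmonize <- function(tokens, map = NULL) {
  tokens <- unique(trimws(as.character(tokens)))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) return(list(symbols = character(0), dropped = 0L))
  if (is.null(map)) return(list(symbols = unique(as_symbol(tokens)), dropped = 0L))
  hit <- tokens %in% map$source
  mapped <- map$target[map$source %in% tokens]
  list(symbols = unique(mapped), dropped = sum(!hit))
}

# vectorized per-token translation used by the PPI parser: returns a list of
# human symbols per token (possibly empty, possibly several)
harmonize_each <- function(tokens, map = NULL) {
  if (is.null(map)) return(as.list(as_symbol(tokens)))
  split_map <- split(map$target, map$source)
  out <- split_map[tokens]
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  unname(out)
}

#' Labeled gold-standard gene sets
#'
#' Holds the positive (gold-standard ciliary genes, GSCG) and negative
#' (non-ciliary genes, NCG) label sets used for training and evaluation.
#' A gene present in both lists is an input error and is rejected.
#'
#' @param positives Character vector of positive gene symbols.
#' @param negatives Character vector of negative gene symbols.
#' @return An object of class `labeled_gene_sets` with elements `positives`
#'   and `negatives`.
#' @export
labeled_gene_sets <- function(positives, negatives) {
  positives <- unique(as_symbol(positives))
  negatives <- unique(as_symbol(negatives))
  if (length(positives) == 0L) stop("positive gene set is empty")
  if (length(negatives) == 0L) stop("negative gene set is empty")
  both <- intersect(positives, negatives)
  if (length(both) > 0L) {
    stop("genes labeled both positive and negative: ",
         paste(utils::head(both, 5), collapse = ", "))
  }
  structure(list(positives = positives, negatives = negatives),
            class = "labeled_gene_sets")
}

#' Read positive/negative label lists from files
#'
#' @param positives_path,negatives_path Gene list files
#'   (see [read_gene_list()]).
#' @return A [labeled_gene_sets()] object.
#' @export
read_labeled_gene_sets <- function(positives_path, negatives_path) {
  labeled_gene_sets(read_gene_list(positives_path),
                    read_gene_list(negatives_path))
}

#' @export
print.labeled_gene_sets <- function(x, ...) {
  cat(sprintf("labeled gene sets: %d positives, %d negatives\n",
              length(x$positives), length(x$negatives)))
  invisible(x)
}
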