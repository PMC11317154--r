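#' Default PSI-MI term confidence weights
#'
#' Confidence weights in [0, 1] for interaction detection-method and
#' interaction-type terms, in the spirit of the MIscore method/type
#' components (the publication component is deliberately excluded to avoid
#' biasing toward well-studied genes). Direct interaction (MI:0407) and the
#' biophysical/biochemical classes carry full weight.
#'
#' @return Named numeric vector MI accession -> weight.
#' @export
default_mi_weights <- function() {
  c("MI:0013" = 1,    # biophysical
    "MI:0090" = 0.66, # protein complementation assay
    "MI:0254" = 0.10, # genetic interference
    "MI:0255" = 0.10, # post-transcriptional interference
    "MI:0401" = 1,    # biochemical
    "MI:0428" = 0.33, # imaging technique
    "MI:0208" = 0.1,  # genetic interaction
    "MI:0403" = 0.33, # colocalization
    "MI:0914" = 0.33, # association
    "MI:0915" = 0.66, # physical association
    "MI:0407" = 1)    # direct interaction
}

#' Parse interaction records
#'
#' Reads a MITAB-style 6-column TSV (interactor A, interactor B, detection
#' method MI term, interaction type MI term, publication id, taxon),
#' harmonizes both interactors to human symbols, and drops self-loops and
#' records whose interactors cannot be mapped. A source gene mapping to
#' several human genes fans the record out to every target pair.
#'
#' @param path Path to the interactions TSV.
#' @param map Optional ortholog map for non-human interactor tokens.
#' @param header Skip the first line when TRUE.
#' @return List with `records` (tibble: a, b, method_term, type_term,
#'   publication, taxon), `self_loops` and `unmapped` drop counts.
#' @export
parse_interactions <- function(path, map = NULL, header = FALSE) {
  raw <- read_tsv_cols(path, 6L,
                       c("a", "b", "method_term", "type_term",
                         "publication", "taxon"),
                       header = header)
  bad <- which(!grepl("^MI:[0-9]{4}$", raw$method_term) |
               !grepl("^MI:[0-9]{4}$", raw$type_term))
  if (length(bad) > 0L) {
    stop(sprintf("malformed MI accession at line %d of '%s'",
                 bad[1] + as.integer(header), path))
  }
  a_h <- harmonize_each(raw$a, map)
  b_h <- harmonize_each(raw$b, map)
  unmapped <- 0L
  self_loops <- 0L
  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    pairs <- expand.grid(a = a_h[[i]], b = b_h[[i]],
                         stringsAsFactors = FALSE)
    if (nrow(pairs) == 0L) { unmapped <- unmapped + 1L; next }
    loops <- pairs$a == pairs$b
    self_loops <- self_loops + sum(loops)
    pairs <- pairs[!loops, , drop = FALSE]
    if (nrow(pairs) == 0L) next
    rows[[i]] <- tibble::tibble(a = pairs$a, b = pairs$b,
                                method_term = raw$method_term[i],
                                type_term = raw$type_term[i],
                                publication = raw$publication[i],
                                taxon = raw$taxon[i])
  }
  records <- dplyr::bind_rows(rows)
  if (nrow(records) == 0L) {
    records <- tibble::tibble(a = character(0), b = character(0),
                              method_term = character(0),
                              type_term = character(0),
                              publication = character(0),
                              taxon = character(0))
  }
  list(records = records, self_loops = self_loops, unmapped = unmapped)
}

# canonical unordered-pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Remove redundant interaction records
#'
#' A record is redundant when both interactors (as an unordered pair) and
#' the publication identifier match an earlier record; the first occurrence
#' is kept.
#'
#' @param records Interaction record tibble.
#' @return De-duplicated tibble.
#' @export
deduplicate_interactions <- function(records) {
  if (nrow(records) == 0L) return(records)
  key <- paste(pair_key(records$a, records$b), records$publication, sep = "@")
  records[!duplicated(key), , drop = FALSE]
}

#' Confidence score per interacting gene pair
#'
#' All evidence records for an unordered pair are aggregated into a method
#' component (the maximum detection-method weight observed) and a type
#' component (the maximum interaction-type weight); the pair score is the
#' mean of the two components. MI terms absent from the weight table score
#' 0 with a warning. Publication counts are deliberately not used.
#'
#' @param records De-duplicated interaction records.
#' @param weights Named weight vector (default [default_mi_weights()]).
#' @return Tibble with one row per unordered pair: `a`, `b` (sorted),
#'   `method_component`, `type_component`, `score`.
#' @export
pair_scores <- function(records, weights = default_mi_weights()) {
  if (nrow(records) == 0L) {
    return(tibble::tibble(a = character(0), b = character(0),
                          method_component = numeric(0),
                          type_component = numeric(0), score = numeric(0)))
  }
  unknown <- setdiff(unique(c(records$method_term, records$type_term)),
                     names(weights))
  if (length(unknown) > 0L) {
    warning("MI terms without a weight (scored 0): ",
            paste(unknown, collapse = ", "))
  }
  w_method <- unname(weights[records$method_term]); w_method[is.na(w_method)] <- 0
  w_type <- unname(weights[records$type_term]); w_type[is.na(w_type)] <- 0
  lo <- pmin(records$a, records$b)
  hi <- pmax(records$a, records$b)
  df <- tibble::tibble(a = lo, b = hi, w_method = w_method, w_type = w_type)
  out <- dplyr::summarise(dplyr::group_by(df, a, b),
                          method_component = max(w_method),
                          type_component = max(w_type),
                          .groups = "drop")
  out$score <- (out$method_component + out$type_component) / 2
  out
}

#' Ciliary-neighborhood interaction (cgi) scores
#'
#' For each gene, Ln is its number of (de-duplicated) interaction records
#' and Lg the geometric mean of its pair scores with known ciliary genes
#' (one score per ciliary partner); the cgi score is
#' `log(Ln/5 + 1) * Lg` (natural log). Genes with no ciliary partner have
#' Lg = 0 and hence cgi = 0; negative-list partners contribute nothing
#' (scores are never negative).
#'
#' @param records De-duplicated interaction records.
#' @param pairs Pair-score tibble from [pair_scores()].
#' @param labels [labeled_gene_sets()]; positives are the known ciliary
#'   genes.
#' @param genes Optional gene universe; genes absent from the network get
#'   Ln = 0, Lg = 0, cgi = 0.
#' @param ln_mode Count `"records"` (evidence lines, default) or
#'   `"partners"` (distinct interaction partners) for Ln.
#' @return Tibble with columns `gene`, `ln_count`, `lg`, `cgi`.
#' @export
cgi_scores <- function(records, pairs, labels, genes = NULL,
                       ln_mode = c("records", "partners")) {
  ln_mode <- match.arg(ln_mode)
  stopifnot(inherits(labels, "labeled_gene_sets"))
  network_genes <- unique(c(records$a, records$b))
  if (is.null(genes)) genes <- sort(network_genes)
  genes <- as_symbol(genes)

  endpoint <- c(records$a, records$b)
  if (ln_mode == "records") {
    ln_tab <- table(endpoint)
  } else {
    ln_tab <- table(unique(
      data.frame(g = endpoint,
                 p = pair_key(c(records$a, records$b),
                              c(records$b, records$a))))$g)
  }
  ln <- stats::setNames(rep(0L, length(genes)), genes)
  hit <- intersect(genes, names(ln_tab))
  ln[hit] <- as.integer(ln_tab[hit])

  # geometric mean of pair scores with positive-labeled partners
  lg <- stats::setNames(rep(0, length(genes)), genes)
  long <- rbind(
    data.frame(gene = pairs$a, partner = pairs$b, score = pairs$score),
    data.frame(gene = pairs$b, partner = pairs$a, score = pairs$score)
  )
  long <- long[long$partner %in% labels$positives & long$gene %in% genes, ,
               drop = FALSE]
  if (nrow(long) > 0L) {
    gm <- tapply(long$score, long$gene,
                 function(s) if (any(s == 0)) 0 else exp(mean(log(s))))
    lg[names(gm)] <- as.numeric(gm)
  }
  tibble::tibble(gene = genes, ln_count = unname(ln), lg = unname(lg),
                 cgi = log(unname(ln) / 5 + 1) * unname(lg))
}

#' Protein-interaction score from an interaction file
#'
#' End-to-end wrapper: parse, de-duplicate, score pairs, and compute cgi
#' scores over the requested gene universe.
#'
#' @param path Interactions TSV (see [parse_interactions()]).
#' @param labels [labeled_gene_sets()].
#' @param genes Gene universe for the score table.
#' @param map Optional ortholog map.
#' @param weights MI weight table.
#' @param ln_mode Passed to [cgi_scores()].
#' @return Tibble with columns `gene` and `score` (cgi, >= 0).
#' @export
score_ppi <- function(path, labels, genes = NULL, map = NULL,
                      weights = default_mi_weights(),
                      ln_mode = "records") {
  parsed <- parse_interactions(path, map = map)
  records <- deduplicate_interactions(parsed$records)
  pairs <- pair_scores(records, weights)
  cgi <- cgi_scores(records, pairs, labels, genes = genes, ln_mode = ln_mode)
  tibble::tibble(gene = cgi$gene, score = cgi$cgi)
}
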