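# small in-code fixtures and independent oracles shared across test files

# tiny expression dataset with exact per-group expressing fractions:
# frac1/frac2 are named per gene, each group has n cells
make_expr_dataset <- function(frac1, frac2, n = 10, tag = "toy",
                              log_transform = FALSE) {
  genes <- names(frac1)
  cells <- sprintf("c%02d", seq_len(2 * n))
  groups <- stats::setNames(rep(c("group1", "group2"), each = n), cells)
  mat <- matrix(0, nrow = length(genes), ncol = 2 * n,
                dimnames = list(genes, cells))
  for (g in genes) {
    k1 <- round(frac1[[g]] * n)
    k2 <- round(frac2[[g]] * n)
    if (k1 > 0) mat[g, seq_len(k1)] <- seq_len(k1)          # arbitrary positives
    if (k2 > 0) mat[g, n + seq_len(k2)] <- 1
  }
  expression_dataset(mat, groups, tag = tag, log_transform = log_transform)
}

make_interactions_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

# independent AUC oracle: Mann-Whitney pair statistic by explicit double loop
auc_pair_oracle <- function(pos, neg) {
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# independent cgi oracle: naive recomputation from raw interaction records
cgi_oracle <- function(records, gene, positives,
                       weights = default_mi_weights()) {
  seen <- character(0)
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    key <- paste(min(records$a[i], records$b[i]),
                 max(records$a[i], records$b[i]),
                 records$publication[i])
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      keep[i] <- TRUE
    }
  }
  rec <- records[keep, , drop = FALSE]
  ln <- sum(rec$a == gene | rec$b == gene)
  partners <- unique(c(rec$b[rec$a == gene], rec$a[rec$b == gene]))
  cil_partners <- intersect(partners, positives)
  if (ln == 0 || length(cil_partners) == 0) {
    return(list(ln = ln, lg = 0, cgi = 0))
  }
  scores <- vapply(cil_partners, function(p) {
    sub <- rec[(rec$a == gene & rec$b == p) | (rec$a == p & rec$b == gene), ]
    wm <- max(ifelse(is.na(weights[sub$method_term]), 0, weights[sub$method_term]))
    wt <- max(ifelse(is.na(weights[sub$type_term]), 0, weights[sub$type_term]))
    (wm + wt) / 2
  }, numeric(1))
  lg <- prod(scores)^(1 / length(scores))
  list(ln = ln, lg = lg, cgi = log(ln / 5 + 1) * lg)
}

# random interaction record table over n_genes genes
random_records <- function(n_genes, n_records, seed) {
  withr::local_seed(seed)
  genes <- sprintf("R%03d", seq_len(n_genes))
  terms <- names(default_mi_weights())
  ab <- t(replicate(n_records, sample(genes, 2)))
  tibble::tibble(a = ab[, 1], b = ab[, 2],
                 method_term = sample(terms, n_records, replace = TRUE),
                 type_term = sample(terms, n_records, replace = TRUE),
                 publication = sprintf("PMID:%d", sample.int(20, n_records, replace = TRUE)),
                 taxon = "9606")
}
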