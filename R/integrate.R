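#' Assemble the gene x method score matrix
#'
#' Aligns per-method score tables onto a common gene universe. Missing
#' entries are 0. By default each method column is min-max rescaled to
#' [0, 1] so that the F1 weights learned later are comparable across
#' methods with different native scales.
#'
#' @param score_list Named list of tibbles with columns `gene` and `score`.
#' @param genes Optional gene universe (default: union of all scored genes).
#' @param rescale Min-max rescale each method column (default TRUE).
#' @return Numeric matrix genes x methods.
#' @export
method_score_matrix <- function(score_list, genes = NULL, rescale = TRUE) {
  stopifnot(length(score_list) >= 1L, !is.null(names(score_list)),
            all(nzchar(names(score_list))))
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(score_list, `[[`, "gene"))))
  }
  genes <- as_symbol(genes)
  m <- matrix(0, nrow = length(genes), ncol = length(score_list),
              dimnames = list(genes, names(score_list)))
  for (method in names(score_list)) {
    s <- score_list[[method]]
    idx <- match(s$gene, genes)
    m[idx[!is.na(idx)], method] <- s$score[!is.na(idx)]
    if (rescale) {
      m[, method] <- suppressWarnings(minmax_normalize(m[, method]))
    }
  }
  m
}

#' Stratified train/test split of labeled genes
#'
#' Positives and negatives are split independently so both classes keep the
#' requested proportion. The train size is floor(frac * n) per class, with
#' at least one gene forced into each side. Deterministic given the seed.
#'
#' @param labels [labeled_gene_sets()].
#' @param train_frac Fraction of each class assigned to training.
#' @param seed Integer RNG seed.
#' @return List with `train` and `test`, both [labeled_gene_sets()].
#' @export
split_labels <- function(labels, train_frac = 0.7, seed = 1) {
  stopifnot(inherits(labels, "labeled_gene_sets"),
            train_frac > 0, train_frac < 1)
  split_one <- function(x) {
    if (length(x) < 2L) stop("need at least 2 genes per class to split")
    n_train <- min(max(floor(train_frac * length(x)), 1L), length(x) - 1L)
    train <- sample(sort(x), n_train)
    list(train = train, test = setdiff(x, train))
  }
  withr::local_seed(seed)
  pos <- split_one(labels$positives)
  neg <- split_one(labels$negatives)
  list(train = labeled_gene_sets(pos$train, neg$train),
       test = labeled_gene_sets(pos$test, neg$test))
}

#' Confusion counts at a score threshold
#'
#' A gene is predicted ciliary when its score is greater than or equal to
#' the threshold. Labeled genes absent from the score vector count as
#' scoring 0, so TPR/FPR denominators always match the label sets.
#'
#' @param scores Named numeric vector gene -> score.
#' @param labels [labeled_gene_sets()].
#' @param t Threshold (inclusive).
#' @return Named integer vector with elements TP, FP, FN, TN.
#' @export
confusion_at <- function(scores, labels, t) {
  get <- function(g) {
    s <- scores[g]
    s[is.na(s)] <- 0
    unname(s)
  }
  pos <- get(labels$positives)
  neg <- get(labels$negatives)
  c(TP = sum(pos >= t), FP = sum(neg >= t),
    FN = sum(pos < t), TN = sum(neg < t))
}

#' F1 score from confusion counts
#'
#' F1 = 2TP / (2TP + FP + FN); defined as 0 when the denominator is 0.
#'
#' @param counts Vector with elements TP, FP, FN (e.g. from
#'   [confusion_at()]).
#' @return F1 in [0, 1].
#' @export
f1_score <- function(counts) {
  denom <- 2 * counts[["TP"]] + counts[["FP"]] + counts[["FN"]]
  if (denom == 0) return(0)
  2 * counts[["TP"]] / denom
}

#' Best-F1 weight of one method
#'
#' Sweeps the finite set of observed score values as candidate thresholds,
#' evaluates F1 on the training labels at each, and returns the maximum F1
#' (the method's weight in the integrated score) together with the
#' threshold attaining it (smallest such threshold on ties).
#'
#' @param scores Named numeric vector gene -> score.
#' @param labels Training [labeled_gene_sets()].
#' @return List with `threshold` and `f1`.
#' @export
f1_weight <- function(scores, labels) {
  thresholds <- sort(unique(c(0, scores[c(labels$positives, labels$negatives)],
                              scores)))
  thresholds <- thresholds[!is.na(thresholds)]
  f1s <- vapply(thresholds, function(t) f1_score(confusion_at(scores, labels, t)),
                numeric(1))
  best <- which.max(f1s)  # which.max returns the first (smallest) maximizer
  if (f1s[best] == 0) warning("no threshold achieves a positive F1; method weight 0")
  list(threshold = thresholds[best], f1 = f1s[best])
}

#' Integrated ciliary score
#'
#' The F1-weighted sum of the per-method scores: each method contributes
#' its score multiplied by the F1 it achieved on the training labels, so
#' methods that discriminate known ciliary genes better carry more weight.
#'
#' @param m Gene x method matrix from [method_score_matrix()].
#' @param weights Named list method -> list(threshold, f1) from
#'   [f1_weight()], or a named numeric vector of weights.
#' @return Tibble with columns `gene`, `integrated_score` and `rank`
#'   (1 = highest score).
#' @export
integrated_score <- function(m, weights) {
  if (is.list(weights) && !is.numeric(weights)) {
    weights <- vapply(weights, `[[`, numeric(1), "f1")
  }
  missing <- setdiff(colnames(m), names(weights))
  if (length(missing) > 0L) {
    stop("no weight for method(s): ", paste(missing, collapse = ", "))
  }
  score <- as.numeric(m %*% weights[colnames(m)])
  tibble::tibble(gene = rownames(m), integrated_score = score,
                 rank = rank(-score, ties.method = "min"))
}

#' ROC curve and AUC
#'
#' Sweeps every observed score as a threshold (inclusive prediction rule),
#' plots TPR against FPR, and integrates by the trapezoid rule. Ties are
#' handled so the AUC equals the Mann-Whitney statistic: the probability a
#' random positive outscores a random negative, counting ties as 1/2.
#'
#' @param scores Named numeric vector gene -> score.
#' @param labels Evaluation [labeled_gene_sets()]; both classes required.
#' @return List with `points` (tibble: threshold, fpr, tpr, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(inherits(labels, "labeled_gene_sets"))
  get <- function(g) {
    s <- scores[g]
    s[is.na(s)] <- 0
    unname(s)
  }
  pos <- get(labels$positives)
  neg <- get(labels$negatives)
  thresholds <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(neg >= t), numeric(1))
  points <- tibble::tibble(
    threshold = c(Inf, thresholds),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                 utils::tail(points$tpr, -1)) / 2)
  list(points = points, auc = auc)
}

#' Learn weights, integrate, and evaluate all methods
#'
#' Learns each method's F1 weight on the training labels, computes the
#' integrated score, and reports ROC/AUC for every method and for the
#' integrated score on the evaluation labels.
#'
#' @param m Gene x method matrix from [method_score_matrix()].
#' @param train_labels Training [labeled_gene_sets()] (F1 weights).
#' @param eval_labels Evaluation [labeled_gene_sets()] (ROC/AUC).
#' @return List with `weights` (tibble: method, threshold, f1), `scores`
#'   (tibble from [integrated_score()], plus per-method columns) and `auc`
#'   (tibble: method, auc).
#' @export
evaluate_methods <- function(m, train_labels, eval_labels) {
  weights <- lapply(colnames(m), function(method) {
    w <- f1_weight(stats::setNames(m[, method], rownames(m)), train_labels)
    tibble::tibble(method = method, threshold = w$threshold, f1 = w$f1)
  })
  weights <- dplyr::bind_rows(weights)
  integrated <- integrated_score(m, stats::setNames(weights$f1, weights$method))
  auc_rows <- lapply(colnames(m), function(method) {
    r <- roc_auc(stats::setNames(m[, method], rownames(m)), eval_labels)
    tibble::tibble(method = method, auc = r$auc)
  })
  combined <- roc_auc(stats::setNames(integrated$integrated_score,
                                      integrated$gene), eval_labels)
  auc <- dplyr::bind_rows(c(auc_rows,
                            list(tibble::tibble(method = "integrated",
                                                auc = combined$auc))))
  scores <- cbind(tibble::as_tibble(m), integrated[c("integrated_score", "rank")])
  scores <- tibble::add_column(scores, gene = rownames(m), .before = 1)
  list(weights = weights, scores = tibble::as_tibble(scores), auc = auc)
}
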