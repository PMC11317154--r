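test_that("label splits are stratified, deterministic, and disjoint", {
  labels <- labeled_gene_sets(sprintf("P%02d", 1:10), sprintf("N%02d", 1:10))
  s <- split_labels(labels, train_frac = 0.7, seed = 5)
  expect_length(s$train$positives, 7)
  expect_length(s$train$negatives, 7)
  expect_length(s$test$positives, 3)
  expect_length(s$test$negatives, 3)
  expect_length(intersect(s$train$positives, s$test$positives), 0)
  expect_length(intersect(s$train$negatives, s$test$negatives), 0)

  s2 <- split_labels(labels, train_frac = 0.7, seed = 5)
  expect_identical(s, s2)

  # extreme fraction still leaves at least one test gene per class
  s99 <- split_labels(labels, train_frac = 0.99, seed = 1)
  expect_length(s99$train$positives, 9)
  expect_length(s99$test$positives, 1)

  tiny <- labeled_gene_sets("P1", c("N1", "N2"))
  expect_error(split_labels(tiny, seed = 1), "at least 2 genes")
})

test_that("confusion counts use an inclusive threshold and score-0 for unscored genes", {
  scores <- c(P1 = 0.9, P2 = 0.2, N1 = 0.1)
  labels <- labeled_gene_sets(c("P1", "P2"), "N1")
  expect_equal(confusion_at(scores, labels, 0.5),
               c(TP = 1L, FP = 0L, FN = 1L, TN = 1L))
  # t = 0: everything predicted positive
  expect_equal(confusion_at(scores, labels, 0)[c("FN", "TN")],
               c(FN = 0L, TN = 0L))
  # t above the maximum: everything negative
  expect_equal(confusion_at(scores, labels, 1.1)[c("TP", "FP")],
               c(TP = 0L, FP = 0L))
  # labeled gene missing from the score vector counts as scoring 0
  labels2 <- labeled_gene_sets(c("P1", "UNSCORED"), "N1")
  expect_equal(confusion_at(scores, labels2, 0.5)[["FN"]], 1L)
})

test_that("F1 matches 2TP/(2TP+FP+FN) including degenerate cases", {
  expect_equal(f1_score(c(TP = 3, FP = 2, FN = 1)), 6 / 9)
  expect_equal(f1_score(c(TP = 0, FP = 0, FN = 0)), 0)

  # constant scores: all predicted positive at t <= c, F1 = 2P/(2P+N)
  labels <- labeled_gene_sets(sprintf("P%d", 1:4), sprintf("N%d", 1:6))
  const <- stats::setNames(rep(0.3, 10), c(labels$positives, labels$negatives))
  w <- f1_weight(const, labels)
  expect_equal(w$f1, 2 * 4 / (2 * 4 + 6))

  # perfectly separating scores: F1 = 1
  sep <- stats::setNames(c(rep(1, 4), rep(0, 6)),
                         c(labels$positives, labels$negatives))
  expect_equal(f1_weight(sep, labels)$f1, 1)
})

test_that("the best-F1 threshold search equals a dense grid search", {
  withr::local_seed(9)
  for (rep in 1:10) {
    labels <- labeled_gene_sets(sprintf("P%d", 1:8), sprintf("N%d", 1:12))
    scores <- stats::setNames(round(runif(20), 2),
                              c(labels$positives, labels$negatives))
    w <- f1_weight(scores, labels)
    grid <- seq(-0.01, 1.01, by = 0.001)
    grid_f1 <- vapply(grid, function(t) f1_score(confusion_at(scores, labels, t)),
                      numeric(1))
    expect_equal(w$f1, max(grid_f1), tolerance = 1e-12)
  }
})

test_that("the integrated score is the F1-weighted sum of method scores", {
  m <- matrix(c(1, 0, 0.5, 0, 0.2), nrow = 1,
              dimnames = list("G1", c("phylo", "scrna", "ppi", "tfnet", "textmine")))
  w <- c(phylo = 0.5, scrna = 0.2, ppi = 0.4, tfnet = 0.3, textmine = 0.1)
  out <- integrated_score(m, w)
  expect_equal(out$integrated_score, 0.5 * 1 + 0.4 * 0.5 + 0.1 * 0.2)  # 0.72

  expect_equal(integrated_score(m, w * 0)$integrated_score, 0)

  m1 <- matrix(c(0.3, 0.9), ncol = 1, dimnames = list(c("A", "B"), "ppi"))
  expect_equal(integrated_score(m1, c(ppi = 1))$integrated_score, c(0.3, 0.9))
  expect_error(integrated_score(m1, c(other = 1)), "no weight")
})

test_that("raising one method score never lowers the integrated score", {
  withr::local_seed(21)
  m <- matrix(runif(50 * 3), nrow = 50,
              dimnames = list(sprintf("G%02d", 1:50), c("a", "b", "c")))
  w <- c(a = 0.4, b = 0.7, c = 0.1)
  base <- integrated_score(m, w)$integrated_score
  for (j in 1:3) {
    bumped <- m
    i <- sample(50, 1)
    bumped[i, j] <- min(1, bumped[i, j] + 0.3)
    after <- integrated_score(bumped, w)$integrated_score
    expect_true(all(after >= base - 1e-12))
  }
})

test_that("ROC/AUC handles separation, ties, and mixed rankings", {
  lab <- function(p, n) labeled_gene_sets(names(p), names(n))
  pos <- c(P1 = 0.9, P2 = 0.8); neg <- c(N1 = 0.2, N2 = 0.1)
  r <- roc_auc(c(pos, neg), lab(pos, neg))
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))

  tied <- c(P1 = 0.5, P2 = 0.5, N1 = 0.5, N2 = 0.5)
  expect_equal(roc_auc(tied, lab(tied[1:2], tied[3:4]))$auc, 0.5)

  mixed <- c(P1 = 0.8, P2 = 0.3, N1 = 0.5, N2 = 0.1)
  expect_equal(roc_auc(mixed, lab(mixed[1:2], mixed[3:4]))$auc, 0.75)

  expect_error(labeled_gene_sets(character(0), "N1"), "empty")
})

test_that("trapezoid AUC equals the Mann-Whitney pair statistic and pROC", {
  withr::local_seed(33)
  for (rep in 1:50) {
    n_pos <- sample(3:100, 1)
    n_neg <- sample(3:100, 1)
    # ties likely: scores on a coarse grid
    pos <- stats::setNames(sample(seq(0, 1, 0.1), n_pos, replace = TRUE),
                           sprintf("P%03d", 1:n_pos))
    neg <- stats::setNames(sample(seq(0, 1, 0.1), n_neg, replace = TRUE),
                           sprintf("N%03d", 1:n_neg))
    labels <- labeled_gene_sets(names(pos), names(neg))
    auc <- roc_auc(c(pos, neg), labels)$auc
    expect_equal(auc, auc_pair_oracle(pos, neg), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  pos <- stats::setNames(runif(40), sprintf("P%03d", 1:40))
  neg <- stats::setNames(runif(60), sprintf("N%03d", 1:60))
  labels <- labeled_gene_sets(names(pos), names(neg))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 60)), predictor = c(pos, neg),
    quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(c(pos, neg), labels)$auc, ref, tolerance = 1e-12)
})

test_that("method score matrix aligns genes, fills missing with 0, rescales", {
  s1 <- tibble::tibble(gene = c("A", "B"), score = c(2, 6))
  s2 <- tibble::tibble(gene = c("B", "C"), score = c(0.5, 0.25))
  m <- method_score_matrix(list(x = s1, y = s2))
  expect_equal(rownames(m), c("A", "B", "C"))
  # x: raw {2, 6, missing->0} min-max rescaled; y: {missing->0, 0.5, 0.25}
  expect_equal(unname(m[, "x"]), c(1 / 3, 1, 0))
  expect_equal(unname(m[, "y"]), c(0, 1, 0.5))
  expect_true(all(m >= 0 & m <= 1))

  m_raw <- method_score_matrix(list(x = s1, y = s2), rescale = FALSE)
  expect_equal(unname(m_raw[, "x"]), c(2, 6, 0))
})
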