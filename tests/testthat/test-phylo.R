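toy_hits <- function(...) {
  rows <- list(...)
  tibble::tibble(
    query = vapply(rows, `[[`, character(1), 1),
    subject = vapply(rows, `[[`, character(1), 2),
    organism = vapply(rows, `[[`, character(1), 3),
    bit_score = vapply(rows, function(r) as.numeric(r[[4]]), numeric(1)),
    p_value = vapply(rows, function(r) as.numeric(r[[5]]), numeric(1))
  )
}

test_that("hit filtering keeps boundary values and removes weak hits", {
  hits <- toy_hits(
    list("GENE1", "p1", "org_a", 50.0, 0.001),   # both at threshold: kept
    list("GENE1", "p2", "org_a", 49.9, 1e-9),    # bit too low
    list("GENE1", "p3", "org_a", 300, 0.01))     # p too high
  kept <- filter_blast_hits(hits)
  expect_equal(kept$subject, "p1")
})

test_that("best hits pick the maximal bit score with lexicographic tie-break", {
  hits <- toy_hits(
    list("GENE1", "x", "org_a", 120, 1e-9),
    list("GENE1", "y", "org_a", 200, 1e-9),
    list("GENE2", "p2", "org_a", 99, 1e-9),
    list("GENE2", "p1", "org_a", 99, 1e-9))
  best <- best_hits(hits)
  expect_equal(best$subject[best$query == "GENE1"], "y")
  expect_equal(best$subject[best$query == "GENE2"], "p1")
  # no hits for (GENE1, org_b): the pair is simply absent
  expect_equal(nrow(best), 2)
})

test_that("presence matrix is the indicator of surviving best hits", {
  best <- toy_hits(
    list("G1", "s", "o1", 100, 1e-9),
    list("G1", "s", "o3", 100, 1e-9),
    list("G2", "s", "o2", 100, 1e-9))
  pm <- build_presence_matrix(best, c("G1", "G2"), c("o1", "o2", "o3"),
                              c(TRUE, FALSE, TRUE))
  expect_equal(unname(pm$cells), rbind(c(1L, 0L, 1L), c(0L, 1L, 0L)))

  none <- build_presence_matrix(best[0, ], c("G1", "G2"), c("o1", "o2"),
                                c(TRUE, FALSE))
  expect_true(all(none$cells == 0))

  expect_error(
    build_presence_matrix(toy_hits(list("G1", "s", "oX", 100, 1e-9)),
                          c("G1"), c("o1", "o2"), c(TRUE, FALSE)),
    "outside the panel")
})

test_that("Gower dissimilarity on binary profiles is the mismatch fraction", {
  m <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0),
             c = c(0, 0, 1, 1), d = c(1, 0, 0, 1))
  d <- gower_dissimilarity(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)       # complementary rows
  expect_equal(d["a", "d"], 0.5)     # 2 mismatches / 4 organisms
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_error(gower_dissimilarity(m[1, , drop = FALSE]), "at least 2 genes")
})

test_that("Gower matches cluster::daisy and the exhaustive Hamming count", {
  withr::local_seed(42)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    p <- sample(3:10, 1)
    m <- matrix(rbinom(n * p, 1, 0.5), nrow = n,
                dimnames = list(sprintf("g%02d", 1:n), NULL))
    d <- gower_dissimilarity(m)
    ref <- as.matrix(suppressWarnings(
      cluster::daisy(as.data.frame(m), metric = "gower")))
    expect_equal(unname(d), unname(ref), tolerance = 1e-12)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      expect_equal(d[i, j], sum(m[i, ] != m[j, ]) / p)
    }
  }
})

test_that("hierarchical clustering recovers planted blocks and respects k", {
  # two tight blocks: within 0, between 1
  block <- function(ids, within, between, labels) {
    n <- length(labels)
    d <- matrix(between, n, n, dimnames = list(labels, labels))
    for (b in unique(ids)) d[ids == b, ids == b] <- within
    diag(d) <- 0
    d
  }
  labels <- sprintf("g%d", 1:6)
  d2 <- block(rep(1:2, each = 3), 0, 1, labels)
  a2 <- cluster_profiles(d2, k = 2)
  expect_length(unique(a2$cluster[1:3]), 1)
  expect_length(unique(a2$cluster[4:6]), 1)
  expect_false(a2$cluster[1] == a2$cluster[4])

  # k = n: singletons
  an <- cluster_profiles(d2, k = 6)
  expect_equal(sort(unique(an$cluster)), 1:6)
  expect_error(cluster_profiles(d2, k = 7), "exceeds")

  # 3 planted blocks with noise margins: every within-block pair co-clusters
  labels9 <- sprintf("h%d", 1:9)
  ids <- rep(1:3, each = 3)
  d3 <- block(ids, 0.05, 0.9, labels9)
  a3 <- cluster_profiles(d3, k = 3)
  for (b in 1:3) expect_length(unique(a3$cluster[ids == b]), 1)
  expect_length(unique(a3$cluster), 3)
})

test_that("cluster contents are invariant to gene order for complete linkage", {
  # unique pairwise dissimilarities make the complete-linkage tree unique
  withr::local_seed(11)
  n <- 30
  d <- matrix(0, n, n, dimnames = list(sprintf("g%02d", 1:n),
                                       sprintf("g%02d", 1:n)))
  vals <- sample(seq_len(n * (n - 1) / 2)) / (n * (n - 1) / 2)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  a1 <- cluster_profiles(d, k = 5)
  perm <- sample(n)
  a2 <- cluster_profiles(d[perm, perm], k = 5)
  # same partition: co-membership must agree for every pair
  part1 <- stats::setNames(a1$cluster, a1$gene)
  part2 <- stats::setNames(a2$cluster, a2$gene)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    gi <- a1$gene[i]; gj <- a1$gene[j]
    expect_equal(part1[[gi]] == part1[[gj]], part2[[gi]] == part2[[gj]])
  }
})

test_that("cluster flagging follows the enrichment rule", {
  # fractions 0.50 / 0.45 / 0.02 against a low background: first two flagged
  assignment <- tibble::tibble(
    gene = sprintf("G%04d", 1:1040),
    cluster = rep(1:3, c(20, 20, 1000)))
  positives <- c(assignment$gene[1:10],          # 10/20 in cluster 1
                 assignment$gene[21:29],         # 9/20 in cluster 2
                 assignment$gene[41:60])         # 20/1000 in cluster 3
  labels <- labeled_gene_sets(positives, "NEG1")
  flagged <- flag_ciliary_clusters(assignment, labels, min_fold = 5)
  expect_setequal(flagged$flagged, c(1L, 2L))
  expect_equal(unname(flagged$fractions), c(0.5, 0.45, 0.02))
  expect_true(all(flagged$scores$phylo_score[flagged$scores$cluster %in% 1:2] == 1))
  expect_true(all(flagged$scores$phylo_score[flagged$scores$cluster == 3] == 0))

  # no positives inside any cluster: warning, all scores 0
  labels_out <- labeled_gene_sets("ELSEWHERE", "NEG1")
  expect_warning(f0 <- flag_ciliary_clusters(assignment, labels_out),
                 "no cluster")
  expect_true(all(f0$scores$phylo_score == 0))

  # a single all-genes cluster equals background, never enriched for fold > 1
  one <- tibble::tibble(gene = sprintf("G%d", 1:10), cluster = rep(1L, 10))
  labels1 <- labeled_gene_sets(one$gene[1:3], "NEG1")
  expect_warning(f1 <- flag_ciliary_clusters(one, labels1, min_fold = 5))
  expect_true(all(f1$scores$phylo_score == 0))
})

test_that("top-clusters flagging picks the highest-fraction clusters only", {
  assignment <- tibble::tibble(gene = sprintf("G%02d", 1:12),
                               cluster = rep(1:4, each = 3))
  labels <- labeled_gene_sets(c("G01", "G02", "G04", "G07"), "NEG1")
  f <- flag_ciliary_clusters(assignment, labels, top_clusters = 2)
  expect_setequal(f$flagged, c(1L, 2L))   # fractions 2/3, 1/3, 1/3, 0 (tie -> smaller id)
})

test_that("planted phylogenetic profiles are recovered at >= 95%", {
  withr::local_seed(2024)
  n_genes <- 200; n_planted <- 30; n_org <- 24
  ciliated <- rep(c(TRUE, FALSE), each = n_org / 2)
  genes <- sprintf("G%03d", seq_len(n_genes))
  planted <- genes[seq_len(n_planted)]
  m <- matrix(rbinom(n_genes * n_org, 1, 0.5), nrow = n_genes,
              dimnames = list(genes, sprintf("o%02d", 1:n_org)))
  flips <- matrix(rbinom(n_planted * n_org, 1, 0.05), nrow = n_planted)
  m[seq_len(n_planted), ] <- abs(matrix(rep(as.integer(ciliated),
                                            each = n_planted),
                                        nrow = n_planted) - flips)
  d <- gower_dissimilarity(m)
  assignment <- cluster_profiles(d, k = 40)
  labels <- labeled_gene_sets(planted, genes[(n_planted + 1):n_genes])
  f <- flag_ciliary_clusters(assignment, labels, min_fold = 5)
  recovered <- f$scores$phylo_score[f$scores$gene %in% planted]
  expect_gte(mean(recovered), 0.95)
})
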