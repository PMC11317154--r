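#' Parameters for the synthetic ciliary-gene benchmark
#'
#' Defines the generative conditions for a fully synthetic benchmark with a
#' planted ciliary gene class. Planted genes carry correlated signal in all
#' five evidence channels: their ortholog profiles track the organism
#' ciliation indicator, they are preferentially expressed in ciliated
#' cells, they interact among themselves more densely than background
#' genes, they are targeted by ciliary transcription factors at a higher
#' rate, and their annotations mention ciliary keywords more often. Effect
#' sizes are set so each single channel is informative but imperfect, which
#' is what makes integration worth testing.
#'
#' @param n_genes Number of genes (default 300).
#' @param n_ciliary Number of planted ciliary genes (default 60).
#' @param n_organisms Organism panel size, half of them ciliated
#'   (default 24).
#' @param profile_flip_p Per-cell probability that a planted gene's
#'   presence call deviates from the organism ciliation indicator
#'   (default 0.05).
#' @param background_presence_p Presence probability for background-gene
#'   profiles (default 0.5).
#' @param n_cells_per_group Cells per group in each expression dataset
#'   (default 200).
#' @param expr_p_ciliary_group1 Probability a planted gene is expressed in
#'   a ciliated cell (default 0.8).
#' @param expr_p_ciliary_group2 Probability a planted gene is expressed in
#'   a non-ciliated cell (default 0.05).
#' @param background_expr_p Expression probability of background genes in
#'   any cell (default 0.3).
#' @param ppi_edge_p_ciliary Interaction probability between two planted
#'   genes (default 0.15).
#' @param ppi_edge_p_background Interaction probability for any other gene
#'   pair (default 0.01).
#' @param tf_lambda_ciliary Poisson rate of per-TF support counts for
#'   planted genes (default 2).
#' @param tf_lambda_background Same for background genes (default 0.1).
#' @param text_keyword_p_ciliary Probability a planted gene has a
#'   ciliary-keyword annotation entry (default 0.5).
#' @param text_keyword_p_background Same for background genes
#'   (default 0.02).
#' @param gscg_frac_of_ciliary Fraction of planted genes sampled into the
#'   gold-standard positive list (default 0.5).
#' @param n_ncg Negative-list size, sampled from background genes
#'   (default 80).
#' @param seed Integer RNG seed.
#' @return A `benchmark_params` list.
#' @export
benchmark_params <- function(n_genes = 300, n_ciliary = 60, n_organisms = 24,
                             profile_flip_p = 0.05,
                             background_presence_p = 0.5,
                             n_cells_per_group = 200,
                             expr_p_ciliary_group1 = 0.8,
                             expr_p_ciliary_group2 = 0.05,
                             background_expr_p = 0.3,
                             ppi_edge_p_ciliary = 0.15,
                             ppi_edge_p_background = 0.01,
                             tf_lambda_ciliary = 2,
                             tf_lambda_background = 0.1,
                             text_keyword_p_ciliary = 0.5,
                             text_keyword_p_background = 0.02,
                             gscg_frac_of_ciliary = 0.5,
                             n_ncg = 80,
                             seed = 1) {
  p <- as.list(environment())
  probs <- c(p$profile_flip_p, p$background_presence_p,
             p$expr_p_ciliary_group1, p$expr_p_ciliary_group2,
             p$background_expr_p, p$ppi_edge_p_ciliary,
             p$ppi_edge_p_background, p$text_keyword_p_ciliary,
             p$text_keyword_p_background, p$gscg_frac_of_ciliary)
  stopifnot(all(probs >= 0 & probs <= 1),
            p$n_ciliary < p$n_genes, p$n_organisms >= 2,
            p$n_ncg <= p$n_genes - p$n_ciliary,
            p$tf_lambda_ciliary >= 0, p$tf_lambda_background >= 0)
  structure(p, class = "benchmark_params")
}

#' Null-benchmark parameters (no planted signal)
#'
#' Keeps the planted gene labels but equalizes every ciliary generation
#' rate with its background counterpart, so no evidence channel carries
#' information about the labels. Used to calibrate the evaluation: every
#' AUC on the ground truth should be near 0.5.
#'
#' @param seed Integer RNG seed.
#' @param ... Overrides passed to [benchmark_params()].
#' @return A `benchmark_params` list.
#' @export
null_benchmark_params <- function(seed = 1, ...) {
  benchmark_params(profile_flip_p = 0.5,
                   expr_p_ciliary_group1 = 0.3,
                   expr_p_ciliary_group2 = 0.3,
                   background_expr_p = 0.3,
                   ppi_edge_p_ciliary = 0.01,
                   tf_lambda_ciliary = 0.1,
                   text_keyword_p_ciliary = 0.02,
                   seed = seed, ...)
}

# one synthetic expression dataset: Bernoulli expression indicator times a
# shifted Poisson count
sim_expression <- function(genes, ciliary, p, cell_prefix) {
  n_cells <- 2L * p$n_cells_per_group
  cells <- sprintf("%s%04d", cell_prefix, seq_len(n_cells))
  groups <- rep(c("group1", "group2"), each = p$n_cells_per_group)
  expr_p <- matrix(p$background_expr_p, nrow = length(genes), ncol = n_cells)
  is_cil <- genes %in% ciliary
  expr_p[is_cil, groups == "group1"] <- p$expr_p_ciliary_group1
  expr_p[is_cil, groups == "group2"] <- p$expr_p_ciliary_group2
  on <- matrix(stats::rbinom(length(expr_p), 1, expr_p), nrow = length(genes))
  counts <- on * (1L + matrix(stats::rpois(length(expr_p), 2),
                              nrow = length(genes)))
  dimnames(counts) <- list(genes, cells)
  list(mat = counts, groups = stats::setNames(groups, cells))
}

#' Generate the synthetic benchmark
#'
#' Draws every input the scoring pipeline consumes — BLAST-style hits with
#' decoy sub-threshold and duplicate rows, two expression datasets (one
#' "human", one "worm" requiring ortholog mapping and the log scoring
#' variant), interaction records with redundant duplicates and self-loops,
#' TF-target records, annotation texts, and GSCG/NCG label lists — from
#' the planted model in `params`. Regeneration with the same parameters
#' and seed is byte-identical.
#'
#' @param params A [benchmark_params()] object.
#' @param dir Optional directory; when given, all input files plus
#'   `truth.tsv` and `config.yaml` are written there.
#' @return Object of class `synthetic_benchmark` holding the in-memory
#'   inputs, the planted truth, and (when written) the file paths.
#' @export
simulate_benchmark <- function(params = benchmark_params(), dir = NULL) {
  stopifnot(inherits(params, "benchmark_params"))
  p <- params
  withr::local_seed(p$seed)

  genes <- sprintf("G%04d", seq_len(p$n_genes))
  ciliary <- sort(sample(genes, p$n_ciliary))
  background <- setdiff(genes, ciliary)
  n_gscg <- min(length(ciliary), max(2L, round(p$gscg_frac_of_ciliary * p$n_ciliary)))
  gscg <- if (n_gscg > 0L) sort(sample(ciliary, n_gscg)) else character(0)
  ncg <- sort(sample(background, p$n_ncg))

  # --- phylogenetic profiles -------------------------------------------
  organisms <- sprintf("org%02d", seq_len(p$n_organisms))
  ciliated <- seq_len(p$n_organisms) <= ceiling(p$n_organisms / 2)
  profile <- matrix(0L, nrow = p$n_genes, ncol = p$n_organisms,
                    dimnames = list(genes, organisms))
  is_cil <- genes %in% ciliary
  flips <- matrix(stats::rbinom(sum(is_cil) * p$n_organisms, 1, p$profile_flip_p),
                  nrow = sum(is_cil))
  indicator <- matrix(rep(as.integer(ciliated), each = sum(is_cil)),
                      nrow = sum(is_cil))
  profile[is_cil, ] <- abs(indicator - flips)
  profile[!is_cil, ] <- stats::rbinom(sum(!is_cil) * p$n_organisms, 1,
                                      p$background_presence_p)

  present <- which(profile == 1L, arr.ind = TRUE)
  hits <- tibble::tibble(
    query = genes[present[, 1]],
    subject = sprintf("%s_p1", organisms[present[, 2]]),
    organism = organisms[present[, 2]],
    bit_score = round(stats::runif(nrow(present), 60, 300), 1),
    p_value = signif(stats::runif(nrow(present), 1e-30, 1e-6), 3)
  )
  # duplicate weaker transcripts (best-hit must discard) and decoy hits
  # below the filter thresholds (absent cells must stay absent)
  dup <- hits[stats::runif(nrow(hits)) < 0.1, , drop = FALSE]
  if (nrow(dup) > 0L) {
    dup$subject <- sprintf("%s_p2", dup$organism)
    dup$bit_score <- round(dup$bit_score * 0.5, 1)
  }
  absent <- which(profile == 0L, arr.ind = TRUE)
  decoy_idx <- which(stats::runif(nrow(absent)) < 0.05)
  decoys <- tibble::tibble(
    query = genes[absent[decoy_idx, 1]],
    subject = sprintf("%s_junk", organisms[absent[decoy_idx, 2]]),
    organism = organisms[absent[decoy_idx, 2]],
    bit_score = round(stats::runif(length(decoy_idx), 20, 49.5), 1),
    p_value = signif(stats::runif(length(decoy_idx), 0.002, 0.5), 3)
  )
  blast <- dplyr::bind_rows(hits, dup, decoys)
  blast <- blast[order(blast$query, blast$organism, blast$subject), ]

  # --- expression ------------------------------------------------------
  ds_human <- sim_expression(genes, ciliary, p, "hc")
  worm_keep <- sort(sample(genes, round(0.85 * p$n_genes)))
  worm_names <- paste0("cel-", tolower(worm_keep))
  ds_worm <- sim_expression(worm_keep, ciliary, p, "wc")
  rownames(ds_worm$mat) <- worm_names
  worm_map <- tibble::tibble(source = worm_names, target = worm_keep)

  # --- protein-protein interactions ------------------------------------
  pair_idx <- utils::combn(p$n_genes, 2)
  both_cil <- is_cil[pair_idx[1, ]] & is_cil[pair_idx[2, ]]
  edge_p <- ifelse(both_cil, p$ppi_edge_p_ciliary, p$ppi_edge_p_background)
  keep <- stats::runif(length(edge_p)) < edge_p
  a <- genes[pair_idx[1, keep]]
  b <- genes[pair_idx[2, keep]]
  method_pool <- names(default_mi_weights())
  type_pool <- c("MI:0914", "MI:0915", "MI:0407", "MI:0403")
  n_ev <- 1L + stats::rpois(length(a), 0.5)
  ppi <- tibble::tibble(
    a = rep(a, n_ev), b = rep(b, n_ev),
    method_term = sample(method_pool, sum(n_ev), replace = TRUE),
    type_term = sample(type_pool, sum(n_ev), replace = TRUE),
    publication = sprintf("PMID:%05d", sample.int(99999, sum(n_ev), replace = TRUE)),
    taxon = "9606"
  )
  if (nrow(ppi) >= 10L) {
    # redundant rows with interactors swapped, plus a few self-loops
    red <- ppi[sample.int(nrow(ppi), 5L), , drop = FALSE]
    red[c("a", "b")] <- red[c("b", "a")]
    loops <- ppi[sample.int(nrow(ppi), 3L), , drop = FALSE]
    loops$b <- loops$a
    ppi <- dplyr::bind_rows(ppi, red, loops)
  }

  # --- TF-target regulome ----------------------------------------------
  panel <- default_tf_panel()
  species <- sprintf("sp%02d", 1:11)
  reg_rows <- list()
  for (tf in panel) {
    lam <- ifelse(is_cil, p$tf_lambda_ciliary, p$tf_lambda_background)
    counts <- pmin(stats::rpois(p$n_genes, lam), length(species))
    tgt <- rep(genes, counts)
    support <- if (tf == "FOXJ1") {
      unlist(lapply(counts[counts > 0], seq_len))
    } else {
      unlist(lapply(counts[counts > 0],
                    function(k) sample(species, k)))
    }
    if (length(tgt) > 0L) {
      reg_rows[[tf]] <- tibble::tibble(tf = tf, target = tgt,
                                       support = as.character(support))
    }
  }
  regulome <- dplyr::bind_rows(reg_rows)

  # --- annotation text --------------------------------------------------
  ciliary_texts <- c("strong cilia staining in airway epithelium",
                     "cilium expression detected in fallopian tube",
                     "localizes to the centrosome during mitosis",
                     "sperm flagellum tail protein",
                     "cilia positivity observed in renal tubules")
  neutral_texts <- c("ubiquitous nuclear expression",
                     "cytoplasmic expression in most tissues",
                     "membrane protein of unknown function")
  keyword_p <- ifelse(is_cil, p$text_keyword_p_ciliary,
                      p$text_keyword_p_background)
  has_kw <- stats::runif(p$n_genes) < keyword_p
  anno <- tibble::tibble(
    gene = c(genes[has_kw], genes),
    text = c(sample(ciliary_texts, sum(has_kw), replace = TRUE),
             sample(neutral_texts, p$n_genes, replace = TRUE))
  )
  anno <- anno[order(anno$gene, anno$text), ]

  truth <- tibble::tibble(gene = genes,
                          label = ifelse(is_cil, "ciliary", "background"))

  bench <- structure(list(
    params = p, genes = genes, ciliary = ciliary, gscg = gscg, ncg = ncg,
    organisms = tibble::tibble(organism = organisms, ciliated = ciliated),
    blast = blast,
    expression = list(
      human = c(ds_human, list(tag = "human_airway", log_transform = FALSE,
                               map = NULL)),
      worm = c(ds_worm, list(tag = "worm_neurons", log_transform = TRUE,
                             map = worm_map))),
    ppi = ppi, regulome = regulome, annotations = anno, truth = truth,
    dir = dir), class = "synthetic_benchmark")
  if (!is.null(dir)) write_benchmark(bench, dir)
  bench
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf("synthetic benchmark: %d genes (%d planted ciliary), seed %d\n",
              x$params$n_genes, x$params$n_ciliary, x$params$seed))
  invisible(x)
}

# write every benchmark input in the pipeline's file formats
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(name) file.path(dir, name)
  writeLines(bench$genes, fp("genes.txt"))
  writeLines(bench$gscg, fp("gscg.txt"))
  writeLines(bench$ncg, fp("ncg.txt"))
  utils::write.table(bench$blast, fp("blast_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(o = bench$organisms$organism,
               c = as.integer(bench$organisms$ciliated)),
    fp("organisms.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  for (name in names(bench$expression)) {
    ds <- bench$expression[[name]]
    mat <- as.data.frame(ds$mat)
    utils::write.table(data.frame(gene = rownames(ds$mat), mat,
                                  check.names = FALSE),
                       fp(sprintf("expr_%s.tsv", name)), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
    utils::write.table(data.frame(cell = names(ds$groups), group = ds$groups),
                       fp(sprintf("cells_%s.tsv", name)), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    if (!is.null(ds$map)) {
      utils::write.table(ds$map, fp(sprintf("ortholog_map_%s.tsv", name)),
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  utils::write.table(bench$ppi, fp("interactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(bench$regulome, fp("regulome.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(bench$annotations, fp("annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv_plain(bench$truth, fp("truth.tsv"))
  config <- list(
    genes = "genes.txt",
    labels = list(positives = "gscg.txt", negatives = "ncg.txt"),
    phylo = list(hits = "blast_hits.tsv", organisms = "organisms.tsv"),
    scrna = list(datasets = lapply(names(bench$expression), function(name) {
      ds <- bench$expression[[name]]
      d <- list(matrix = sprintf("expr_%s.tsv", name),
                cells = sprintf("cells_%s.tsv", name),
                tag = ds$tag, log_transform = ds$log_transform)
      if (!is.null(ds$map)) d$map <- sprintf("ortholog_map_%s.tsv", name)
      d
    })),
    ppi = list(interactions = "interactions.tsv"),
    tfnet = list(regulome = "regulome.tsv"),
    textmine = list(annotations = "annotations.tsv"),
    truth = "truth.tsv"
  )
  yaml::write_yaml(config, fp("config.yaml"))
  invisible(dir)
}

#' Ground-truth evaluation labels of a benchmark
#'
#' Planted ciliary genes versus background genes — the generator's truth,
#' as opposed to the GSCG/NCG lists used for training (GSCG is a proper
#' subset of the planted class, NCG of the background).
#'
#' @param bench A `synthetic_benchmark`.
#' @return A [labeled_gene_sets()] object.
#' @export
benchmark_truth <- function(bench) {
  stopifnot(inherits(bench, "synthetic_benchmark"))
  labeled_gene_sets(bench$truth$gene[bench$truth$label == "ciliary"],
                    bench$truth$gene[bench$truth$label == "background"])
}
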