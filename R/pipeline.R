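#' Run the full scoring pipeline from a config
#'
#' Executes every evidence scorer (phylogenetic profiling, single-cell
#' specificity, protein interactions, TF network, text mining) named in the
#' config, learns F1 weights on a stratified train split of the GSCG/NCG
#' labels, computes the integrated ciliary score, and evaluates every
#' method by ROC/AUC on the held-out test split (and on the generator's
#' ground truth when the config names a truth file). Evidence sections
#' missing from the config are skipped with a warning and carry weight 0.
#'
#' @param config Path to a YAML config, a directory containing
#'   `config.yaml`, or an equivalent named list. File paths inside the
#'   config are resolved relative to the config's directory.
#' @param output_dir Optional directory for the result TSVs and the run
#'   manifest.
#' @param seed Integer seed for the label split.
#' @param train_frac Fraction of each label class used to learn F1 weights.
#' @param scrna_mode Dataset combination mode, `"mean"` or
#'   `"intersection-count"`.
#' @param top_clusters Number of top ciliary clusters flagged by the
#'   phylogenetic scorer (default 2); set NULL to use the enrichment rule.
#' @param min_fold Enrichment rule threshold when `top_clusters` is NULL.
#' @param k Number of profile clusters.
#' @param rescale Min-max rescale method scores before weighting.
#' @return List with `scores` (gene x method tibble plus integrated score
#'   and rank), `weights`, `auc` (test-split AUCs), `auc_truth` (NULL
#'   without a truth file), `roc` points for the integrated score, and the
#'   label `split`.
#' @export
run_pipeline <- function(config, output_dir = NULL, seed = 1,
                         train_frac = 0.7, scrna_mode = "mean",
                         top_clusters = 2, min_fold = 5, k = 40,
                         rescale = TRUE) {
  if (is.character(config)) {
    path <- if (dir.exists(config)) file.path(config, "config.yaml") else config
    base <- dirname(path)
    config <- yaml::read_yaml(path)
  } else {
    base <- "."
  }
  resolve <- function(f) if (is.null(f)) NULL else file.path(base, f)

  genes <- read_gene_list(resolve(config$genes))
  labels <- read_labeled_gene_sets(resolve(config$labels$positives),
                                   resolve(config$labels$negatives))
  split <- split_labels(labels, train_frac = train_frac, seed = seed)

  score_list <- list()
  skipped <- character(0)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (!is.null(config$phylo)) {
    score_list$phylo <- run_stage("phylo", {
      hits <- read_blast_hits(resolve(config$phylo$hits))
      panel <- read_organism_panel(resolve(config$phylo$organisms))
      score_phylo(hits, genes, panel, labels, k = k,
                  top_clusters = top_clusters, min_fold = min_fold)
    })
  } else { skipped <- c(skipped, "phylo"); warning("no phylo input configured; method weight 0") }

  if (!is.null(config$scrna)) {
    score_list$scrna <- run_stage("scrna", {
      datasets <- list(); maps <- list()
      for (i in seq_along(config$scrna$datasets)) {
        d <- config$scrna$datasets[[i]]
        mat <- read_expression_matrix(resolve(d$matrix))
        groups <- read_cell_groups(resolve(d$cells))
        datasets[[i]] <- expression_dataset(
          mat, groups, tag = d$tag %||% sprintf("dataset%d", i),
          log_transform = isTRUE(d$log_transform))
        maps[i] <- list(if (!is.null(d$map)) read_ortholog_map(resolve(d$map)))
      }
      s <- score_scrna(datasets, maps = maps, mode = scrna_mode)
      s[s$gene %in% genes, ]
    })
  } else { skipped <- c(skipped, "scrna"); warning("no scrna input configured; method weight 0") }

  if (!is.null(config$ppi)) {
    score_list$ppi <- run_stage("ppi", {
      map <- if (!is.null(config$ppi$map)) read_ortholog_map(resolve(config$ppi$map))
      score_ppi(resolve(config$ppi$interactions), labels, genes = genes,
                map = map)
    })
  } else { skipped <- c(skipped, "ppi"); warning("no ppi input configured; method weight 0") }

  if (!is.null(config$tfnet)) {
    score_list$tfnet <- run_stage("tfnet", {
      map <- if (!is.null(config$tfnet$map)) read_ortholog_map(resolve(config$tfnet$map))
      score_tfnet(resolve(config$tfnet$regulome), map = map, genes = genes)
    })
  } else { skipped <- c(skipped, "tfnet"); warning("no tfnet input configured; method weight 0") }

  if (!is.null(config$textmine)) {
    score_list$textmine <- run_stage("textmine", {
      score_textmine(resolve(config$textmine$annotations), genes = genes)
    })
  } else { skipped <- c(skipped, "textmine"); warning("no textmine input configured; method weight 0") }

  if (length(score_list) == 0L) stop("no evidence inputs configured")

  m <- method_score_matrix(score_list, genes = genes, rescale = rescale)
  result <- evaluate_methods(m, split$train, split$test)
  if (length(skipped) > 0L) {
    result$weights <- dplyr::bind_rows(
      result$weights,
      tibble::tibble(method = skipped, threshold = NA_real_, f1 = 0))
  }

  auc_truth <- NULL
  if (!is.null(config$truth)) {
    truth_df <- utils::read.table(resolve(config$truth), sep = "\t",
                                  header = TRUE, stringsAsFactors = FALSE)
    truth <- labeled_gene_sets(truth_df$gene[truth_df$label == "ciliary"],
                               truth_df$gene[truth_df$label == "background"])
    auc_truth <- evaluate_methods(m, split$train, truth)$auc
  }

  roc_integrated <- roc_auc(
    stats::setNames(result$scores$integrated_score, result$scores$gene),
    split$test)

  out <- list(scores = result$scores, weights = result$weights,
              auc = result$auc, auc_truth = auc_truth,
              roc = roc_integrated$points, split = split)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    ranked <- out$scores[order(out$scores$rank), ]
    write_tsv_plain(ranked, file.path(output_dir, "scores.tsv"))
    write_tsv_plain(out$weights, file.path(output_dir, "weights.tsv"))
    write_tsv_plain(out$auc, file.path(output_dir, "auc.tsv"))
    if (!is.null(out$auc_truth)) {
      write_tsv_plain(out$auc_truth, file.path(output_dir, "auc_truth.tsv"))
    }
    write_tsv_plain(out$roc, file.path(output_dir, "roc_integrated.tsv"))
    manifest <- list(
      seed = seed, train_frac = train_frac, scrna_mode = scrna_mode,
      top_clusters = top_clusters, min_fold = min_fold, k = k,
      rescale = rescale,
      package_version = as.character(utils::packageVersion("ciliascore")),
      r_version = R.version.string,
      methods = names(score_list)
    )
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
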