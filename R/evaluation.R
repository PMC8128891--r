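#' Balanced accuracy
#'
#' Mean over the observed true classes of the per-class recall: the number
#' of correctly predicted samples of each class normalised by the class
#' size. Equals plain accuracy when classes are exactly balanced, and 0.5
#' for any constant predictor on a two-class problem.
#'
#' @param y_true,y_pred vectors of class labels (equal length).
#' @return scalar in [0, 1].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- unique(y_true)
  recalls <- vapply(classes, function(cl) {
    idx <- y_true == cl
    mean(y_pred[idx] == cl)
  }, numeric(1))
  mean(recalls)
}

#' ROC curve and AUC from a score vector
#'
#' Standard ROC sweep over the distinct score thresholds (higher score =
#' more positive); AUC by trapezoidal integration, which coincides with
#' the Mann-Whitney rank statistic.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) positive-class indicator.
#' @return list with \code{roc} (data.frame fpr, tpr) and \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("need both positive and negative samples for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  # collapse tied scores: keep the last point of each tie block
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tpr <- c(0, tp[keep] / sum(lab))
  fpr <- c(0, fp[keep] / sum(!lab))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluation-classifier configuration
#'
#' @param subset_size genes per evaluated subset (default 10).
#' @param n_runs repeated subset draws per strategy (default 100).
#' @param n_permutation random subsets for the permutation null
#'   (default 400).
#' @param top_pool pool size from which top-CC subsets are drawn
#'   (default 40).
#' @param hidden_width hidden-layer width of the evaluation network
#'   (default 16).
#' @param epochs,learning_rate full-batch Adam schedule.
#' @param seed integer seed.
#' @return list of class \code{eval_config}.
#' @export
eval_config <- function(subset_size = 10, n_runs = 100, n_permutation = 400,
                        top_pool = 40, hidden_width = 16, epochs = 200,
                        learning_rate = 0.01, seed = 0) {
  if (subset_size > top_pool) stop("subset_size must be <= top_pool")
  if (n_runs < 1) stop("n_runs must be >= 1")
  structure(list(subset_size = as.integer(subset_size),
                 n_runs = as.integer(n_runs),
                 n_permutation = as.integer(n_permutation),
                 top_pool = as.integer(top_pool),
                 hidden_width = as.integer(hidden_width),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "eval_config")
}

#' Train and score the evaluation classifier on a gene subset
#'
#' A small feed-forward network (one hidden layer, logistic output,
#' binary cross-entropy loss) is fed only the chosen genes and trained to
#' separate tumor from normal samples of one tissue, using training
#' samples only; balanced accuracy, ROC and AUC are computed on the test
#' samples only.
#'
#' @param expr gene x sample expression matrix (TPM scale).
#' @param metadata metadata with tissue, state and split columns.
#' @param genes character vector of gene ids to feed the classifier.
#' @param tissue tissue whose tumor/normal samples are evaluated.
#' @param config an [eval_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return list: balanced_accuracy, auc, roc, scores and labels on the
#'   test samples.
#' @export
train_eval_classifier <- function(expr, metadata, genes, tissue, config,
                                  seed = config$seed) {
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g) > 0)
    stop("subset gene(s) absent from matrix: ",
         paste(missing_g, collapse = ", "))
  if (length(genes) == 0) stop("empty gene subset")
  keep <- metadata$tissue == tissue
  md <- metadata[keep, , drop = FALSE]
  sub <- log_transform(expr[genes, md$sample_id, drop = FALSE])
  X <- t(sub)
  y <- as.numeric(md$state == "tumor")
  tr <- md$split == "train"; te <- md$split == "test"
  if (!any(tr) || !any(te)) stop("need both train and test samples")
  center <- colMeans(X[tr, , drop = FALSE])
  scl <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  X <- sweep(sweep(X, 2L, center, "-"), 2L, scl, "/")

  layers <- with_seed(derive_seed(seed, "evalnet"), {
    nn_init(c(length(genes), config$hidden_width, 1L), c("relu", "linear"))
  })
  state <- nn_adam_init(layers)
  Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
  for (t in seq_len(config$epochs)) {
    fw <- nn_forward(layers, Xtr, keep = TRUE)
    a <- 1 / (1 + exp(-pmin(pmax(fw$out, -30), 30)))
    d_out <- (a - ytr) / length(ytr)  # BCE-with-logits gradient
    grads <- nn_backward(layers, fw$cache, d_out)$grads
    up <- nn_adam_step(layers, grads, state, config$learning_rate, t)
    layers <- up$layers; state <- up$state
  }
  z_te <- nn_forward(layers, X[te, , drop = FALSE])[, 1]
  sc_te <- 1 / (1 + exp(-pmin(pmax(z_te, -30), 30)))
  y_te <- y[te]
  pred <- ifelse(sc_te > 0.5, "tumor", "normal")
  ba <- balanced_accuracy(ifelse(y_te == 1, "tumor", "normal"), pred)
  ra <- roc_auc(sc_te, y_te == 1)
  list(balanced_accuracy = ba, auc = ra$auc, roc = ra$roc,
       scores = sc_te, labels = y_te)
}

#' Compare gene-subset selection strategies
#'
#' For each strategy and each of \code{n_runs} seeded draws, a
#' \code{subset_size}-gene subset is drawn by the strategy's rule, the
#' evaluation classifier is trained and its test balanced accuracy and AUC
#' recorded. Strategies: \code{top_cc_tissue} and \code{top_cc_all}
#' (uniform draws from the top \code{top_pool} of the respective ranking),
#' \code{literature} (draws from a curated gene list), \code{deg} (draws
#' from the DE genes), \code{random} (any genes), \code{non_deg}
#' (non-DE genes), \code{bottom_cc} (draws from the \code{top_pool}
#' lowest-ranked genes).
#'
#' @param expr,metadata,tissue,config as in [train_eval_classifier()].
#' @param ranking_tissue,ranking_all \code{gene_ranking}s for the
#'   tissue-specific and all-class schemes.
#' @param de_result a \code{de_result} for the tissue.
#' @param literature_genes character vector for the literature strategy
#'   (optional).
#' @param strategies which strategies to run.
#' @return object of class \code{evaluation_report}: list with
#'   \code{metrics} (data.frame strategy, run, balanced_accuracy, auc) and
#'   \code{summary} (per-strategy medians).
#' @export
compare_subsets <- function(expr, metadata, tissue,
                            ranking_tissue, ranking_all, de_result,
                            literature_genes = NULL, config = eval_config(),
                            strategies = c("top_cc_tissue", "top_cc_all",
                                           "literature", "deg", "random",
                                           "non_deg", "bottom_cc")) {
  k <- config$subset_size
  all_genes <- rownames(expr)
  de_genes <- intersect(de_result$gene_id[de_result$is_de], all_genes)
  non_de_genes <- setdiff(all_genes, de_result$gene_id[de_result$is_de])
  pools <- list(
    top_cc_tissue = ranking_tissue$gene_id[seq_len(min(config$top_pool,
                                                       nrow(ranking_tissue)))],
    top_cc_all = ranking_all$gene_id[seq_len(min(config$top_pool,
                                                 nrow(ranking_all)))],
    literature = intersect(literature_genes, all_genes),
    deg = de_genes,
    random = all_genes,
    non_deg = non_de_genes,
    bottom_cc = rev(ranking_tissue$gene_id)[seq_len(min(config$top_pool,
                                                        nrow(ranking_tissue)))]
  )
  rows <- list()
  for (strat in strategies) {
    pool <- pools[[strat]]
    if (length(pool) < k) {
      warning("strategy ", strat, " skipped: pool smaller than subset_size")
      next
    }
    for (r in seq_len(config$n_runs)) {
      sd_r <- derive_seed(config$seed, paste0(strat, ":", r))
      subset <- with_seed(sd_r, sample(pool, k))
      fit <- train_eval_classifier(expr, metadata, subset, tissue, config,
                                   seed = sd_r)
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = strat, run = r,
        balanced_accuracy = fit$balanced_accuracy, auc = fit$auc,
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(metrics, metrics$strategy),
    function(d) data.frame(strategy = d$strategy[1],
                           median_balanced_accuracy =
                             stats::median(d$balanced_accuracy),
                           median_auc = stats::median(d$auc),
                           stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(metrics = metrics, summary = summary, config = config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation report (", max(x$metrics$run), "runs/strategy )\n")
  print(x$summary[order(-x$summary$median_balanced_accuracy), ],
        row.names = FALSE)
  invisible(x)
}

#' Permutation p-value for an observed subset AUC
#'
#' Repeatedly draws a random gene subset of the same size, trains and
#' tests the evaluation classifier, and reports the fraction of random
#' AUCs strictly above the observed one. When no random AUC exceeds the
#' observed value the p-value is reported as below the procedure's
#' resolution, i.e. floored at 1/n_permutation.
#'
#' @param observed_auc AUC of the subset under test.
#' @param expr,metadata,tissue,config as in [train_eval_classifier()].
#' @param seed integer seed.
#' @return list: p (count/n), p_floor (max(p, 1/n)), label (e.g.
#'   "< 1/400" when the count is 0), and the vector of random AUCs.
#' @export
permutation_pvalue <- function(observed_auc, expr, metadata, tissue,
                               config = eval_config(), seed = 0) {
  n <- config$n_permutation
  if (n < 1) stop("n_permutation must be >= 1")
  all_genes <- rownames(expr)
  aucs <- vapply(seq_len(n), function(r) {
    sd_r <- derive_seed(seed, paste0("perm", r))
    subset <- with_seed(sd_r, sample(all_genes, config$subset_size))
    train_eval_classifier(expr, metadata, subset, tissue, config,
                          seed = sd_r)$auc
  }, numeric(1))
  cnt <- sum(aucs > observed_auc)
  p <- cnt / n
  list(p = p, p_floor = max(p, 1 / n),
       label = if (cnt == 0) paste0("< 1/", n) else format(p),
       random_aucs = aucs)
}

#' Curated prostate-cancer biomarker genes from the literature
#'
#' A static list of genes reported as prostate-cancer biomarkers in expert
#' reviews, used by the "literature" evaluation strategy on real data
#' (synthetic runs substitute a planted truth category). Also shipped as
#' \code{inst/extdata/literature_pca_biomarkers.tsv}.
#'
#' @return character vector of gene symbols.
#' @export
literature_pca_biomarkers <- function() {
  c("HNF1B", "KLK2", "MYC", "NFE2L2", "POU5F1B", "PTEN", "RNASEL",
    "SLC45A3", "SOX2", "SRD5A2", "BRCA1", "BRCA2", "HOXB13", "TP53",
    "RAD51D", "PALB2", "NCOA3", "MSR1", "MSH2", "MLH1", "AIG1", "ATM",
    "BRAF", "CDK12", "CDKN1B", "CHEK2", "ELAC2", "HIF1A")
}
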