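#' Configuration for the synthetic expression generator
#'
#' The generator emulates a multi-cohort tumor/normal design: three tissues,
#' two disease states, strong class imbalance including one tissue with no
#' normal samples at all, log-scale tissue baseline differences, and three
#' disjoint categories of planted markers:
#' \itemize{
#'   \item tissue markers - shifted in every sample of one tissue;
#'   \item shared disease markers - shifted in tumor samples of all tissues
#'     (the cross-cancer signal);
#'   \item private disease markers - shifted in tumor samples of one tissue
#'     only.
#' }
#' Expression is built additively on the log2 scale and exponentiated, so
#' marker shifts are fold changes on the TPM scale; log-normal noise is
#' added per entry.
#'
#' @param n_genes total number of genes.
#' @param tissues character vector of tissue labels.
#' @param samples_per_class data.frame with columns tissue, state, n giving
#'   the class sizes; zero is allowed (default mirrors a scaled-down
#'   tumor-heavy cohort with no ovary normals).
#' @param n_tissue_markers planted tissue markers per tissue.
#' @param n_shared_disease_markers planted cross-cancer disease markers.
#' @param n_private_disease_markers planted tissue-specific disease markers
#'   per tissue.
#' @param effect_size log2-scale mean shift carried by every marker.
#' @param noise_sd log2-scale standard deviation of the per-entry noise.
#' @param baseline_log_mean,baseline_log_sd parameters of the per-gene
#'   baseline draw (normal on log2 scale, i.e. log-normal TPM baselines).
#' @param test_fraction fraction of each class routed to the test split.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a list of class \code{synth_config}.
#' @export
synth_config <- function(n_genes = 500,
                         tissues = c("breast", "ovary", "prostate"),
                         samples_per_class = NULL,
                         n_tissue_markers = 10,
                         n_shared_disease_markers = 20,
                         n_private_disease_markers = 10,
                         effect_size = 2,
                         noise_sd = 0.5,
                         baseline_log_mean = 3,
                         baseline_log_sd = 2,
                         test_fraction = 0.25,
                         seed = 0) {
  if (is.null(samples_per_class)) {
    samples_per_class <- data.frame(
      tissue = rep(c("ovary", "prostate", "breast"), each = 2),
      state  = rep(c("tumor", "normal"), 3),
      n      = c(24L, 0L, 40L, 16L, 36L, 4L),
      stringsAsFactors = FALSE
    )
    samples_per_class <-
      samples_per_class[samples_per_class$tissue %in% tissues, , drop = FALSE]
  }
  cfg <- list(
    n_genes = as.integer(n_genes), tissues = tissues,
    samples_per_class = samples_per_class,
    n_tissue_markers = as.integer(n_tissue_markers),
    n_shared_disease_markers = as.integer(n_shared_disease_markers),
    n_private_disease_markers = as.integer(n_private_disease_markers),
    effect_size = effect_size, noise_sd = noise_sd,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    test_fraction = test_fraction, seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  counts <- c(cfg$n_genes, cfg$n_tissue_markers, cfg$n_shared_disease_markers,
              cfg$n_private_disease_markers, cfg$samples_per_class$n)
  if (any(counts < 0)) stop("configuration error: negative count")
  n_markers <- cfg$n_tissue_markers * length(cfg$tissues) +
    cfg$n_shared_disease_markers +
    cfg$n_private_disease_markers * length(cfg$tissues)
  if (n_markers > cfg$n_genes)
    stop("configuration error: marker counts (", n_markers,
         ") exceed n_genes (", cfg$n_genes, ")")
  if (cfg$noise_sd < 0) stop("configuration error: negative noise_sd")
  bad <- !cfg$samples_per_class$state %in% c("tumor", "normal")
  if (any(bad)) stop("configuration error: state must be tumor/normal")
  invisible(cfg)
}

#' Generate a synthetic expression dataset with planted markers
#'
#' See [synth_config()] for the generative model. Columns of the returned
#' TPM matrix sum to 1e6; \code{truth} records which genes carry which
#' planted shift (categories are disjoint by construction).
#'
#' @param config a \code{synth_config}.
#' @return list of class \code{synth_dataset} with elements
#'   \code{expression} (gene x sample TPM matrix), \code{metadata}
#'   (sample_id, tissue, state, source, split), \code{truth} (named list
#'   of gene-id character vectors: \code{tissue:<t>}, \code{shared_disease},
#'   \code{private_disease:<t>}), and \code{truth_signs} (named +1/-1 per
#'   marker gene: direction of its planted shift).
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  with_seed(config$seed, {
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    baseline <- stats::rnorm(config$n_genes, config$baseline_log_mean,
                             config$baseline_log_sd)
    names(baseline) <- genes
    # markers are planted outside the top-expressed quartile: disease genes
    # are rarely the dominant housekeeping transcripts, and keeping the
    # planted mass small stops the TPM rescale from pushing a systematic
    # class shift onto non-marker genes
    n_markers <- config$n_tissue_markers * length(config$tissues) +
      config$n_shared_disease_markers +
      config$n_private_disease_markers * length(config$tissues)
    eligible <- genes[baseline <= stats::quantile(baseline, 0.75)]
    if (n_markers > length(eligible))
      eligible <- genes[order(baseline)][seq_len(max(n_markers,
                                                     length(eligible)))]
    pool <- sample(eligible)
    truth <- list()
    take <- function(k) {
      if (k == 0) return(character(0))
      picked <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      picked
    }
    for (t in config$tissues)
      truth[[paste0("tissue:", t)]] <- take(config$n_tissue_markers)
    truth[["shared_disease"]] <- take(config$n_shared_disease_markers)
    for (t in config$tissues)
      truth[[paste0("private_disease:", t)]] <-
        take(config$n_private_disease_markers)
    # each marker is up- or down-regulated with equal probability; signs
    # are part of the recorded ground truth
    all_markers <- unlist(truth, use.names = FALSE)
    signs <- stats::setNames(sample(c(-1, 1), length(all_markers),
                                    replace = TRUE), all_markers)

    spc <- config$samples_per_class
    spc <- spc[spc$n > 0, , drop = FALSE]
    tissue <- rep(spc$tissue, spc$n)
    state <- rep(spc$state, spc$n)
    n_samples <- length(tissue)
    if (n_samples == 0) stop("configuration error: no samples requested")
    sample_id <- sprintf("%s_%s_%03d", tissue,
                         ifelse(state == "tumor", "T", "N"),
                         stats::ave(seq_len(n_samples),
                                    paste(tissue, state),
                                    FUN = seq_along))

    logm <- matrix(baseline, config$n_genes, n_samples,
                   dimnames = list(genes, sample_id))
    add_shift <- function(gset, cols) {
      if (length(gset) > 0 && any(cols))
        logm[gset, cols] <<- logm[gset, cols] +
          signs[gset] * config$effect_size
    }
    for (t in config$tissues) {
      cols <- tissue == t
      add_shift(truth[[paste0("tissue:", t)]], cols)
      add_shift(truth[[paste0("private_disease:", t)]],
                cols & state == "tumor")
    }
    add_shift(truth[["shared_disease"]], state == "tumor")
    if (config$noise_sd > 0)
      logm <- logm + matrix(stats::rnorm(length(logm), 0, config$noise_sd),
                            nrow(logm), ncol(logm))
    expr <- 2^logm
    expr <- sweep(expr, 2L, colSums(expr), "/") * 1e6

    metadata <- data.frame(
      sample_id = sample_id, tissue = tissue, state = state,
      source = "synthetic", split = "train", stringsAsFactors = FALSE
    )
  })
  metadata <- split_train_test(metadata, config$test_fraction,
                               seed = derive_seed(config$seed, "split"))
  ds <- list(expression = expr, metadata = metadata, truth = truth,
             truth_signs = signs, config = config)
  class(ds) <- "synth_dataset"
  ds
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("synthetic expression dataset:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples\n")
  cat("classes:\n")
  print(table(joint_labels(x$metadata)))
  cat("planted markers:",
      paste(sprintf("%s=%d", names(x$truth), lengths(x$truth)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Expression and metadata use the same TSV dialects [read_expression()] and
#' [read_metadata()] read; the truth table is a two-column TSV
#' (gene_id, category).
#'
#' @param dataset a \code{synth_dataset}.
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_expr <- file.path(dir, "expression.tsv")
  p_meta <- file.path(dir, "metadata.tsv")
  p_truth <- file.path(dir, "truth.tsv")
  write_expression(dataset$expression, p_expr)
  write_metadata(dataset$metadata, p_meta)
  truth_df <- data.frame(
    gene_id = unlist(dataset$truth, use.names = FALSE),
    category = rep(names(dataset$truth), lengths(dataset$truth)),
    stringsAsFactors = FALSE
  )
  utils::write.table(truth_df, p_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression = p_expr, metadata = p_meta, truth = p_truth))
}

#' Generate random signed acyclic pathway graphs
#'
#' Each pathway samples \code{genes_per_pathway} gene identifiers, imposes a
#' random topological order and draws each forward edge independently with
#' probability \code{edge_density}; an edge is repressive (beta = -1) with
#' probability \code{repression_fraction}, activating (beta = +1) otherwise.
#' Graphs are acyclic by construction.
#'
#' @param n_pathways number of graphs.
#' @param genes_per_pathway nodes per graph (>= 1).
#' @param edge_density probability of each forward edge, in [0, 1].
#' @param repression_fraction probability an edge is repressive, in [0, 1].
#' @param seed integer seed.
#' @param genes optional gene-id universe to sample node labels from;
#'   defaults to fresh identifiers per pathway.
#' @return list of \code{pathway_graph} objects (fields: id, nodes,
#'   edges = data.frame(from, to, beta)).
#' @export
generate_pathways <- function(n_pathways, genes_per_pathway,
                              edge_density = 0.3, repression_fraction = 0.25,
                              seed = 0, genes = NULL) {
  if (genes_per_pathway < 1)
    stop("configuration error: genes_per_pathway must be >= 1")
  if (edge_density < 0 || edge_density > 1)
    stop("configuration error: edge_density outside [0, 1]")
  if (repression_fraction < 0 || repression_fraction > 1)
    stop("configuration error: repression_fraction outside [0, 1]")
  with_seed(seed, {
    lapply(seq_len(n_pathways), function(i) {
      nodes <- if (is.null(genes)) {
        sprintf("p%02d_g%03d", i, seq_len(genes_per_pathway))
      } else {
        sample(genes, genes_per_pathway,
               replace = genes_per_pathway > length(genes))
      }
      nodes <- unique(nodes)
      ord <- sample(nodes)  # topological order
      from <- character(0); to <- character(0)
      if (length(ord) >= 2) {
        for (a in seq_len(length(ord) - 1)) {
          targets <- ord[(a + 1):length(ord)]
          hit <- stats::runif(length(targets)) < edge_density
          from <- c(from, rep(ord[a], sum(hit)))
          to <- c(to, targets[hit])
        }
      }
      beta <- ifelse(stats::runif(length(from)) < repression_fraction, -1, 1)
      pathway_graph(sprintf("pathway_%02d", i), nodes,
                    data.frame(from = from, to = to, beta = beta,
                               stringsAsFactors = FALSE))
    })
  })
}
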