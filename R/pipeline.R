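#' End-to-end pipeline configuration
#'
#' Exactly one of \code{synthetic} (a [synth_config()]) or the pair
#' \code{expression_path}/\code{metadata_path} must be supplied. All stage
#' seeds are derived deterministically from the global seed, so a rerun
#' with the same configuration reproduces every artifact.
#'
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param synthetic optional [synth_config()] describing a generated cohort.
#' @param expression_path,metadata_path optional TSV inputs for a real
#'   cohort.
#' @param tissue tissue evaluated for tumor/normal discrimination.
#' @param mlcae optional [mlcae_config()] overrides as a named list (e.g.
#'   \code{list(epochs = 50, encoder_widths = c(128, 32))}).
#' @param de named list of [de_test()] threshold overrides.
#' @param evaluation an [eval_config()].
#' @param attribution named list: \code{n_draws}, \code{background_size},
#'   \code{balanced} (class-balanced background draw, default TRUE).
#' @param pathways either a pathway TSV path or a named list of
#'   [generate_pathways()] arguments (plus \code{plant} = TRUE to add one
#'   pathway built from planted disease markers on synthetic data).
#' @param top_n_pathway_genes ranked genes feeding the impact analysis.
#' @param seed global integer seed.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir,
                            synthetic = NULL,
                            expression_path = NULL, metadata_path = NULL,
                            tissue = "prostate",
                            mlcae = list(),
                            de = list(),
                            evaluation = eval_config(),
                            attribution = list(n_draws = 256,
                                               background_size = 100),
                            pathways = list(n_pathways = 20,
                                            genes_per_pathway = 15,
                                            edge_density = 0.15,
                                            repression_fraction = 0.25,
                                            plant = TRUE),
                            top_n_pathway_genes = 1000,
                            seed = 0) {
  has_synth <- !is.null(synthetic)
  has_paths <- !is.null(expression_path) || !is.null(metadata_path)
  if (has_synth && has_paths)
    stop("configuration error: give either a synthetic block or input ",
         "paths, not both")
  if (!has_synth && !(is.character(expression_path) &&
                      is.character(metadata_path)))
    stop("configuration error: need a synthetic block or both input paths")
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 expression_path = expression_path,
                 metadata_path = metadata_path, tissue = tissue,
                 mlcae = mlcae, de = de, evaluation = evaluation,
                 attribution = attribution, pathways = pathways,
                 top_n_pathway_genes = top_n_pathway_genes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full discovery pipeline
#'
#' Stages: data (generate or load), model training, attribution and gene
#' ranking, differential expression, subset evaluation, permutation null,
#' pathway impact. Each stage writes its artifact under \code{out_dir};
#' a JSON manifest records the config snapshot, per-stage seeds and file
#' checksums. Any stage failure aborts with the stage name; artifacts of
#' completed stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list()
  artifacts <- list()
  stage_seed <- function(stage) {
    seeds[[stage]] <<- derive_seed(config$seed, stage)
    seeds[[stage]]
  }

  # -- data -----------------------------------------------------------------
  ds <- run_stage("data", {
    if (!is.null(config$synthetic)) {
      scfg <- config$synthetic
      scfg$seed <- stage_seed("data")
      d <- generate_dataset(scfg)
      paths <- write_dataset(d, file.path(config$out_dir, "data"))
      artifacts$data <- unname(paths)
      d
    } else {
      stage_seed("data")
      expr <- read_expression(config$expression_path)
      md <- read_metadata(config$metadata_path)
      artifacts$data <- c(config$expression_path, config$metadata_path)
      list(expression = expr, metadata = md, truth = NULL)
    }
  })
  expr <- ds$expression
  md <- ds$metadata
  labels <- joint_labels(md)
  train_idx <- md$split == "train"
  test_idx <- md$split == "test"

  # -- model ----------------------------------------------------------------
  model <- run_stage("model", {
    args <- utils::modifyList(
      list(n_genes = nrow(expr), seed = stage_seed("model")), config$mlcae)
    mcfg <- do.call(mlcae_config, args)
    m <- build_mlcae(mcfg, levels(labels))
    m <- train_mlcae(m, expr[, train_idx, drop = FALSE], labels[train_idx])
    p_hist <- file.path(config$out_dir, "training_history.tsv")
    utils::write.table(m$history, p_hist, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p_model <- file.path(config$out_dir, "model.rds")
    saveRDS(m, p_model)
    artifacts$model <- c(p_model, p_hist)
    m
  })

  # -- attribution ----------------------------------------------------------
  rankings <- run_stage("attribution", {
    s <- stage_seed("attribution")
    bg <- draw_background(expr, md, n = config$attribution$background_size,
                          balanced = !isFALSE(config$attribution$balanced),
                          seed = s)
    att <- expected_gradients(model,
                              expr[, test_idx, drop = FALSE],
                              bg,
                              n_draws = config$attribution$n_draws,
                              seed = s)
    agg <- aggregate_attributions(att)
    r_all <- rank_genes(agg, "cc_all")
    r_tis <- rank_genes(agg, "cc_tissue", tissue = config$tissue)
    p_ranks <- file.path(config$out_dir, "ranks.tsv")
    write_ranking(rbind(r_all, r_tis), p_ranks)
    artifacts$attribution <- p_ranks
    list(all = r_all, tissue = r_tis, matrix = agg)
  })

  # -- differential expression ----------------------------------------------
  de <- run_stage("de", {
    stage_seed("de")
    keep <- md$tissue == config$tissue
    args <- utils::modifyList(
      list(expr = expr[, keep, drop = FALSE], groups = md$state[keep]),
      config$de)
    res <- do.call(de_test, args)
    p_de <- file.path(config$out_dir, "de.tsv")
    utils::write.table(res, p_de, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts$de <- p_de
    res
  })

  # -- evaluation -----------------------------------------------------------
  report <- run_stage("evaluation", {
    ecfg <- config$evaluation
    ecfg$seed <- stage_seed("evaluation")
    lit <- if (!is.null(ds$truth)) {
      # synthetic stand-in for the curated literature list: the planted
      # disease markers private to the evaluated tissue
      ds$truth[[paste0("private_disease:", config$tissue)]]
    } else {
      literature_pca_biomarkers()
    }
    strategies <- c("top_cc_tissue", "top_cc_all", "literature", "deg",
                    "random", "non_deg", "bottom_cc")
    rep <- compare_subsets(expr, md, config$tissue,
                           rankings$tissue, rankings$all, de,
                           literature_genes = lit, config = ecfg,
                           strategies = strategies)
    p_rep <- file.path(config$out_dir, "evaluation.tsv")
    utils::write.table(rep$metrics, p_rep, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts$evaluation <- p_rep
    rep
  })

  # -- permutation null -----------------------------------------------------
  perm <- run_stage("permutation", {
    s <- stage_seed("permutation")
    ecfg <- config$evaluation
    top_genes <- rankings$tissue$gene_id[seq_len(ecfg$subset_size)]
    obs <- train_eval_classifier(expr, md, top_genes, config$tissue, ecfg,
                                 seed = s)
    pv <- permutation_pvalue(obs$auc, expr, md, config$tissue, ecfg,
                             seed = s)
    p_perm <- file.path(config$out_dir, "permutation.json")
    jsonlite::write_json(list(observed_auc = obs$auc, p = pv$p,
                              p_floor = pv$p_floor, label = pv$label),
                         p_perm, auto_unbox = TRUE, digits = NA)
    artifacts$permutation <- p_perm
    pv
  })

  # -- pathway impact -------------------------------------------------------
  impact <- run_stage("pathways", {
    s <- stage_seed("pathways")
    pw <- if (is.character(config$pathways)) {
      read_pathways(config$pathways)
    } else {
      args <- config$pathways
      plant <- isTRUE(args$plant)
      args$plant <- NULL
      n_boot <- if (is.null(args$n_boot)) 2000 else args$n_boot
      args$n_boot <- NULL
      args$seed <- s
      args$genes <- rownames(expr)
      pws <- do.call(generate_pathways, args)
      if (plant && !is.null(ds$truth)) {
        marked <- ds$truth$shared_disease
        pws <- c(pws, with_seed(derive_seed(s, "plant"), {
          list(generate_pathways(1, length(marked), edge_density = 0.2,
                                 repression_fraction = 0, seed = s + 1L,
                                 genes = marked)[[1]])
        }))
        pws[[length(pws)]]$id <- "planted_pathway"
      }
      pws
    }
    res <- run_impact_analysis(rankings$all, de, pw,
                               top_n = config$top_n_pathway_genes,
                               n_boot = if (is.character(config$pathways))
                                 2000 else n_boot,
                               seed = s)
    p_imp <- file.path(config$out_dir, "impact.tsv")
    utils::write.table(res, p_imp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts$pathways <- p_imp
    res
  })

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed,
    stage_seeds = seeds,
    tissue = config$tissue,
    artifacts = artifacts,
    checksums = as.list(tools::md5sum(unlist(artifacts)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, dataset = ds, model = model,
                 rankings = rankings, de = de, evaluation = report,
                 permutation = perm, impact = impact))
}

#' Filter a cohort to advanced-disease samples
#'
#' Retains samples with at least one of: (1) a new tumor event (local
#' recurrence or distant metastasis), (2) biochemical evidence of disease
#' after remission, or (3) death due to cancer - each within five years of
#' initial diagnosis. The downstream pipeline is unchanged; only the
#' cohort shrinks.
#'
#' @param metadata sample metadata.
#' @param clinical data.frame with columns sample_id, new_tumor_event,
#'   biochemical_recurrence, cancer_death (logical) and
#'   years_from_diagnosis (numeric).
#' @param window_years event window (default 5).
#' @return the filtered metadata.
#' @export
advanced_cohort_filter <- function(metadata, clinical, window_years = 5) {
  need <- c("sample_id", "new_tumor_event", "biochemical_recurrence",
            "cancer_death", "years_from_diagnosis")
  miss <- setdiff(need, names(clinical))
  if (length(miss) > 0)
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  hit <- (clinical$new_tumor_event | clinical$biochemical_recurrence |
            clinical$cancer_death) &
    clinical$years_from_diagnosis <= window_years
  keep_ids <- clinical$sample_id[hit %in% TRUE]
  metadata[metadata$sample_id %in% keep_ids, , drop = FALSE]
}
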