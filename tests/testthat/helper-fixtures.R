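# shared fixtures, memoised so expensive objects are built once per run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small planted dataset used by model / attribution / evaluation tests
small_synth <- function() fixture("small_synth", function() {
  generate_dataset(synth_config(
    n_genes = 80, n_tissue_markers = 3, n_shared_disease_markers = 6,
    n_private_disease_markers = 3,
    samples_per_class = data.frame(
      tissue = rep(c("ovary", "prostate", "breast"), each = 2),
      state = rep(c("tumor", "normal"), 3),
      n = c(20L, 0L, 30L, 16L, 24L, 4L)),
    seed = 11))
})

small_model <- function() fixture("small_model", function() {
  ds <- small_synth()
  labels <- joint_labels(ds$metadata)
  tr <- ds$metadata$split == "train"
  cfg <- mlcae_config(nrow(ds$expression), latent_dim = 12,
                      encoder_widths = 32, epochs = 300, seed = 1)
  train_mlcae(build_mlcae(cfg, levels(labels)),
              ds$expression[, tr, drop = FALSE], labels[tr])
})

# hand-weighted, mildly nonlinear 6-gene model (linear encoder, softplus
# classification head); standardisation fixed to the identity so model
# inputs can be written directly
smooth_mlcae_6 <- function(seed = 4, n_classes = 3) {
  cfg <- mlcae_config(6, latent_dim = 3, encoder_widths = integer(0),
                      epochs = 1, l1_input = 0, seed = seed)
  m <- build_mlcae(cfg, paste0("class", seq_len(n_classes)))
  set.seed(seed)
  m$encoder[[1]]$W <- matrix(rnorm(6 * 3, 0, 0.5), 6, 3)
  m$encoder[[1]]$b <- rnorm(3, 0, 0.2)
  m$classifier[[1]]$W <- matrix(rnorm(3 * n_classes, 0, 0.7), 3, n_classes)
  m$classifier[[1]]$b <- rnorm(n_classes, 0, 0.2)
  m$std <- list(center = rep(0, 6), scale = rep(1, 6))
  m$genes <- sprintf("g%04d", 1:6)
  m
}

# expression matrix whose model-input rows equal X (samples x genes) under
# identity standardisation: log2(expr + 1) == X
expr_from_input <- function(X, genes) {
  E <- t(2^X - 1)
  rownames(E) <- genes
  colnames(E) <- paste0("s", seq_len(ncol(E)))
  E
}

# class-score closure of a model for exact Shapley cross-checks
mlcae_score_closure <- function(model, class_index) {
  function(Z) {
    colnames(Z) <- NULL
    latent <- ccbiomark:::nn_forward(model$encoder, Z)
    ccbiomark:::nn_forward(model$classifier, latent)[, class_index]
  }
}

# one full discovery run at the generator's default study conditions
# (500 genes, 120 samples, one tissue without normals), memoised per seed
# so several test blocks can share the trained model and rankings
acceptance_seed_run <- function(sd) fixture(paste0("acc_run_", sd), function() {
  ds <- generate_dataset(synth_config(seed = sd))
  labels <- joint_labels(ds$metadata)
  tr <- ds$metadata$split == "train"
  te <- !tr
  cfg <- mlcae_config(nrow(ds$expression), encoder_widths = c(128, 32),
                      epochs = 200, seed = sd)
  m <- train_mlcae(build_mlcae(cfg, levels(labels)),
                   ds$expression[, tr, drop = FALSE], labels[tr])
  bg <- draw_background(ds$expression, ds$metadata, 100, seed = sd + 104729)
  att <- expected_gradients(m, ds$expression[, te, drop = FALSE], bg,
                            n_draws = 128, seed = sd)
  agg <- aggregate_attributions(att)
  lab_te <- as.character(labels)[te]
  pred <- predict_mlcae(m, ds$expression[, te, drop = FALSE])$class
  maj <- names(which.max(table(labels[tr])))
  list(ds = ds,
       agg = agg,
       r_all = rank_genes(agg, "cc_all"),
       r_tis = rank_genes(agg, "cc_tissue", tissue = "prostate"),
       ba = balanced_accuracy(lab_te, pred),
       ba_majority = balanced_accuracy(lab_te, rep(maj, length(lab_te))))
})

# tiny named expression matrix builder
toy_expr <- function(values, genes, samples) {
  matrix(values, length(genes), length(samples),
         dimnames = list(genes, samples))
}
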