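#' MLC-AE configuration
#'
#' The multi-label classification autoencoder compresses a standardised
#' log2(TPM + 1) profile to a low-dimensional latent code (default 12) that
#' is simultaneously decoded back to the input and mapped by a single
#' classification head to scores over the joint (tissue, state) classes.
#' The classification loss is one minus the cosine similarity between the
#' one-hot class vector and the (non-negative) classifier output; the
#' reconstruction loss is mean-squared error.
#'
#' @param n_genes input width (number of genes).
#' @param latent_dim latent width (default 12).
#' @param encoder_widths hidden widths of the encoder, input to latent; the
#'   decoder mirrors them.
#' @param classifier_widths hidden widths of the classification head
#'   (default none: a single layer from the latent code).
#' @param w_recon,w_class non-negative loss weights (at least one positive).
#' @param l1_input L1 penalty on the first encoder layer, applied as a
#'   proximal soft-threshold after each optimiser step (default 0.5).
#'   With many more genes than samples a sparse input layer drives the
#'   weights of uninformative genes to exactly zero, which concentrates
#'   both the model and its attributions on informative genes; set to 0 to
#'   disable.
#' @param class_weighting reweight the classification term by inverse class
#'   frequency (default FALSE).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param seed integer seed controlling initialisation and batching.
#' @return list of class \code{mlcae_config}.
#' @export
mlcae_config <- function(n_genes,
                         latent_dim = 12,
                         encoder_widths = c(1024, 256, 64),
                         classifier_widths = integer(0),
                         w_recon = 1, w_class = 1,
                         l1_input = 0.5,
                         class_weighting = FALSE,
                         epochs = 200, batch_size = 64,
                         learning_rate = 1e-3, seed = 0) {
  if (latent_dim < 1) stop("configuration error: latent_dim must be >= 1")
  if (latent_dim >= n_genes)
    stop("configuration error: latent_dim must be smaller than n_genes")
  if (w_recon < 0 || w_class < 0 || w_recon + w_class <= 0)
    stop("configuration error: loss weights must be non-negative, not both 0")
  if (l1_input < 0) stop("configuration error: l1_input must be >= 0")
  cfg <- list(n_genes = as.integer(n_genes),
              latent_dim = as.integer(latent_dim),
              encoder_widths = as.integer(encoder_widths),
              classifier_widths = as.integer(classifier_widths),
              w_recon = w_recon, w_class = w_class, l1_input = l1_input,
              class_weighting = isTRUE(class_weighting),
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate, seed = as.integer(seed))
  class(cfg) <- "mlcae_config"
  cfg
}

#' Build an (untrained) MLC-AE
#'
#' One classification head over the joint (tissue, state) classes - not
#' separate tissue and state heads - so a cohort where one class is absent
#' (e.g. no ovary normals) simply yields a narrower head.
#'
#' @param config an [mlcae_config()].
#' @param class_names character vector of joint class names (>= 2).
#' @return list of class \code{mlcae} with seeded initial parameters.
#' @export
build_mlcae <- function(config, class_names) {
  if (length(class_names) < 2) stop("need at least 2 classes")
  n_classes <- length(class_names)
  with_seed(derive_seed(config$seed, "init"), {
    enc_w <- c(config$n_genes, config$encoder_widths, config$latent_dim)
    enc_a <- c(rep("relu", length(config$encoder_widths)), "linear")
    dec_w <- rev(enc_w)
    dec_a <- c(rep("relu", length(config$encoder_widths)), "linear")
    cls_w <- c(config$latent_dim, config$classifier_widths, n_classes)
    cls_a <- c(rep("relu", length(config$classifier_widths)), "softplus")
    model <- list(
      config = config,
      classes = class_names,
      encoder = nn_init(enc_w, enc_a),
      decoder = nn_init(dec_w, dec_a),
      classifier = nn_init(cls_w, cls_a),
      std = NULL,       # per-gene center/scale, fitted on training data
      genes = NULL,     # training gene order
      history = NULL
    )
  })
  class(model) <- "mlcae"
  model
}

# cosine similarity between each score row and its one-hot target:
# for one-hot y with hot index c, cos = s_c / ||s||
cosine_rows <- function(scores, class_idx) {
  nrm <- sqrt(rowSums(scores^2))
  sc <- scores[cbind(seq_len(nrow(scores)), class_idx)]
  ifelse(nrm == 0, 0, sc / nrm)
}

#' Cosine-similarity classification loss
#'
#' \code{mean(1 - cos(one_hot(y), scores))} over samples. With non-negative
#' scores the cosine lies in [0, 1], so the loss does too: identical
#' direction gives 0, an orthogonal prediction gives 1.
#'
#' @param scores samples x classes matrix of non-negative class scores.
#' @param class_idx integer vector of true class indices.
#' @param weights optional per-sample weights (mean-normalised internally).
#' @return scalar loss.
#' @export
cosine_class_loss <- function(scores, class_idx, weights = NULL) {
  cs <- cosine_rows(scores, class_idx)
  if (is.null(weights)) mean(1 - cs)
  else mean((1 - cs) * weights / mean(weights))
}

# gradient of cosine_class_loss wrt the score matrix
cosine_class_loss_grad <- function(scores, class_idx, weights = NULL) {
  n <- nrow(scores)
  nrm <- sqrt(rowSums(scores^2))
  nrm[nrm == 0] <- 1
  sc <- scores[cbind(seq_len(n), class_idx)]
  # d(1 - cos)/d s_j = s_c s_j / ||s||^3 - delta_jc / ||s||
  d <- scores * (sc / nrm^3)
  d[cbind(seq_len(n), class_idx)] <-
    d[cbind(seq_len(n), class_idx)] - 1 / nrm
  w <- if (is.null(weights)) rep(1, n) else weights / mean(weights)
  d * (w / n)
}

# standardise samples x genes matrix with fitted stats
mlcae_standardize <- function(model, X) {
  sweep(sweep(X, 2L, model$std$center, "-"), 2L, model$std$scale, "/")
}

# expression matrix (genes x samples) -> model-input rows, checking order
mlcae_input <- function(model, expr) {
  if (is.null(model$genes)) stop("model has no fitted gene order; train first")
  if (!identical(rownames(expr), model$genes))
    stop("gene set/order mismatch between input and training data ",
         "(no silent reindexing)")
  mlcae_standardize(model, t(log_transform(expr)))
}

#' Train the MLC-AE
#'
#' Minimises \code{w_recon * MSE(reconstruction, input) + w_class *
#' (1 - cosine(one-hot label, class scores))} with Adam on mini-batches.
#' The input transform is log2(TPM + 1) followed by per-gene
#' standardisation whose statistics are fitted here, on the training
#' samples only, and stored in the model.
#'
#' @param model an untrained [build_mlcae()] model.
#' @param expr gene x sample expression matrix (TPM scale), training samples.
#' @param labels factor of joint class labels, one per sample; its levels
#'   must all be in \code{model$classes}.
#' @return the trained model; \code{$history} holds per-epoch total,
#'   reconstruction and classification losses.
#' @export
train_mlcae <- function(model, expr, labels) {
  cfg <- model$config
  if (ncol(expr) != length(labels))
    stop("one label per sample required")
  unknown <- setdiff(levels(droplevels(factor(labels))), model$classes)
  if (length(unknown) > 0)
    stop("class present in labels but absent from the model's class map: ",
         paste(unknown, collapse = ", "))
  class_idx <- match(as.character(labels), model$classes)

  Xlog <- t(log_transform(expr))          # samples x genes
  center <- colMeans(Xlog)
  scale <- apply(Xlog, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  model$std <- list(center = center, scale = scale)
  model$genes <- rownames(expr)
  X <- mlcae_standardize(model, Xlog)

  n <- nrow(X)
  w_sample <- NULL
  if (cfg$class_weighting) {
    freq <- table(factor(class_idx, levels = seq_along(model$classes)))
    w_sample <- as.numeric(1 / pmax(freq[class_idx], 1))
    w_sample <- w_sample / mean(w_sample)
  }

  st_enc <- nn_adam_init(model$encoder)
  st_dec <- nn_adam_init(model$decoder)
  st_cls <- nn_adam_init(model$classifier)
  hist <- data.frame(epoch = seq_len(cfg$epochs), loss = NA_real_,
                     recon = NA_real_, class = NA_real_)
  step <- 0L
  with_seed(derive_seed(cfg$seed, "train"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_tot <- ep_rec <- ep_cls <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- X[idx, , drop = FALSE]
        yb <- class_idx[idx]
        wb <- if (is.null(w_sample)) NULL else w_sample[idx]

        fe <- nn_forward(model$encoder, xb, keep = TRUE)
        fd <- nn_forward(model$decoder, fe$out, keep = TRUE)
        l_rec <- mean((fd$out - xb)^2)
        d_latent <- 0
        grads_dec <- NULL; grads_cls <- NULL
        if (cfg$w_recon > 0) {
          d_xhat <- cfg$w_recon * 2 * (fd$out - xb) / length(xb)
          bd <- nn_backward(model$decoder, fd$cache, d_xhat)
          grads_dec <- bd$grads
          d_latent <- d_latent + bd$d_input
        }
        l_cls <- 0
        if (cfg$w_class > 0) {
          fc <- nn_forward(model$classifier, fe$out, keep = TRUE)
          l_cls <- cosine_class_loss(fc$out, yb, wb)
          d_s <- cfg$w_class * cosine_class_loss_grad(fc$out, yb, wb)
          bc <- nn_backward(model$classifier, fc$cache, d_s)
          grads_cls <- bc$grads
          d_latent <- d_latent + bc$d_input
        }
        be <- nn_backward(model$encoder, fe$cache, d_latent)

        step <- step + 1L
        up <- nn_adam_step(model$encoder, be$grads, st_enc,
                           cfg$learning_rate, step)
        model$encoder <- up$layers; st_enc <- up$state
        if (cfg$l1_input > 0) {
          # proximal soft-threshold keeps the input layer sparse
          W1 <- model$encoder[[1]]$W
          thr <- cfg$learning_rate * cfg$l1_input
          model$encoder[[1]]$W <- sign(W1) * pmax(abs(W1) - thr, 0)
        }
        if (!is.null(grads_dec)) {
          up <- nn_adam_step(model$decoder, grads_dec, st_dec,
                             cfg$learning_rate, step)
          model$decoder <- up$layers; st_dec <- up$state
        }
        if (!is.null(grads_cls)) {
          up <- nn_adam_step(model$classifier, grads_cls, st_cls,
                             cfg$learning_rate, step)
          model$classifier <- up$layers; st_cls <- up$state
        }
        nb <- length(idx)
        ep_tot <- ep_tot + (cfg$w_recon * l_rec + cfg$w_class * l_cls) * nb
        ep_rec <- ep_rec + l_rec * nb
        ep_cls <- ep_cls + l_cls * nb
      }
      hist$loss[ep] <- ep_tot / n
      hist$recon[ep] <- ep_rec / n
      hist$class[ep] <- ep_cls / n
    }
  })
  model$history <- hist
  model
}

#' Encode profiles to the latent space
#'
#' @param model a trained \code{mlcae}.
#' @param expr gene x sample expression matrix with the training gene order.
#' @return samples x latent_dim matrix.
#' @export
encode <- function(model, expr) {
  Z <- nn_forward(model$encoder, mlcae_input(model, expr))
  rownames(Z) <- colnames(expr)
  Z
}

#' Predict joint classes and reconstructions
#'
#' @inheritParams encode
#' @return list with \code{scores} (samples x classes, non-negative),
#'   \code{class} (predicted class name, argmax of the scores),
#'   \code{latent}, and \code{reconstruction} (samples x genes, on the
#'   standardised log scale of the model input).
#' @export
predict_mlcae <- function(model, expr) {
  X <- mlcae_input(model, expr)
  latent <- nn_forward(model$encoder, X)
  scores <- nn_forward(model$classifier, latent)
  recon <- nn_forward(model$decoder, latent)
  colnames(scores) <- model$classes
  rownames(scores) <- colnames(expr)
  list(scores = scores,
       class = model$classes[max.col(scores, ties.method = "first")],
       latent = latent,
       reconstruction = recon)
}

#' @export
print.mlcae <- function(x, ...) {
  cfg <- x$config
  cat("MLC-AE:", cfg$n_genes, "genes ->",
      paste(cfg$encoder_widths, collapse = " -> "), "->",
      cfg$latent_dim, "latent;", length(x$classes), "joint classes\n")
  if (!is.null(x$history))
    cat(sprintf("trained %d epochs; final loss %.4f (recon %.4f, class %.4f)\n",
                nrow(x$history), x$history$loss[nrow(x$history)],
                x$history$recon[nrow(x$history)],
                x$history$class[nrow(x$history)]))
  invisible(x)
}

# gradient of the class-c score (post-softplus, summed over rows) wrt the
# standardised input rows Z
mlcae_class_input_gradient <- function(model, Z, class_index) {
  fe <- nn_forward(model$encoder, Z, keep = TRUE)
  fc <- nn_forward(model$classifier, fe$out, keep = TRUE)
  d_s <- matrix(0, nrow(Z), length(model$classes))
  d_s[, class_index] <- 1
  d_latent <- nn_backward(model$classifier, fc$cache, d_s)$d_input
  nn_backward(model$encoder, fe$cache, d_latent)$d_input
}
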