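#' Exact Shapley values by subset enumeration
#'
#' Computes, for each feature i, the exact Shapley value
#' \deqn{\phi_i = \sum_{S \subseteq F \setminus \{i\}}
#'   \frac{|S|!(|F|-|S|-1)!}{|F|!} [v(S \cup \{i\}) - v(S)]}
#' under the mean-imputation value function: \eqn{v(S)} is the model output
#' with the features in S taken from \code{x} and the remaining features
#' taken from a background reference, averaged over the background set.
#' This gives the efficiency property
#' \eqn{\sum_i \phi_i = f(x) - mean_b f(b)}.
#'
#' Enumeration costs \eqn{2^M |B|} model evaluations and is refused beyond
#' 20 features; use [expected_gradients()] at scale.
#'
#' @param f model function, vectorised over rows: takes an n x M matrix and
#'   returns n numeric outputs.
#' @param x numeric feature vector of length M (the instance to explain).
#' @param background numeric matrix (rows = reference points, M columns) or
#'   a single reference vector.
#' @return numeric vector of M Shapley values (named after \code{x} if it
#'   has names).
#' @export
exact_shapley <- function(f, x, background) {
  if (is.vector(background)) background <- matrix(background, nrow = 1)
  M <- length(x)
  if (ncol(background) != M) stop("background width must match length(x)")
  if (nrow(background) < 1) stop("background must contain >= 1 reference")
  if (M > 20)
    stop("exact enumeration refused for M > 20 features; ",
         "use expected_gradients() instead")
  n_sub <- 2^M
  nb <- nrow(background)
  # value of every subset: average model output over the background set
  # with features outside S reset to the reference
  big <- matrix(0, n_sub * nb, M)
  member <- matrix(FALSE, n_sub, M)
  for (s in seq_len(n_sub)) {
    bits <- bitwAnd(s - 1L, bitwShiftL(1L, seq_len(M) - 1L)) > 0
    member[s, ] <- bits
    block <- background
    block[, bits] <- matrix(x[bits], nb, sum(bits), byrow = TRUE)
    big[(s - 1L) * nb + seq_len(nb), ] <- block
  }
  vals <- f(big)
  if (length(vals) != n_sub * nb) stop("f must return one value per row")
  v <- rowMeans(matrix(vals, n_sub, nb, byrow = TRUE))

  sizes <- rowSums(member)
  w_of_size <- exp(lfactorial(0:(M - 1)) + lfactorial(M - 1 - (0:(M - 1))) -
                     lfactorial(M))
  phi <- numeric(M)
  bit <- bitwShiftL(1L, seq_len(M) - 1L)
  for (i in seq_len(M)) {
    without_i <- which(!member[, i])
    with_i <- without_i + bit[i]  # subset index after adding feature i
    phi[i] <- sum(w_of_size[sizes[without_i] + 1] * (v[with_i] - v[without_i]))
  }
  names(phi) <- names(x)
  phi
}

#' Draw a background reference set for attribution
#'
#' Samples training columns to serve as expected-gradients references.
#' By default the draw is class-balanced (each joint class equally likely,
#' with replacement) so that reference profiles are not dominated by the
#' majority class of an imbalanced cohort; with \code{balanced = FALSE}
#' columns are drawn uniformly without replacement.
#'
#' @param expr gene x sample expression matrix.
#' @param metadata companion metadata; only samples with
#'   \code{split == "train"} are eligible.
#' @param n background set size (default 100).
#' @param balanced class-balanced draw (default TRUE).
#' @param seed integer seed.
#' @return gene x n expression matrix (column names uniquified).
#' @export
draw_background <- function(expr, metadata, n = 100, balanced = TRUE,
                            seed = 0) {
  tr <- metadata$split == "train"
  if (!any(tr)) stop("no training samples to draw a background from")
  cols <- with_seed(seed, {
    if (balanced) {
      lab <- as.character(joint_labels(metadata))
      freq <- table(lab[tr])
      prob <- ifelse(tr, 1 / as.numeric(freq[lab]), 0)
      sample(seq_len(ncol(expr)), n, prob = prob, replace = TRUE)
    } else {
      sample(which(tr), min(n, sum(tr)))
    }
  })
  bg <- expr[, cols, drop = FALSE]
  colnames(bg) <- make.unique(colnames(bg))
  bg
}

# core expected-gradients estimator: average over seeded (background, u)
# draws of (x - b) * grad f(b + u (x - b)); grad_fn(Z) must return the
# per-row input gradient matrix
expected_gradients_fn <- function(grad_fn, X, background, n_draws, seed) {
  n <- nrow(X); p <- ncol(X); m <- nrow(background)
  if (m < 1) stop("background must contain >= 1 reference")
  att <- matrix(0, n, p)
  with_seed(seed, {
    # stratified background sampling: each sample cycles through seeded
    # permutations of the background set, so that when n_draws is a
    # multiple of the background size every reference contributes equally
    # (and a linear model reproduces its exact Shapley values)
    reps <- ceiling(n_draws / m)
    b_idx <- t(vapply(seq_len(n), function(i) {
      ord <- unlist(lapply(seq_len(reps), function(r) sample.int(m)))
      ord[seq_len(n_draws)]
    }, integer(n_draws)))
    if (n_draws == 1) b_idx <- matrix(b_idx, n, 1)
    u <- matrix(stats::runif(n * n_draws), n, n_draws)
  })
  for (d in seq_len(n_draws)) {
    B <- background[b_idx[, d], , drop = FALSE]
    D <- X - B
    Z <- B + u[, d] * D
    att <- att + D * grad_fn(Z)
  }
  att / n_draws
}

#' Expected-gradients attributions for an MLC-AE
#'
#' Sampling approximation of Shapley values for differentiable models:
#' for each sample x, background reference b and interpolation point
#' u ~ Uniform(0, 1), the contribution of gene i to the class-c score is
#' \eqn{(x_i - b_i) \cdot \partial f_c/\partial x_i} evaluated at
#' \eqn{b + u(x - b)}, averaged over \code{n_draws} seeded draws.
#' Attributions are computed on the classifier's class-score outputs
#' (pre-argmax), in the model's standardised log-expression input space.
#'
#' @param model a trained \code{mlcae}.
#' @param expr gene x sample matrix of samples to explain (training gene
#'   order).
#' @param background_expr gene x sample matrix of background references,
#'   typically a draw of training samples.
#' @param n_draws (background, interpolation) draws per sample
#'   (default 256).
#' @param seed integer seed; attributions are deterministic given it.
#' @return array with dim (samples, genes, classes) and corresponding
#'   dimnames.
#' @export
expected_gradients <- function(model, expr, background_expr,
                               n_draws = 256, seed = 0) {
  if (ncol(background_expr) < 1) stop("background must contain >= 1 sample")
  X <- mlcae_input(model, expr)
  B <- mlcae_input(model, background_expr)
  n_classes <- length(model$classes)
  att <- array(0, dim = c(nrow(X), ncol(X), n_classes),
               dimnames = list(colnames(expr), model$genes, model$classes))
  for (c_idx in seq_len(n_classes)) {
    att[, , c_idx] <- expected_gradients_fn(
      function(Z) mlcae_class_input_gradient(model, Z, c_idx),
      X, B, n_draws, seed = derive_seed(seed, "eg")
    )
  }
  att
}

#' Aggregate per-sample attributions into a gene x class score matrix
#'
#' Per class, a gene's contribution score is the mean absolute attribution
#' over all evaluated samples (absolute values, so contributions of
#' opposite sign across samples do not cancel). Under the sum-to-one
#' normalisation the scores are divided by their grand total over genes
#' and classes.
#'
#' @param att attribution array from [expected_gradients()].
#' @param normalization "sum_to_one" (default) or "raw".
#' @return object of class \code{attribution_matrix}: list with
#'   \code{values} (genes x classes), \code{normalization}, \code{classes}.
#' @export
aggregate_attributions <- function(att,
                                   normalization = c("sum_to_one", "raw")) {
  normalization <- match.arg(normalization)
  vals <- apply(abs(att), c(2, 3), mean)   # genes x classes
  if (normalization == "sum_to_one") {
    tot <- sum(vals)
    if (tot > 0) vals <- vals / tot
  }
  structure(list(values = vals, normalization = normalization,
                 classes = colnames(vals)),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat("attribution matrix:", nrow(x$values), "genes x",
      ncol(x$values), "classes (", x$normalization, ")\n")
  invisible(x)
}

#' Rank genes by aggregated contribution score
#'
#' Two ranking schemes: \code{cc_all} sums a gene's scores over all joint
#' classes (the cross-cancer ranking); \code{cc_tissue} sums only over the
#' chosen tissue's classes (tumor and normal). Scores are normalised so the
#' scheme's gene scores sum to 1; ordering is by descending score with a
#' lexicographic gene-id tie-break.
#'
#' @param att an \code{attribution_matrix}.
#' @param scheme "cc_all" or "cc_tissue".
#' @param tissue tissue label (required for \code{cc_tissue}).
#' @param normalize rescale the scheme's scores to sum to 1 (default TRUE).
#' @return data.frame of class \code{gene_ranking} with columns rank,
#'   gene_id, score, scheme.
#' @export
rank_genes <- function(att, scheme = c("cc_all", "cc_tissue"),
                       tissue = NULL, normalize = TRUE) {
  scheme <- match.arg(scheme)
  vals <- att$values
  if (scheme == "cc_all") {
    cols <- seq_len(ncol(vals))
    label <- "cc_all"
  } else {
    if (is.null(tissue)) stop("cc_tissue ranking needs a tissue")
    cols <- which(startsWith(colnames(vals), paste0(tissue, " ")))
    if (length(cols) == 0) stop("unknown tissue: ", tissue)
    label <- paste0("cc_tissue:", tissue)
  }
  score <- rowSums(vals[, cols, drop = FALSE])
  if (normalize && sum(score) > 0) score <- score / sum(score)
  ord <- order(-score, rownames(vals))
  out <- data.frame(rank = seq_along(ord), gene_id = rownames(vals)[ord],
                    score = score[ord], scheme = label,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Write / read a gene ranking
#'
#' TSV with columns rank, gene_id, score, scheme.
#' @param ranking a \code{gene_ranking}.
#' @param path TSV path.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  out <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  class(out) <- c("gene_ranking", "data.frame")
  out
}
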