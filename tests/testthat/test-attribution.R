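test_that("exact Shapley matches the linear-model closed form", {
  set.seed(1)
  M <- 5
  w <- rnorm(M)
  x <- rnorm(M)
  B <- matrix(rnorm(20 * M), 20, M)
  f <- function(X) drop(X %*% w)
  phi <- exact_shapley(f, x, B)
  expect_equal(unname(phi), w * (x - colMeans(B)), tolerance = 1e-10)
  # and at M = 3 against the same closed form
  phi3 <- exact_shapley(function(X) drop(X %*% w[1:3]), x[1:3],
                        B[, 1:3, drop = FALSE])
  expect_equal(unname(phi3), w[1:3] * (x[1:3] - colMeans(B[, 1:3])),
               tolerance = 1e-10)
})

test_that("exact Shapley: constant model, product game and efficiency", {
  expect_equal(unname(exact_shapley(function(X) rep(3, nrow(X)),
                                    c(1, 2, 3), c(0, 0, 0))),
               c(0, 0, 0))
  # two-feature product, single zero background: both orderings by hand
  phi <- exact_shapley(function(X) X[, 1] * X[, 2], c(1, 1), c(0, 0))
  expect_equal(unname(phi), c(0.5, 0.5))
  # efficiency on a nonlinear model with a multi-point background
  set.seed(2)
  f <- function(X) tanh(X[, 1] * X[, 2]) + X[, 3]^2
  x <- rnorm(3); B <- matrix(rnorm(30), 10, 3)
  phi <- exact_shapley(f, x, B)
  expect_equal(sum(phi), f(matrix(x, 1)) - mean(f(B)), tolerance = 1e-8)
})

test_that("exact Shapley is additive over models sharing a background", {
  set.seed(3)
  f1 <- function(X) sin(X[, 1]) + X[, 2] * X[, 3]
  f2 <- function(X) exp(X[, 2] / 2) - X[, 1]
  x <- rnorm(3); B <- matrix(rnorm(24), 8, 3)
  phi12 <- exact_shapley(function(X) f1(X) + f2(X), x, B)
  expect_equal(phi12, exact_shapley(f1, x, B) + exact_shapley(f2, x, B),
               tolerance = 1e-10)
})

test_that("enumeration is refused beyond 20 features", {
  x <- rnorm(21)
  expect_error(exact_shapley(function(X) rowSums(X), x, rep(0, 21)),
               "expected_gradients")
})

test_that("expected gradients reproduce a linear model's exact Shapley values", {
  set.seed(4)
  M <- 7
  w <- rnorm(M)
  X <- matrix(rnorm(3 * M), 3, M)
  B <- matrix(rnorm(16 * M), 16, M)   # 16 divides 64 draws
  grad_fn <- function(Z) matrix(w, nrow(Z), M, byrow = TRUE)
  att <- ccbiomark:::expected_gradients_fn(grad_fn, X, B, 64, seed = 1)
  for (i in 1:3)
    expect_equal(att[i, ], unname(exact_shapley(function(Z) drop(Z %*% w),
                                                X[i, ], B)),
                 tolerance = 1e-6)
})

test_that("a gene the model provably ignores gets exactly zero attribution", {
  ds <- small_synth()
  m <- small_model()
  g <- 13L  # zero every first-layer weight attached to this gene
  m$encoder[[1]]$W[g, ] <- 0
  te <- which(ds$metadata$split == "test")[1:4]
  bg <- draw_background(ds$expression, ds$metadata, 10, seed = 2)
  att <- expected_gradients(m, ds$expression[, te, drop = FALSE], bg,
                            n_draws = 8, seed = 3)
  expect_identical(unname(att[, g, ]),
                   matrix(0, length(te), length(m$classes)))
  expect_gt(max(abs(att)), 0)
})

test_that("a sample equal to its only background gets zero attributions", {
  m <- smooth_mlcae_6()
  X <- matrix(rnorm(6), 1, 6)
  e <- expr_from_input(X, m$genes)
  att <- expected_gradients(m, e, e, n_draws = 16, seed = 1)
  expect_equal(max(abs(att)), 0)
})

test_that("expected gradients track exact Shapley on a nonlinear 6-gene model", {
  m <- smooth_mlcae_6()
  set.seed(6)
  X <- matrix(rnorm(6), 1, 6)
  B <- matrix(rnorm(8 * 6), 8, 6)
  att <- expected_gradients(m, expr_from_input(X, m$genes),
                            expr_from_input(B, m$genes),
                            n_draws = 512, seed = 7)
  for (ci in seq_along(m$classes)) {
    phi <- exact_shapley(mlcae_score_closure(m, ci), X[1, ], B)
    rng <- diff(range(phi))
    expect_lte(max(abs(phi - att[1, , ci])) / rng, 0.05)
  }
})

test_that("expected gradients are deterministic under a fixed seed", {
  m <- smooth_mlcae_6()
  set.seed(8)
  e <- expr_from_input(matrix(rnorm(12), 2, 6), m$genes)
  b <- expr_from_input(matrix(rnorm(30), 5, 6), m$genes)
  a1 <- expected_gradients(m, e, b, n_draws = 32, seed = 9)
  a2 <- expected_gradients(m, e, b, n_draws = 32, seed = 9)
  expect_identical(a1, a2)
  expect_error(expected_gradients(m, e, b[, 0, drop = FALSE]), "background")
})

test_that("aggregation takes mean absolute attributions and normalises to one", {
  att <- array(0, dim = c(3, 4, 2),
               dimnames = list(paste0("s", 1:3), paste0("g", 1:4),
                               c("c1", "c2")))
  att[, 2, 1] <- c(1, -1, 1)   # signs must not cancel
  agg <- aggregate_attributions(att)
  expect_equal(unname(agg$values["g2", "c1"]), 1)
  expect_equal(sum(agg$values), 1)
  # two genes with equal total mass split the normalised score
  att[, 4, 2] <- c(-1, 1, -1)
  agg2 <- aggregate_attributions(att)
  expect_equal(unname(agg2$values["g2", "c1"]), 0.5)
  expect_equal(unname(agg2$values["g4", "c2"]), 0.5)
  raw <- aggregate_attributions(att, "raw")
  expect_equal(unname(raw$values["g2", "c1"]), 1)
})

test_that("ranking schemes sum the right classes and break ties lexically", {
  vals <- matrix(0, 3, 3,
                 dimnames = list(c("gB", "gA", "gC"),
                                 c("tisA (T)", "tisA (N)", "tisB (T)")))
  vals["gB", ] <- c(0.30, 0.05, 0.00)  # strong only in tissue A
  vals["gA", ] <- c(0.10, 0.05, 0.25)  # equal total, spread across tissues
  vals["gC", ] <- c(0.10, 0.05, 0.10)
  att <- structure(list(values = vals, normalization = "raw",
                        classes = colnames(vals)),
                   class = "attribution_matrix")
  r_tis <- rank_genes(att, "cc_tissue", tissue = "tisA")
  expect_equal(r_tis$gene_id[1], "gB")
  r_all <- rank_genes(att, "cc_all")
  # equal totals under cc_all: lexicographic tie-break, scores sum to 1
  expect_equal(r_all$gene_id[1:2], c("gA", "gB"))
  expect_equal(sum(r_all$score), 1)
  expect_true(all(diff(r_all$score) <= 0))
  expect_error(rank_genes(att, "cc_tissue", tissue = "kidney"), "kidney")

  # a single nonzero gene ranks first under every scheme
  vals0 <- vals * 0; vals0["gC", 2] <- 1
  att0 <- structure(list(values = vals0, normalization = "raw",
                         classes = colnames(vals0)),
                    class = "attribution_matrix")
  expect_equal(rank_genes(att0, "cc_all")$gene_id[1], "gC")
  expect_equal(rank_genes(att0, "cc_tissue", tissue = "tisA")$gene_id[1], "gC")
})

test_that("rankings round-trip through their TSV form", {
  vals <- matrix(runif(6), 3, 2,
                 dimnames = list(paste0("g", 1:3), c("t (T)", "t (N)")))
  att <- structure(list(values = vals, normalization = "raw",
                        classes = colnames(vals)),
                   class = "attribution_matrix")
  r <- rank_genes(att, "cc_all")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ranking(r, f)
  back <- read_ranking(f)
  expect_equal(back$gene_id, r$gene_id)
  expect_equal(back$score, r$score, tolerance = 1e-12)
})
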