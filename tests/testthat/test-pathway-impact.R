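# independent oracle: Jacobi fixed-point iteration of the propagation
# equation, no topological ordering
jacobi_pf <- function(graph, delta_e, tol = 1e-10, max_iter = 10000) {
  nodes <- graph$nodes
  de <- stats::setNames(rep(0, length(nodes)), nodes)
  de[intersect(names(delta_e), nodes)] <-
    delta_e[intersect(names(delta_e), nodes)]
  outd <- table(factor(graph$edges$from, levels = nodes))
  pf <- de
  for (it in seq_len(max_iter)) {
    pf_new <- de
    for (k in seq_len(nrow(graph$edges))) {
      e <- graph$edges[k, ]
      pf_new[e$to] <- pf_new[e$to] + e$beta * pf[e$from] / outd[[e$from]]
    }
    if (max(abs(pf_new - pf)) < tol) return(pf_new)
    pf <- pf_new
  }
  pf
}

test_that("perturbation factors on a two-node chain match hand evaluation", {
  chain <- pathway_graph("chain", c("A", "B"),
                         data.frame(from = "A", to = "B", beta = 1))
  st <- compute_pf(chain, c(A = 2, B = 1))
  expect_equal(st$pf[st$gene == "A"], 2)     # source: PF = delta E
  expect_equal(st$pf[st$gene == "B"], 3)     # 1 + 2/1
  expect_equal(st$acc[st$gene == "A"], 0)
  expect_equal(st$acc[st$gene == "B"], 2)

  repress <- pathway_graph("rep", c("A", "B"),
                           data.frame(from = "A", to = "B", beta = -1))
  st2 <- compute_pf(repress, c(A = 2, B = 1))
  expect_equal(st2$pf[st2$gene == "B"], -1)  # 1 - 2/1
})

test_that("isolated genes keep their measured change; absent genes default to 0", {
  iso <- pathway_graph("iso", c("X", "Y"))
  st <- compute_pf(iso, c(X = 1.7))
  expect_equal(st$pf[st$gene == "X"], 1.7)
  expect_equal(st$acc[st$gene == "X"], 0)
  expect_equal(st$pf[st$gene == "Y"], 0)
})

test_that("downstream normalisation divides by the out-degree", {
  # A feeds B and C: each inherits PF(A)/2
  g <- pathway_graph("fan", c("A", "B", "C"),
                     data.frame(from = c("A", "A"), to = c("B", "C"),
                                beta = c(1, -1)))
  st <- compute_pf(g, c(A = 4))
  expect_equal(st$pf[st$gene == "B"], 2)
  expect_equal(st$pf[st$gene == "C"], -2)
})

test_that("cyclic pathways are rejected with an edge named", {
  cyc <- pathway_graph("cyc", c("A", "B"),
                       data.frame(from = c("A", "B"), to = c("B", "A"),
                                  beta = c(1, 1)))
  expect_error(compute_pf(cyc, c(A = 1)), "cycle")
})

test_that("propagation is linear in the expression changes", {
  pws <- generate_pathways(3, 10, edge_density = 0.4, seed = 3)
  for (p in pws) {
    set.seed(4)
    de <- stats::setNames(rnorm(length(p$nodes)), p$nodes)
    pf1 <- compute_pf(p, de)$pf
    pf3 <- compute_pf(p, de * 3.7)$pf
    expect_equal(pf3, pf1 * 3.7, tolerance = 1e-12)
  }
})

test_that("topological evaluation equals the Jacobi fixed point on random DAGs", {
  pws <- generate_pathways(4, 12, edge_density = 0.35,
                           repression_fraction = 0.4, seed = 6)
  for (p in pws) {
    set.seed(7)
    de <- stats::setNames(rnorm(length(p$nodes)), sample(p$nodes))
    st <- compute_pf(p, de)
    oracle <- jacobi_pf(p, de)
    expect_equal(stats::setNames(st$pf, st$gene), oracle[st$gene],
                 tolerance = 1e-9)
  }
})

test_that("enrichment probability matches hand hypergeometrics", {
  # pathway of 2 genes, universe 4 with 2 DE, both pathway genes DE -> 1/6
  g2 <- pathway_graph("p", c("a", "b"))
  expect_equal(enrichment_p(g2, c("a", "b"), 4, 2), 1 / 6)
  # no DE genes -> probability 1
  expect_equal(enrichment_p(g2, character(0), 4, 2), 1)
  # the whole universe as the pathway -> probability 1
  gu <- pathway_graph("u", letters[1:4])
  expect_equal(enrichment_p(gu, c("a", "b"), 4, 2), 1)
  # cross-check a larger case against stats::phyper directly
  g5 <- pathway_graph("q", letters[1:5])
  expect_equal(enrichment_p(g5, letters[1:3], 30, 10),
               phyper(2, 10, 20, 5, lower.tail = FALSE))
})

test_that("the impact factor combines both terms as specified", {
  st <- data.frame(gene = c("a", "b"), delta_e = c(1, 1), pf = c(2, 3),
                   acc = c(1, 2))
  # ln(1/0.01) + 5 / (1 * 2) = ln(100) + 2.5
  out <- impact_factor(st, 0.01, n_de = 2, mean_abs_de = 1)
  expect_equal(out$value, log(100) + 2.5, tolerance = 1e-12)
  expect_false(out$flagged)
  # p = 1 with zero perturbation -> 0
  st0 <- data.frame(gene = "a", delta_e = 0, pf = 0, acc = 0)
  expect_equal(impact_factor(st0, 1, 1, 1)$value, 0)
  # undefined second term is flagged, enrichment term kept
  out2 <- impact_factor(st, 0.01, n_de = 0, mean_abs_de = 1)
  expect_true(out2$flagged)
  expect_equal(out2$value, log(100))
  expect_error(impact_factor(st, 0, 1, 1), "p_i")
})

test_that("doubling all expression changes leaves the perturbation term fixed", {
  chain <- pathway_graph("chain", c("A", "B"),
                         data.frame(from = "A", to = "B", beta = 1))
  de1 <- c(A = 2, B = 1)
  st1 <- compute_pf(chain, de1)
  st2 <- compute_pf(chain, de1 * 2)
  term <- function(st, de) sum(abs(st$pf)) / (mean(abs(de)) * length(de))
  expect_equal(term(st1, de1), term(st2, de1 * 2), tolerance = 1e-12)
})

test_that("pathway file format round-trips including singleton nodes", {
  pws <- generate_pathways(3, 8, edge_density = 0.3, seed = 8)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pathways(pws, f)
  back <- read_pathways(f)
  expect_length(back, 3L)
  for (p in pws) {
    q <- back[[p$id]]
    expect_setequal(q$nodes, p$nodes)
    expect_equal(nrow(q$edges), nrow(p$edges))
  }
})

test_that("a planted concordant pathway outranks decoys and a label permutation kills it", {
  recovered <- 0
  destroyed <- 0
  for (sd in 1:3) {
    spc <- data.frame(tissue = "prostate", state = c("tumor", "normal"),
                      n = c(30L, 30L))
    ds <- generate_dataset(synth_config(
      n_genes = 150, tissues = "prostate", n_tissue_markers = 0,
      n_shared_disease_markers = 8, n_private_disease_markers = 0,
      samples_per_class = spc, seed = sd))
    de <- de_test(ds$expression, ds$metadata$state)
    ranking <- structure(
      data.frame(rank = seq_len(nrow(de)),
                 gene_id = de$gene_id[order(-abs(de$log2fc))],
                 score = sort(abs(de$log2fc), decreasing = TRUE),
                 scheme = "cc_all", stringsAsFactors = FALSE),
      class = c("gene_ranking", "data.frame"))
    nulls <- setdiff(de$gene_id[!de$is_de], unlist(ds$truth))
    planted <- generate_pathways(1, 5, edge_density = 0.4,
                                 repression_fraction = 0, seed = sd,
                                 genes = ds$truth$shared_disease[1:5])[[1]]
    planted$id <- "planted"
    decoys <- generate_pathways(20, 5, edge_density = 0.4, seed = sd + 50,
                                genes = nulls)
    res <- run_impact_analysis(ranking, de, c(list(planted), decoys),
                               top_n = 150, n_boot = 500, seed = sd)
    recovered <- recovered + (res$pathway_id[1] == "planted")

    # permuting the gene labels of the fold changes destroys significance
    de_perm <- de
    set.seed(sd)
    de_perm$gene_id <- sample(de_perm$gene_id)
    res_p <- run_impact_analysis(ranking, de_perm,
                                 c(list(planted), decoys),
                                 top_n = 150, n_boot = 500, seed = sd)
    destroyed <- destroyed +
      (res_p$q[res_p$pathway_id == "planted"] > 0.05)
  }
  expect_gte(recovered, 2)
  expect_gte(destroyed, 2)
})

test_that("pathways disjoint from the DE genes are reported as unenriched", {
  de <- structure(
    data.frame(gene_id = sprintf("g%03d", 1:100),
               log2fc = c(rep(2, 10), rep(0, 90)),
               p = c(rep(1e-8, 10), rep(0.9, 90)),
               q = c(rep(1e-6, 10), rep(0.95, 90)),
               is_de = c(rep(TRUE, 10), rep(FALSE, 90)),
               stringsAsFactors = FALSE),
    class = c("de_result", "data.frame"))
  ranking <- structure(
    data.frame(rank = 1:100, gene_id = de$gene_id, score = 100:1,
               scheme = "cc_all", stringsAsFactors = FALSE),
    class = c("gene_ranking", "data.frame"))
  hit <- pathway_graph("hit", sprintf("g%03d", 1:8))
  miss <- pathway_graph("miss", sprintf("g%03d", 50:57))
  res <- run_impact_analysis(ranking, de, list(hit, miss),
                             top_n = 100, n_boot = 200, seed = 1)
  miss_row <- res[res$pathway_id == "miss", ]
  expect_equal(miss_row$p_enrich, 1)
  expect_equal(miss_row$n_de, 0L)
  expect_equal(miss_row$p_perturb, 1)
  expect_gte(miss_row$q, res$q[res$pathway_id == "hit"])
  expect_error(run_impact_analysis(ranking, de, list(), 10), "empty")
})

test_that("the bootstrap perturbation p is near-uniform under the null", {
  p <- generate_pathways(1, 12, edge_density = 0.35, seed = 9)[[1]]
  pool <- c(rnorm(30, 2, 0.5), rnorm(30, -2, 0.5))
  de_pos <- p$nodes[1:6]
  set.seed(10)
  pvals <- vapply(1:200, function(r) {
    obs <- stats::setNames(sample(pool, 6), de_pos)
    s_obs <- sum(abs(compute_pf(p, obs)$pf))
    null_s <- vapply(1:120, function(b) {
      d0 <- stats::setNames(sample(pool, 6, replace = TRUE), de_pos)
      sum(abs(compute_pf(p, d0)$pf))
    }, numeric(1))
    (1 + sum(null_s >= s_obs)) / (1 + 120)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lte(unname(ks$statistic), 0.1)
})
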