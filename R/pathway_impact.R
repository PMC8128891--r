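#' Signed directed pathway graph
#'
#' A pathway is a directed gene graph whose edges carry an interaction sign:
#' beta = +1 for activation, beta = -1 for repression. Perturbation
#' propagation is only defined on acyclic graphs; acyclicity is checked at
#' evaluation time.
#'
#' @param id pathway identifier.
#' @param nodes character vector of gene identifiers.
#' @param edges data.frame with columns from, to, beta (+1/-1); may have
#'   zero rows.
#' @return object of class \code{pathway_graph}.
#' @export
pathway_graph <- function(id, nodes, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        beta = numeric(0), stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "beta") %in% names(edges)))
  if (nrow(edges) > 0 && !all(edges$beta %in% c(-1, 1)))
    stop("edge signs must be +1 or -1")
  nodes <- unique(c(nodes, edges$from, edges$to))
  structure(list(id = id, nodes = nodes, edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("pathway_graph", x$id, ":", length(x$nodes), "genes,",
      nrow(x$edges), "edges (",
      sum(x$edges$beta == -1), "repressive )\n")
  invisible(x)
}

pathway_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = data.frame(name = graph$nodes))
  igraph::E(g)$beta <- graph$edges$beta
  g
}

#' Read / write pathway sets
#'
#' TSV with columns pathway_id, source_gene, target_gene, sign (+1/-1);
#' singleton nodes are listed with an empty target.
#'
#' @param path TSV path.
#' @return list of \code{pathway_graph}.
#' @export
read_pathways <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(pathway_id = "character",
                                         source_gene = "character",
                                         target_gene = "character"))
  lapply(split(df, df$pathway_id), function(d) {
    has_edge <- !is.na(d$target_gene) & nzchar(d$target_gene)
    pathway_graph(d$pathway_id[1],
                  nodes = unique(d$source_gene),
                  edges = data.frame(from = d$source_gene[has_edge],
                                     to = d$target_gene[has_edge],
                                     beta = as.numeric(d$sign[has_edge]),
                                     stringsAsFactors = FALSE))
  })
}

#' @rdname read_pathways
#' @param pathways list of \code{pathway_graph}.
#' @export
write_pathways <- function(pathways, path) {
  rows <- lapply(pathways, function(p) {
    e <- p$edges
    iso <- setdiff(p$nodes, unique(c(e$from, e$to)))
    rbind(
      if (nrow(e) > 0)
        data.frame(pathway_id = p$id, source_gene = e$from,
                   target_gene = e$to, sign = e$beta,
                   stringsAsFactors = FALSE),
      if (length(iso) > 0)
        data.frame(pathway_id = p$id, source_gene = iso, target_gene = "",
                   sign = NA_real_, stringsAsFactors = FALSE)
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Perturbation-factor propagation on a pathway
#'
#' Each gene's perturbation factor is its own measured expression change
#' plus the signed, out-degree-normalised perturbation inherited from its
#' direct upstream genes:
#' \deqn{PF(g) = \Delta E(g) + \sum_{u \in US_g} \beta_{ug} PF(u)/N_{ds}(u)}
#' where \eqn{N_{ds}(u)} is the number of genes directly downstream of
#' \eqn{u}. A gene with no upstream genes therefore has \eqn{PF = \Delta E}.
#' The accumulated perturbation is \eqn{Acc(g) = PF(g) - \Delta E(g)}.
#' Evaluation is in topological order and requires an acyclic graph.
#'
#' @param graph a \code{pathway_graph}.
#' @param delta_e named numeric vector of measured expression changes
#'   (log2 fold changes); pathway genes absent from it are taken as 0.
#' @return data.frame with columns gene, delta_e, pf, acc.
#' @export
compute_pf <- function(graph, delta_e) {
  prop <- pf_propagator(graph)
  de <- prop$align(delta_e)
  pf <- prop$run(de)
  data.frame(gene = prop$nodes, delta_e = unname(de), pf = unname(pf),
             acc = unname(pf - de), stringsAsFactors = FALSE)
}

# precompile a pathway's topology into an evaluator reused across
# bootstrap draws: topological node order, integer upstream index lists and
# signed out-degree-normalised edge weights
pf_propagator <- function(graph) {
  g <- pathway_igraph(graph)
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    enda <- igraph::ends(g, cyc[1])
    stop("pathway ", graph$id, " contains a cycle (e.g. through edge ",
         enda[1], " -> ", enda[2], "); perturbation propagation needs a DAG")
  }
  nodes <- igraph::V(g)$name
  ord <- as.integer(igraph::topo_sort(g, mode = "out"))
  out_deg <- igraph::degree(g, mode = "out")
  e_from <- match(graph$edges$from, nodes)
  e_to <- match(graph$edges$to, nodes)
  e_w <- graph$edges$beta / out_deg[e_from]
  up_idx <- split(seq_along(e_to), factor(e_to, levels = seq_along(nodes)))
  list(
    nodes = nodes,
    align = function(delta_e) {
      de <- delta_e[nodes]
      de[is.na(de)] <- 0
      names(de) <- nodes
      de
    },
    run = function(de) {
      pf <- de
      for (v in ord) {
        ei <- up_idx[[v]]
        if (length(ei) > 0)
          pf[v] <- de[v] + sum(e_w[ei] * pf[e_from[ei]])
      }
      pf
    }
  )
}

#' Hypergeometric enrichment probability of DE genes on a pathway
#'
#' The probability of observing at least the pathway's number of
#' differentially expressed genes by chance, given the DE rate in the gene
#' universe (hypergeometric upper tail).
#'
#' @param graph a \code{pathway_graph}.
#' @param de_genes character vector of DE gene identifiers.
#' @param universe_size number of genes in the analysis universe.
#' @param universe_de_count number of DE genes in the universe.
#' @return upper-tail probability \eqn{P(X \ge N_{de})} in (0, 1].
#' @export
enrichment_p <- function(graph, de_genes, universe_size, universe_de_count) {
  n_path <- length(graph$nodes)
  n_de <- sum(graph$nodes %in% de_genes)
  if (n_de > n_path) stop("more DE genes than pathway genes")
  if (universe_de_count > universe_size)
    stop("universe_de_count exceeds universe_size")
  if (n_de == 0) return(1)
  stats::phyper(n_de - 1, universe_de_count,
                universe_size - universe_de_count, n_path,
                lower.tail = FALSE)
}

#' Pathway impact factor
#'
#' Combines the enrichment probability with the total propagated
#' perturbation:
#' \deqn{IF(P) = \ln(1/p_i) + \frac{\sum_{g \in P} |PF(g)|}{|\bar{\Delta E}|
#'   \cdot N_{de}(P)}}
#' where \eqn{|\bar{\Delta E}|} is the mean absolute expression change of
#' the DE genes in the analysis. With no DE genes on the pathway (or a zero
#' mean change) the second term is undefined; only the enrichment term is
#' returned and the result is flagged.
#'
#' @param state data.frame from [compute_pf()].
#' @param p_i enrichment probability in (0, 1].
#' @param n_de number of DE genes on the pathway.
#' @param mean_abs_de mean absolute delta-E over the analysis' DE genes.
#' @return list with \code{value} and \code{flagged} (TRUE when the
#'   perturbation term was undefined).
#' @export
impact_factor <- function(state, p_i, n_de, mean_abs_de) {
  if (p_i <= 0 || p_i > 1) stop("p_i must lie in (0, 1]")
  term1 <- log(1 / p_i)
  if (n_de == 0 || mean_abs_de == 0)
    return(list(value = term1, flagged = TRUE))
  list(value = term1 + sum(abs(state$pf)) / (mean_abs_de * n_de),
       flagged = FALSE)
}

#' Full pathway impact analysis
#'
#' The expression changes fed into the propagation are the log2 fold
#' changes of the \code{top_n} highest-ranked genes that are also called
#' DE; all other genes carry delta-E = 0. Per pathway the analysis reports
#' the DE count, hypergeometric enrichment p, total |PF|, impact factor, a
#' bootstrap perturbation p (total |PF| recomputed with the pathway's DE
#' fold changes resampled from the DE pool), a combined p (Fisher's
#' method over the enrichment and perturbation p), and a
#' Benjamini-Hochberg q across pathways.
#'
#' @param ranking a \code{gene_ranking} (see [rank_genes()]).
#' @param de_result a \code{de_result} (see [de_test()]).
#' @param pathways list of \code{pathway_graph}.
#' @param top_n how many top-ranked genes contribute fold changes
#'   (default 1000).
#' @param n_boot bootstrap draws for the perturbation p (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return data.frame, one row per pathway, sorted by q ascending:
#'   pathway_id, size, n_de, p_enrich, sum_abs_pf, impact_factor,
#'   if_flagged, p_perturb, p_combined, q.
#' @export
run_impact_analysis <- function(ranking, de_result, pathways,
                                top_n = 1000, n_boot = 2000, seed = 0) {
  if (length(pathways) == 0) stop("empty pathway list")
  if (top_n > nrow(ranking)) top_n <- nrow(ranking)
  de_genes <- de_result$gene_id[de_result$is_de]
  top_genes <- ranking$gene_id[seq_len(top_n)]
  active <- intersect(top_genes, de_genes)
  delta_e <- stats::setNames(
    de_result$log2fc[match(active, de_result$gene_id)], active)
  universe <- de_result$gene_id
  mean_abs_de <- if (length(active) > 0) mean(abs(delta_e)) else 0
  pool <- delta_e  # DE fold-change pool for the bootstrap null

  rows <- lapply(seq_along(pathways), function(i) {
    p <- pathways[[i]]
    prop <- pf_propagator(p)
    de_vec <- prop$align(delta_e)
    st <- data.frame(gene = prop$nodes, delta_e = unname(de_vec),
                     pf = unname(prop$run(de_vec)), stringsAsFactors = FALSE)
    st$acc <- st$pf - st$delta_e
    n_de <- sum(p$nodes %in% names(delta_e))
    p_enr <- enrichment_p(p, names(delta_e), length(universe), length(active))
    s_abs <- sum(abs(st$pf))
    impf <- impact_factor(st, p_enr, n_de, mean_abs_de)
    # bootstrap null for the perturbation term: same DE positions on the
    # pathway, fold changes resampled from the DE pool
    p_pert <- 1
    if (n_de > 0 && length(pool) > 1) {
      on_path <- prop$nodes %in% names(delta_e)
      null_s <- with_seed(derive_seed(seed, paste0("boot", i)), {
        vapply(seq_len(n_boot), function(b) {
          d0 <- numeric(length(prop$nodes))
          names(d0) <- prop$nodes
          d0[on_path] <- sample(pool, n_de, replace = TRUE)
          sum(abs(prop$run(d0)))
        }, numeric(1))
      })
      p_pert <- (1 + sum(null_s >= s_abs)) / (1 + n_boot)
    }
    chisq <- -2 * (log(p_enr) + log(p_pert))
    p_comb <- stats::pchisq(chisq, df = 4, lower.tail = FALSE)
    data.frame(pathway_id = p$id, size = length(p$nodes), n_de = n_de,
               p_enrich = p_enr, sum_abs_pf = s_abs,
               impact_factor = impf$value, if_flagged = impf$flagged,
               p_perturb = p_pert, p_combined = p_comb,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p_combined, method = "BH")
  res[order(res$q, res$p_combined, res$pathway_id), ]
}
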