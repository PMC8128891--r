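#' Differential expression between tumor and normal samples
#'
#' Per-gene Welch two-sample t-test on log2(TPM + pseudocount), with
#' Benjamini-Hochberg adjustment across all tested genes. The fold change
#' is \code{mean(log2 tumor) - mean(log2 normal)}. A gene is called DE when
#' \code{|log2FC| > fc_threshold} (strictly) and \code{q < q_threshold}:
#' with the default 0.6 gate a gene at fold change 0.5 is not DE however
#' small its p-value.
#'
#' @param expr gene x sample expression matrix (TPM scale).
#' @param groups character/factor per sample with values "tumor"/"normal".
#' @param fc_threshold absolute log2 fold-change gate (default 0.6).
#' @param q_threshold FDR gate (default 0.05).
#' @param pseudocount added before the log transform (default 1).
#' @return data.frame of class \code{de_result}: gene_id, log2fc, p, q,
#'   is_de.
#' @export
de_test <- function(expr, groups, fc_threshold = 0.6, q_threshold = 0.05,
                    pseudocount = 1) {
  groups <- as.character(groups)
  if (!all(groups %in% c("tumor", "normal")))
    stop("groups must be 'tumor' or 'normal'")
  n1 <- sum(groups == "tumor"); n2 <- sum(groups == "normal")
  if (n1 < 2 || n2 < 2)
    stop("each group needs >= 2 samples (tumor: ", n1, ", normal: ", n2, ")")
  lx <- log_transform(expr, pseudocount)
  x1 <- lx[, groups == "tumor", drop = FALSE]
  x2 <- lx[, groups == "normal", drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, stats::var); v2 <- apply(x2, 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  # Welch-Satterthwaite degrees of freedom
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se2 == 0] <- 1  # constant gene in both groups: no evidence
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene_id = rownames(expr), log2fc = m1 - m2, p = p, q = q,
                    is_de = abs(m1 - m2) > fc_threshold & q < q_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Overlap of a top-k gene ranking with per-cancer DE sets
#'
#' For the top-k ranked genes, reports per-gene membership in each DE set
#' and the Venn-style region counts (one count per membership pattern plus
#' the "in no set" count); region counts sum to k.
#'
#' @param ranking a \code{gene_ranking}.
#' @param de_sets named list of character vectors of DE gene ids.
#' @param k how many top genes to consider (default 10).
#' @return list with \code{membership} (data.frame: gene_id plus one
#'   logical column per DE set), \code{regions} (named counts by
#'   membership pattern, "none" for no set), and \code{n_non_de}.
#' @export
overlap_analysis <- function(ranking, de_sets, k = 10) {
  if (k > nrow(ranking)) stop("k exceeds ranking length")
  top <- ranking$gene_id[seq_len(k)]
  memb <- data.frame(gene_id = top, stringsAsFactors = FALSE)
  for (nm in names(de_sets)) memb[[nm]] <- top %in% de_sets[[nm]]
  pat <- apply(memb[, -1, drop = FALSE], 1L, function(r) {
    if (!any(r)) "none" else paste(names(de_sets)[r], collapse = "&")
  })
  regions <- table(pat)
  list(membership = memb,
       regions = as.integer(regions) |> stats::setNames(names(regions)),
       n_non_de = sum(pat == "none"))
}
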