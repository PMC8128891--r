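#' Read a gene x sample expression matrix from TSV
#'
#' The on-disk dialect is a tab-separated table with gene identifiers in the
#' first column and sample identifiers in the header row, matching GDC-style
#' expression dumps. Identifiers are treated as opaque strings.
#'
#' @param path path to a TSV file.
#' @return numeric matrix, genes as rows (rownames = gene ids,
#'   colnames = sample ids), non-negative, no missing values.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs a gene column plus >= 1 sample")
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0)
    stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression entries in ", path)
  rownames(m) <- genes
  validate_expression(m)
  m
}

#' Write an expression matrix to TSV
#'
#' @param mat expression matrix as returned by [read_expression()].
#' @param path output path.
#' @param digits significant digits written (default 10, so that a
#'   write/read round trip reproduces values to ~1e-9 relative tolerance).
#' @export
write_expression <- function(mat, path, digits = 10) {
  validate_expression(mat)
  df <- data.frame(gene_id = rownames(mat),
                   signif(mat, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression <- function(mat) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene identifier(s): ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample identifier(s): ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  if (anyNA(mat)) stop("missing expression entries")
  if (any(mat < 0)) stop("negative expression entries")
  invisible(mat)
}

#' Read / write a sample metadata table
#'
#' Columns: sample_id, tissue, state ("tumor"/"normal"), source, split
#' ("train"/"test").
#'
#' @param path TSV path.
#' @return data.frame with the five metadata columns.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "state", "source", "split")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  md
}

#' @rdname read_metadata
#' @param metadata metadata data.frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' TPM-normalise a count matrix
#'
#' Per sample, counts are divided by gene length (in any consistent unit),
#' and the length-corrected rates are rescaled to sum to one million:
#' \code{tpm_g = (count_g / length_g) / sum_g(count_g / length_g) * 1e6}.
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @param lengths positive gene lengths, one per row of \code{counts}.
#' @return matrix of the same shape; every column sums to 1e6.
#' @export
tpm_normalize <- function(counts, lengths) {
  validate_expression(counts)
  if (length(lengths) != nrow(counts))
    stop("need one length per gene")
  if (any(lengths <= 0)) stop("gene lengths must be strictly positive")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Restrict matrices to their common genes
#'
#' Profiles from different sources only become comparable on the genes they
#' share; every output matrix is restricted to the intersection of the
#' inputs' gene sets, in lexicographic order.
#'
#' @param matrices list of >= 2 expression matrices.
#' @return list of matrices over the identical, sorted common gene set.
#' @export
intersect_genes <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2)
    stop("need a list of at least two matrices")
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0) stop("empty gene intersection across inputs")
  common <- sort(common)
  lapply(matrices, function(m) m[common, , drop = FALSE])
}

#' Stratified train/test split
#'
#' Samples are split within each (source, tissue, state) cell so that every
#' cohort contributes to both sides, mirroring per-project train/test
#' accounting. Cells with a single sample go to the training side; any cell
#' with >= 2 samples keeps at least one sample on each side.
#'
#' @param metadata metadata data.frame (split column ignored if present).
#' @param test_fraction fraction assigned to the test side, in (0, 1).
#' @param seed integer seed; the assignment is deterministic given it.
#' @return the metadata with the \code{split} column (re)assigned.
#' @export
split_train_test <- function(metadata, test_fraction = 0.25, seed = 1) {
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must lie strictly between 0 and 1")
  cell <- interaction(metadata$source, metadata$tissue, metadata$state,
                      drop = TRUE)
  split <- rep("train", nrow(metadata))
  with_seed(seed, {
    for (cl in levels(cell)) {
      idx <- which(cell == cl)
      n <- length(idx)
      if (n < 2) next  # singleton cells stay in train
      n_test <- round(n * test_fraction)
      n_test <- max(1L, min(n - 1L, n_test))
      split[sample(idx, n_test)] <- "test"
    }
  })
  metadata$split <- split
  metadata
}

#' Joint tissue/disease-state class labels
#'
#' Builds the joint class factor the MLC-AE predicts: one class per
#' (tissue, state) pair observed in the metadata, named "tissue (T)" for
#' tumor and "tissue (N)" for normal. Classes absent from the data (e.g. a
#' tissue with no normal samples) get no level.
#'
#' @param metadata metadata data.frame.
#' @return factor of length nrow(metadata); levels are the observed joint
#'   classes in sorted order.
#' @export
joint_labels <- function(metadata) {
  tag <- ifelse(metadata$state == "tumor", "(T)", "(N)")
  factor(paste(metadata$tissue, tag))
}

#' Model-input transform for expression profiles
#'
#' log2(TPM + 1) on the gene x sample matrix; per-gene standardisation is
#' fitted on training samples only (see [train_mlcae()]).
#'
#' @param mat expression matrix (TPM scale).
#' @param pseudocount added before the log (default 1).
#' @return matrix of the same shape on log2 scale.
#' @export
log_transform <- function(mat, pseudocount = 1) {
  log2(mat + pseudocount)
}
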