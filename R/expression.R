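#' Normalize expression intensities (low-signal cutoff, log2, percentile shift)
#'
#' The standard one-colour array normalization chain: raw intensities below
#' `low_cutoff` are replaced by `low_cutoff`, values are log2-transformed,
#' and each sample is shifted so that its chosen percentile (75th by
#' default) becomes zero. Percentiles use linear interpolation between order
#' statistics ([stats::quantile()] type 7); this convention is fixed and
#' documented here because published analyses typically state only the
#' percentile, not the interpolation rule.
#'
#' @param raw Numeric matrix of raw intensities (probes x samples), values
#'   strictly positive after cutoff replacement by construction.
#' @param low_cutoff Replacement floor applied before the log transform.
#' @param percentile Per-sample percentile (in `[0, 100]`) shifted to zero.
#' @return Matrix of normalized log2 intensities; every sample's
#'   `percentile`-th percentile is exactly 0.
#' @examples
#' m <- matrix(c(0.5, 1, 2, 4), ncol = 1, dimnames = list(1:4, "s1"))
#' normalize_expression(m)  # -1.25 -1.25 -0.25 0.75
#' @export
normalize_expression <- function(raw, low_cutoff = 1.0, percentile = 75) {
  raw <- as.matrix(raw)
  if (ncol(raw) == 0 || nrow(raw) == 0) stop("empty intensity matrix")
  if (percentile < 0 || percentile > 100) stop("'percentile' must be in [0, 100]")
  empty <- colSums(!is.na(raw)) == 0
  if (any(empty)) stop("sample with no values: ", colnames(raw)[empty][1])
  x <- raw
  x[!is.na(x) & x < low_cutoff] <- low_cutoff
  x <- log2(x)
  shift <- apply(x, 2, stats::quantile, probs = percentile / 100,
                 na.rm = TRUE, names = FALSE, type = 7)
  sweep(x, 2, shift, "-")
}

#' Aggregate expression probes to genes by the mean
#'
#' When several expression probes are annotated to the same RefSeq ID the
#' gene-level value is the per-sample mean of the probe values; single-probe
#' genes pass through unchanged. Probes absent from the map are dropped with
#' a message. A probe annotated to several genes contributes to each.
#'
#' @param mat Numeric matrix (probes x samples), typically normalized log2.
#' @param probe_to_gene Data.frame with columns `probe_id`, `gene_id`.
#' @return Matrix (genes x samples) of group means.
#' @export
aggregate_probes_to_genes <- function(mat, probe_to_gene) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_to_gene)))
  map <- probe_to_gene[probe_to_gene$probe_id %in% rownames(mat), , drop = FALSE]
  unmapped <- setdiff(rownames(mat), map$probe_id)
  if (length(unmapped)) {
    message(length(unmapped), " probe(s) without a gene mapping dropped")
  }
  if (nrow(map) == 0) stop("no probe maps to any gene")
  x <- mat[map$probe_id, , drop = FALSE]
  g <- factor(map$gene_id)
  sums <- rowsum(x, g)
  counts <- as.vector(table(g))
  sums / counts
}

#' Call expression fold changes for a senescence contrast
#'
#' The fold change per gene is the ratio of the geometric means of test
#' (senescent) and control (proliferating) intensities, computed as
#' `2^(mean log2 test - mean log2 control)`. At the default threshold a
#' gene is called `up` when the fold change is >= `up_fc` and `down` when
#' it is <= `1/up_fc` (both inclusive).
#'
#' @param gene_mat Gene-level log2 matrix (genes x samples), as produced by
#'   [normalize_expression()] + [aggregate_probes_to_genes()].
#' @param test,control Character vectors of test and control sample names
#'   (>= 1 each).
#' @param up_fc Fold-change threshold for the up call; the down call uses
#'   its reciprocal.
#' @param contrast Optional label stored in the output.
#' @return Data.frame with columns `gene_id`, `contrast`, `log2_fc`, `fc`
#'   and `call` (factor up/down/none). Genes with a missing value in either
#'   group are omitted with a message.
#' @export
call_fold_changes <- function(gene_mat, test, control, up_fc = 2.0,
                              contrast = "senescent_vs_control") {
  if (length(test) < 1 || length(control) < 1) {
    stop("need at least one test and one control sample")
  }
  miss <- setdiff(c(test, control), colnames(gene_mat))
  if (length(miss)) stop("samples not present: ", paste(miss, collapse = ", "))
  if (up_fc <= 1) stop("'up_fc' must exceed 1")
  mt <- rowMeans(gene_mat[, test, drop = FALSE])
  mc <- rowMeans(gene_mat[, control, drop = FALSE])
  ok <- !is.na(mt) & !is.na(mc)
  if (any(!ok)) message(sum(!ok), " gene(s) with missing values omitted")
  lfc <- mt[ok] - mc[ok]
  fc <- 2^lfc
  call <- rep("none", length(fc))
  call[fc >= up_fc] <- "up"
  call[fc <= 1 / up_fc] <- "down"
  data.frame(
    gene_id = rownames(gene_mat)[ok],
    contrast = contrast,
    log2_fc = unname(lfc),
    fc = unname(fc),
    call = factor(call, levels = c("up", "down", "none")),
    row.names = NULL
  )
}

#' Select genes past a stronger fold-change cutoff
#'
#' Convenience selector for downstream functional annotation, which often
#' requires a smaller input list: keeps genes whose fold change is at least
#' `min_fc` or at most `1/min_fc` (default 3-fold either way).
#'
#' @param fc_table Data.frame from [call_fold_changes()].
#' @param min_fc Fold-change magnitude cutoff.
#' @return Character vector of gene ids.
#' @export
select_high_fold_change <- function(fc_table, min_fc = 3.0) {
  fc_table$gene_id[fc_table$fc >= min_fc | fc_table$fc <= 1 / min_fc]
}

#' Count shared and specific calls among three contrasts
#'
#' Computes the seven Venn-region counts for three labelled id sets (e.g.
#' probes up-regulated in each of three senescence models).
#'
#' @param sets Named list of exactly three character vectors.
#' @return Data.frame with columns `region` (e.g. `"A"`, `"A&B"`,
#'   `"A&B&C"` using the set names) and `count`; attribute `union_size`
#'   holds the size of the union (equal to `sum(count)`).
#' @export
count_shared_calls <- function(sets) {
  if (length(sets) != 3 || is.null(names(sets)) || any(names(sets) == "")) {
    stop("'sets' must be a named list of three id vectors")
  }
  ids <- unique(unlist(sets, use.names = FALSE))
  mem <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) mem <- matrix(mem, nrow = 1, dimnames = list(NULL, names(sets)))
  nm <- names(sets)
  patterns <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                          c = c(TRUE, FALSE))
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  region <- apply(patterns, 1, function(r) paste(nm[as.logical(r)], collapse = "&"))
  key <- apply(patterns, 1, paste, collapse = ".")
  obs_key <- apply(mem, 1, paste, collapse = ".")
  count <- as.vector(table(factor(obs_key, levels = key)))
  out <- data.frame(region = region, count = count, row.names = NULL)
  attr(out, "union_size") <- length(ids)
  out
}

#' Uncentered-correlation distance between samples
#'
#' The sample-clustering distance used for expression heatmaps: the
#' uncentered (non-mean-subtracted) correlation
#' \deqn{r_u(x, y) = \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}}
#' turned into a distance `1 - r_u`. The matrix is symmetric with a zero
#' diagonal; distances range over `[0, 2]`.
#'
#' @param mat Numeric matrix (features x samples), >= 2 samples, no sample
#'   with zero norm.
#' @return Symmetric distance matrix (samples x samples).
#' @seealso [average_linkage_clustering()]
#' @export
uncentered_correlation_distance <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 samples")
  if (anyNA(mat)) stop("missing values not supported in the distance")
  norms <- sqrt(colSums(mat^2))
  if (any(norms == 0)) {
    stop("zero-norm sample: ", colnames(mat)[norms == 0][1])
  }
  r <- crossprod(mat) / tcrossprod(norms)
  d <- 1 - r
  diag(d) <- 0
  d
}

#' Average-linkage dendrogram from a distance matrix
#'
#' @param d Symmetric distance matrix, e.g. from
#'   [uncentered_correlation_distance()].
#' @return An [stats::hclust] object (average linkage).
#' @export
average_linkage_clustering <- function(d) {
  stats::hclust(stats::as.dist(d), method = "average")
}
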