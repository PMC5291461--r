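#' Compute beta values from allele intensities
#'
#' The methylation level of a CpG site on the BeadChip is summarised as
#' \deqn{\beta = M / (U + M + offset)}
#' where `M` and `U` are the intensities of the methylated and unmethylated
#' allele and the offset (100 by default) regularises low-intensity probes.
#' Beta therefore lies in `[0, 1)`.
#'
#' @param m Methylated-allele intensity (vector or matrix), non-negative.
#' @param u Unmethylated-allele intensity, same shape as `m`, non-negative.
#' @param offset Regularising constant added to the denominator.
#' @return Beta values with the shape of `m`.
#' @examples
#' beta_from_intensities(400, 500)  # 0.4
#' @export
beta_from_intensities <- function(m, u, offset = 100) {
  if (any(m < 0, na.rm = TRUE) || any(u < 0, na.rm = TRUE)) {
    stop("allele intensities must be non-negative")
  }
  if (offset <= 0) stop("'offset' must be positive")
  m / (u + m + offset)
}

#' Filter probes by detection p-value and missingness
#'
#' A probe is eliminated from all further analysis if, in *any* sample of the
#' analysis set, its detection p-value exceeds `p_max` (strictly; p equal to
#' the threshold is retained) or its beta value is blank. This analysis-set
#' wide rule keeps every contrast on an identical probe universe.
#'
#' @param bs A [beta_set()].
#' @param p_max Detection p-value threshold; probes with p `> p_max` fail.
#' @param samples Optional character vector restricting the analysis set to
#'   these sample columns before filtering.
#' @return A `beta_set` containing only the surviving probes (and, if
#'   `samples` was given, only those columns), with an attribute
#'   `n_removed` giving the number of probes eliminated.
#' @export
filter_probes <- function(bs, p_max = 0.05, samples = NULL) {
  stopifnot(inherits(bs, "beta_set"))
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(bs$beta))
    if (length(missing_s)) {
      stop("samples not present: ", paste(missing_s, collapse = ", "))
    }
    bs <- bs[, samples]
  }
  ok_beta <- rowSums(is.na(bs$beta)) == 0
  ok_p <- rowSums(is.na(bs$detection_p) | bs$detection_p > p_max) == 0
  keep <- ok_beta & ok_p
  out <- bs[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Call differential methylation between two samples
#'
#' Computes the per-probe beta difference (test minus control) and calls each
#' probe hypermethylated when the difference is at or above `delta_beta`,
#' hypomethylated when at or below `-delta_beta`, and unchanged otherwise.
#' Both thresholds are inclusive. The study design this mirrors used single
#' arrays per passage, so the difference is taken between single-sample beta
#' values and no variance model is fitted.
#'
#' @param bs A [beta_set()] or bare beta matrix (probes x samples).
#' @param test,control Sample column names of the senescent (test) and
#'   proliferating (control) arrays.
#' @param delta_beta Call threshold on the beta difference (default 0.2).
#' @return A data.frame with columns `probe_id`, `beta_control`, `beta_test`,
#'   `delta_beta` and `call` (factor: hyper/hypo/none). Probes with a missing
#'   beta in either sample are excluded.
#' @export
call_differential <- function(bs, test, control, delta_beta = 0.2) {
  beta <- as_beta_matrix(bs)
  for (s in c(test, control)) {
    if (!s %in% colnames(beta)) stop("sample not present: ", s)
  }
  if (delta_beta <= 0) stop("'delta_beta' must be positive")
  bt <- beta[, test]
  bc <- beta[, control]
  ok <- !is.na(bt) & !is.na(bc)
  d <- bt[ok] - bc[ok]
  call <- rep("none", length(d))
  # tiny tolerance keeps the documented inclusive boundary inclusive when
  # decimal beta values land on it up to floating-point representation
  eps <- 1e-9
  call[d >= delta_beta - eps] <- "hyper"
  call[d <= -delta_beta + eps] <- "hypo"
  data.frame(
    probe_id = rownames(beta)[ok],
    beta_control = unname(bc[ok]),
    beta_test = unname(bt[ok]),
    delta_beta = unname(d),
    call = factor(call, levels = c("hyper", "hypo", "none")),
    row.names = NULL
  )
}

#' Flag sequential (stepwise) methylation change across a passage series
#'
#' A probe called hypermethylated at the final passage shows *sequential*
#' change when its beta value is non-decreasing across every pair of
#' consecutive passages, up to a tolerance `epsilon`
#' (`beta[i+1] >= beta[i] - epsilon`); the mirrored rule applies to
#' hypomethylated probes. Probes without a call get `NA`. This separates
#' methylation drift accumulated over population doublings from one-off
#' changes appearing only in the terminal comparison.
#'
#' @param bs A [beta_set()] or beta matrix containing all passage columns.
#' @param passages Ordered character vector (>= 3) of passage sample labels,
#'   earliest first.
#' @param calls Data.frame from [call_differential()] computed between the
#'   final and first passage.
#' @param epsilon Non-negative tolerance for dips/bumps between consecutive
#'   passages (default 0: strict non-decrease / non-increase).
#' @return `calls` with an added logical column `sequential` (`NA` for
#'   probes with call `none`).
#' @export
classify_sequential <- function(bs, passages, calls, epsilon = 0) {
  beta <- as_beta_matrix(bs)
  if (length(passages) < 3) stop("need at least 3 ordered passages")
  if (epsilon < 0) stop("'epsilon' must be non-negative")
  missing_s <- setdiff(passages, colnames(beta))
  if (length(missing_s)) {
    stop("passage labels not present in the beta matrix: ",
         paste(missing_s, collapse = ", "))
  }
  b <- beta[match(calls$probe_id, rownames(beta)), passages, drop = FALSE]
  if (anyNA(b)) stop("missing beta values within the passage series")
  steps <- b[, -1, drop = FALSE] - b[, -ncol(b), drop = FALSE]
  non_decreasing <- rowSums(steps < -epsilon) == 0
  non_increasing <- rowSums(steps > epsilon) == 0
  seq_flag <- rep(NA, nrow(calls))
  hyper <- calls$call == "hyper"
  hypo <- calls$call == "hypo"
  seq_flag[hyper] <- non_decreasing[hyper]
  seq_flag[hypo] <- non_increasing[hypo]
  calls$sequential <- seq_flag
  calls
}

# Canonical subcategory orders (manifest vocabulary).
CPG_CONTEXTS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
GENE_FEATURES <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")
GENE_FEATURES_ALL <- c(GENE_FEATURES, "Intergenic")

#' Summarise differential-methylation calls by subcategory
#'
#' Tallies hyper- and hypomethylation calls over the six CpG-context
#' subcategories (island, north/south shore, north/south shelf, open sea)
#' and the seven gene-feature subcategories (TSS1500, TSS200, 5'UTR, first
#' exon, gene body, 3'UTR, intergenic). Each probe has exactly one CpG
#' context, so the context totals sum to the number of analysed probes; a
#' probe annotated to several genes contributes once per gene-feature
#' annotation, and probes with no gene annotation form the intergenic
#' bucket.
#'
#' @param calls Data.frame from [call_differential()].
#' @param probes Probe annotation data.frame (see [read_probe_annotation()]).
#' @return A list with data.frames `cpg_context` and `gene_feature`, each
#'   with per-subcategory columns `total`, `n_hyper`, `n_hypo`,
#'   `hyper_rate`, `hypo_rate` and `rate_ratio` (hyper rate / hypo rate,
#'   `NA` where undefined).
#' @export
summarize_subcategories <- function(calls, probes) {
  idx <- match(calls$probe_id, probes$probe_id)
  if (anyNA(idx)) stop("calls contain probes absent from the annotation")
  ann <- probes[idx, , drop = FALSE]

  make_summary <- function(group, call, levels) {
    g <- factor(group, levels = levels)
    total <- as.vector(table(g))
    n_hyper <- as.vector(table(g[call == "hyper"]))
    n_hypo <- as.vector(table(g[call == "hypo"]))
    hyper_rate <- ifelse(total > 0, n_hyper / total, NA_real_)
    hypo_rate <- ifelse(total > 0, n_hypo / total, NA_real_)
    ratio <- ifelse(!is.na(hyper_rate) & !is.na(hypo_rate) & hypo_rate > 0,
                    hyper_rate / hypo_rate, NA_real_)
    data.frame(subcategory = levels, total = total, n_hyper = n_hyper,
               n_hypo = n_hypo, hyper_rate = hyper_rate,
               hypo_rate = hypo_rate, rate_ratio = ratio, row.names = NULL)
  }

  cpg <- make_summary(ann$cpg_context, calls$call, CPG_CONTEXTS)

  feat <- probe_gene_features(ann)
  feat_call <- calls$call[match(feat$probe_id, calls$probe_id)]
  gf <- make_summary(feat$feature, feat_call, GENE_FEATURES_ALL)

  list(cpg_context = cpg, gene_feature = gf)
}

#' Squared Pearson correlation between two beta profiles
#'
#' The statistic shown on between-sample beta scatter plots: the squared
#' Pearson correlation coefficient over pairwise non-missing beta values.
#'
#' @param a,b Numeric beta vectors of equal length.
#' @return A list with `r_squared` and `n_pairs` (pairs used).
#' @export
beta_scatter_stats <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]
  b <- b[ok]
  if (length(a) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant beta vector")
  }
  r <- stats::cor(a, b)
  list(r_squared = r^2, n_pairs = length(a))
}
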