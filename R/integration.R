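#' Map CpG probes to the nearest transcription start site
#'
#' Each probe is assigned to the minimum-distance TSS on its own chromosome,
#' provided that distance does not exceed `window` (8 kb by default);
#' otherwise the probe is left unmapped. Distance is the unsigned base-pair
#' separation `|pos - tss|` (CpG sites are strand-symmetric, so probe strand
#' plays no role); a signed distance (`pos - tss`) is retained for
#' diagnostics. Every isoform row in `genes` competes independently in the
#' search. Ties - several TSSs equidistant from a probe, or several genes
#' sharing one TSS - are broken by the lexicographically smallest `gene_id`,
#' which makes the mapping deterministic and invariant to gene-table row
#' order.
#'
#' @param probes Probe annotation data.frame with `probe_id`, `chrom`, `pos`.
#' @param genes Gene model data.frame with `gene_id`, `chrom`, `tss`.
#' @param window Maximum probe-TSS distance in bp (inclusive).
#' @return Data.frame with one row per input probe: `probe_id`, `gene_id`
#'   (`NA` when unmapped), `tss`, `distance`, `signed_distance`.
#' @export
map_probes_to_nearest_tss <- function(probes, genes, window = 8000) {
  n <- nrow(probes)
  out <- data.frame(
    probe_id = probes$probe_id,
    gene_id = NA_character_,
    tss = NA_integer_,
    distance = NA_integer_,
    signed_distance = NA_integer_,
    row.names = NULL
  )
  for (ch in unique(probes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    # one candidate per distinct TSS position: the smallest gene_id there
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    g <- g[!duplicated(g$tss), , drop = FALSE]
    tss <- g$tss
    ids <- g$gene_id
    pi <- which(probes$chrom == ch)
    pos <- probes$pos[pi]
    i <- findInterval(pos, tss)
    left <- pmax(i, 1L)
    right <- pmin(i + 1L, length(tss))
    dl <- abs(pos - tss[left])
    dr <- abs(pos - tss[right])
    dl[i == 0L] <- Inf
    dr[i >= length(tss)] <- Inf
    take_left <- dl < dr |
      (dl == dr & ids[left] <= ids[right])
    pick <- ifelse(take_left, left, right)
    d <- pmin(dl, dr)
    ok <- d <= window
    out$gene_id[pi[ok]] <- ids[pick[ok]]
    out$tss[pi[ok]] <- tss[pick[ok]]
    out$distance[pi[ok]] <- as.integer(d[ok])
    out$signed_distance[pi[ok]] <- as.integer(pos[ok] - tss[pick[ok]])
  }
  out
}

#' Joint methylation-expression call for probe-gene pairs
#'
#' Combines the nearest-TSS mapping with differential-methylation calls and
#' gene-level expression fold changes. A pair is `hyper_down` when the probe
#' is hypermethylated and the nearest gene's expression fold change is at or
#' below the down threshold; `hypo_up` when the probe is hypomethylated and
#' the gene is up-regulated; `none` otherwise. Pairs whose gene lacks an
#' expression value are retained with call `none` and flagged.
#'
#' @param mapped Output of [map_probes_to_nearest_tss()] (unmapped rows are
#'   ignored).
#' @param meth_calls Data.frame from [call_differential()].
#' @param fc_table Data.frame from [call_fold_changes()].
#' @param delta_beta Methylation threshold (must match the one used for the
#'   calls; used here only for documentation of the rule).
#' @param up_fc Expression fold-change threshold; the down rule uses its
#'   reciprocal.
#' @return Data.frame with columns `probe_id`, `gene_id`, `distance`,
#'   `delta_beta`, `fc`, `joint_call` (factor hyper_down/hypo_up/none) and
#'   `has_expression`.
#' @export
joint_call <- function(mapped, meth_calls, fc_table, delta_beta = 0.2,
                       up_fc = 2.0) {
  m <- mapped[!is.na(mapped$gene_id), , drop = FALSE]
  mi <- match(m$probe_id, meth_calls$probe_id)
  if (anyNA(mi)) {
    stop("mapped probes missing from the methylation calls: ",
         m$probe_id[is.na(mi)][1])
  }
  fi <- match(m$gene_id, fc_table$gene_id)
  has_expr <- !is.na(fi)
  if (any(!has_expr)) {
    message(sum(!has_expr), " pair(s) without expression data kept as 'none'")
  }
  call <- meth_calls$call[mi]
  fc <- ifelse(has_expr, fc_table$fc[fi], NA_real_)
  jc <- rep("none", nrow(m))
  jc[has_expr & call == "hyper" & fc <= 1 / up_fc] <- "hyper_down"
  jc[has_expr & call == "hypo" & fc >= up_fc] <- "hypo_up"
  data.frame(
    probe_id = m$probe_id,
    gene_id = m$gene_id,
    distance = m$distance,
    delta_beta = meth_calls$delta_beta[mi],
    fc = fc,
    joint_call = factor(jc, levels = c("hyper_down", "hypo_up", "none")),
    has_expression = has_expr,
    row.names = NULL
  )
}

#' Distance-to-TSS distribution by promoter class
#'
#' Bins probe-TSS distances (0 to `max_distance` in `bin_width` steps,
#' left-closed bins) separately for probes whose nearest gene has a CGI or
#' a non-CGI promoter, and reports the aggregate count of probes within
#' 1 kb of the TSS per class.
#'
#' @param mapped Data.frame with `gene_id` and `distance` columns (from
#'   [map_probes_to_nearest_tss()] or [joint_call()]); unmapped rows are
#'   ignored.
#' @param promoter_classes Data.frame from [classify_promoters()] (columns
#'   `gene_id`, `class`).
#' @param bin_width Histogram bin width in bp.
#' @param max_distance Upper bound of the binned range in bp.
#' @return List with `histogram` (data.frame: `bin_start`, `bin_end`,
#'   `class`, `count`) and `within_1kb` (data.frame: `class`, `count`).
#' @export
distance_distribution <- function(mapped, promoter_classes, bin_width = 250,
                                  max_distance = 8000) {
  m <- mapped[!is.na(mapped$gene_id), , drop = FALSE]
  cls <- promoter_classes$class[match(m$gene_id, promoter_classes$gene_id)]
  if (anyNA(cls)) {
    stop("promoter class missing for gene: ",
         m$gene_id[is.na(cls)][1])
  }
  cls <- factor(as.character(cls), levels = c("CGI", "nonCGI"))
  breaks <- seq(0, max_distance, by = bin_width)
  if (breaks[length(breaks)] < max_distance) breaks <- c(breaks, max_distance)
  bin <- cut(m$distance, breaks = breaks, right = FALSE,
             include.lowest = FALSE)
  # distances equal to max_distance fall in the last bin
  bin[m$distance == max_distance] <- levels(bin)[length(levels(bin))]
  tab <- table(bin, cls)
  hist <- data.frame(
    bin_start = rep(breaks[-length(breaks)], times = ncol(tab)),
    bin_end = rep(breaks[-1], times = ncol(tab)),
    class = rep(colnames(tab), each = nrow(tab)),
    count = as.vector(tab),
    row.names = NULL
  )
  within <- table(cls[m$distance <= 1000])
  list(
    histogram = hist,
    within_1kb = data.frame(class = names(within),
                            count = as.vector(within), row.names = NULL)
  )
}

# Functional groups used to summarise annotation terms in this analysis.
FUNCTIONAL_GROUPS <- c("immune response", "metabolic process", "transport",
                       "cell adhesion", "development", "signal transduction",
                       "transcription", "others")

#' Functional-group ratios per gene subcategory
#'
#' Cross-tabulates user-supplied functional-group assignments (e.g. derived
#' from an external annotation-enrichment tool) over gene sets defined per
#' subcategory and direction of change. Genes absent from the map are
#' counted in the `"others"` group. Empty gene sets yield zero counts and
#' missing fractions.
#'
#' @param gene_sets Named list of character vectors of gene ids (names
#'   identify the subcategory/direction cell).
#' @param gene_groups Data.frame with columns `gene_id`, `group`.
#' @param groups Character vector of group levels; the last level collects
#'   unmapped genes.
#' @return Data.frame with columns `set`, `group`, `count`, `fraction`
#'   (fraction of the set's genes; `NA` for empty sets).
#' @export
functional_group_ratios <- function(gene_sets, gene_groups,
                                    groups = FUNCTIONAL_GROUPS) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  other <- groups[length(groups)]
  res <- lapply(names(gene_sets), function(nm) {
    g <- unique(gene_sets[[nm]])
    grp <- gene_groups$group[match(g, gene_groups$gene_id)]
    grp[is.na(grp) | !grp %in% groups] <- other
    tab <- table(factor(grp, levels = groups))
    data.frame(
      set = nm,
      group = groups,
      count = as.vector(tab),
      fraction = if (length(g)) as.vector(tab) / length(g) else NA_real_,
      row.names = NULL
    )
  })
  do.call(rbind, res)
}
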