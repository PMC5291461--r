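#' Select methylation probes annotated to miRNA genes
#'
#' Finds manifest probes whose gene annotation names a miRNA host gene
#' (symbols such as `MIR7-1` or `MIRLET7A`) and maps each probe to those
#' symbols. The match is anchored and word-boundary aware - `MIR` must be
#' followed by a digit or `LET`, so symbols like `MIRROR1` never match. By
#' default only promoter-region annotations (features TSS1500 and TSS200)
#' qualify; pass `features = NULL` to accept any feature.
#'
#' @param probes Probe annotation data.frame.
#' @param features Character vector of qualifying gene features, or `NULL`
#'   for no restriction.
#' @param pattern Regular expression identifying miRNA gene symbols.
#' @return Data.frame with columns `probe_id`, `mirna_symbol`, `feature`.
#' @export
select_mirna_probes <- function(probes, features = c("TSS1500", "TSS200"),
                                pattern = "^MIR(LET)?[0-9]") {
  feat <- probe_gene_features(probes)
  keep <- !is.na(feat$gene) & grepl(pattern, feat$gene)
  if (!is.null(features)) keep <- keep & feat$feature %in% features
  out <- feat[keep, , drop = FALSE]
  out <- unique(data.frame(probe_id = out$probe_id, mirna_symbol = out$gene,
                           feature = out$feature, row.names = NULL))
  out
}

#' Normalize miRNA expression intensities by a percentile shift
#'
#' Log2-transforms raw miRNA array intensities and shifts each sample so
#' that its 90th percentile (by default) becomes zero. Shift normalization
#' makes the result invariant to any common rescaling of a sample's raw
#' intensities.
#'
#' @param raw Numeric matrix of strictly positive raw intensities
#'   (miRNAs x samples).
#' @param percentile Per-sample percentile (in `[0, 100]`) shifted to zero.
#' @return Matrix of normalized log2 intensities.
#' @export
normalize_mirna <- function(raw, percentile = 90) {
  raw <- as.matrix(raw)
  if (ncol(raw) == 0 || nrow(raw) == 0) stop("empty intensity matrix")
  if (any(raw <= 0, na.rm = TRUE)) stop("intensities must be positive")
  empty <- colSums(!is.na(raw)) == 0
  if (any(empty)) stop("sample with no values: ", colnames(raw)[empty][1])
  x <- log2(raw)
  shift <- apply(x, 2, stats::quantile, probs = percentile / 100,
                 na.rm = TRUE, names = FALSE, type = 7)
  sweep(x, 2, shift, "-")
}

#' Call concordance between miRNA promoter methylation and expression
#'
#' A miRNA is concordant `hyper_down` when at least one of its promoter
#' probes is hypermethylated and its expression falls by at least the
#' fold-change cutoff (fc <= 1/`fc_cut`); concordant `hypo_up` when at
#' least one promoter probe is hypomethylated and expression rises by at
#' least the cutoff. Both directions are always evaluated. Manifest host
#' gene symbols and mature miRNA names from the expression array differ, so
#' an alias table supplies the harmonization; with `alias = NULL` the
#' symbols are used as-is. miRNAs with promoter methylation but no
#' expression measurement are reported as unevaluable.
#'
#' @param mirna_probes Data.frame from [select_mirna_probes()].
#' @param meth_calls Data.frame from [call_differential()].
#' @param mirna_fc Data.frame with columns `mirna_id`, `fc` (linear-scale
#'   expression ratio, senescent / control).
#' @param alias Optional data.frame with columns `mirna_symbol`,
#'   `mirna_id` mapping manifest symbols to mature names.
#' @param fc_cut Expression fold-change cutoff (default 1.5).
#' @return Data.frame with one row per miRNA: `mirna_id`, `n_probes`,
#'   `max_delta_beta`, `min_delta_beta`, `fc`, `evaluable`, `concordance`
#'   (factor hyper_down/hypo_up/none, `NA` when unevaluable).
#' @export
call_concordance <- function(mirna_probes, meth_calls, mirna_fc,
                             alias = NULL, fc_cut = 1.5) {
  if (fc_cut <= 1) stop("'fc_cut' must exceed 1")
  mp <- mirna_probes
  if (!is.null(alias)) {
    id <- alias$mirna_id[match(mp$mirna_symbol, alias$mirna_symbol)]
    mp$mirna_id <- ifelse(is.na(id), mp$mirna_symbol, id)
  } else {
    mp$mirna_id <- mp$mirna_symbol
  }
  mi <- match(mp$probe_id, meth_calls$probe_id)
  mp <- mp[!is.na(mi), , drop = FALSE]
  mi <- mi[!is.na(mi)]
  mp$delta_beta <- meth_calls$delta_beta[mi]
  mp$call <- as.character(meth_calls$call[mi])
  ids <- sort(unique(mp$mirna_id))
  res <- lapply(ids, function(id) {
    rows <- mp[mp$mirna_id == id, , drop = FALSE]
    fc <- mirna_fc$fc[match(id, mirna_fc$mirna_id)]
    evaluable <- !is.na(fc)
    conc <- NA_character_
    if (evaluable) {
      conc <- "none"
      if (any(rows$call == "hyper") && fc <= 1 / fc_cut) conc <- "hyper_down"
      if (any(rows$call == "hypo") && fc >= fc_cut) conc <- "hypo_up"
    }
    data.frame(
      mirna_id = id,
      n_probes = nrow(rows),
      max_delta_beta = max(rows$delta_beta),
      min_delta_beta = min(rows$delta_beta),
      fc = fc,
      evaluable = evaluable,
      concordance = conc,
      row.names = NULL
    )
  })
  out <- do.call(rbind, res)
  out$concordance <- factor(out$concordance,
                            levels = c("hyper_down", "hypo_up", "none"))
  out
}

#' Filter targeted genes supported by multiple concordant miRNAs
#'
#' The final step of the miRNA axis: a gene passes when (i) it is targeted
#' by at least `min_mirnas` concordant miRNAs of the same direction and
#' (ii) its own expression change is opposite in direction and past the
#' `gene_fc` cutoff - up-regulated genes (fc >= `gene_fc`) require
#' `hyper_down` miRNA support (the miRNAs are silenced, releasing the
#' target), down-regulated genes (fc <= 1/`gene_fc`) require `hypo_up`
#' support. Target predictions are consumed as an input table and never
#' computed here.
#'
#' @param concordance Data.frame from [call_concordance()].
#' @param targets Data.frame with columns `mirna_id`, `gene_id` (one row
#'   per predicted miRNA-target link).
#' @param gene_fc_table Data.frame with columns `gene_id`, `fc`.
#' @param min_mirnas Minimum number of supporting concordant miRNAs
#'   (default 2, inclusive).
#' @param gene_fc Gene expression fold-change cutoff (default 2).
#' @return Data.frame with one row per passing gene: `gene_id`, `fc`,
#'   `direction` (`up` or `down`), `n_support`, `mirnas`
#'   (comma-separated supporting miRNA ids, sorted), sorted by `gene_id`.
#' @export
triad_filter <- function(concordance, targets, gene_fc_table,
                         min_mirnas = 2, gene_fc = 2.0) {
  if (min_mirnas < 1) stop("'min_mirnas' must be at least 1")
  if (gene_fc <= 1) stop("'gene_fc' must exceed 1")
  conc <- concordance[!is.na(concordance$concordance) &
                        concordance$concordance != "none", , drop = FALSE]
  t_ok <- targets[targets$mirna_id %in% conc$mirna_id, , drop = FALSE]
  if (nrow(t_ok) == 0) {
    return(data.frame(gene_id = character(), fc = numeric(),
                      direction = character(), n_support = integer(),
                      mirnas = character()))
  }
  t_ok$direction <- as.character(
    conc$concordance[match(t_ok$mirna_id, conc$mirna_id)])
  res <- lapply(split(t_ok, t_ok$gene_id), function(rows) {
    fc <- gene_fc_table$fc[match(rows$gene_id[1], gene_fc_table$gene_id)]
    if (is.na(fc)) return(NULL)
    down_support <- sort(unique(rows$mirna_id[rows$direction == "hyper_down"]))
    up_support <- sort(unique(rows$mirna_id[rows$direction == "hypo_up"]))
    if (fc >= gene_fc && length(down_support) >= min_mirnas) {
      support <- down_support
      direction <- "up"
    } else if (fc <= 1 / gene_fc && length(up_support) >= min_mirnas) {
      support <- up_support
      direction <- "down"
    } else {
      return(NULL)
    }
    data.frame(gene_id = rows$gene_id[1], fc = fc, direction = direction,
               n_support = length(support),
               mirnas = paste(support, collapse = ","), row.names = NULL)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), fc = numeric(),
                      direction = character(), n_support = integer(),
                      mirnas = character())
  }
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reference triad table from the replicative-senescence miRNA axis
#'
#' Loads the bundled reference table of up-regulated genes supported by
#' two or more promoter-hypermethylated, down-regulated miRNAs in
#' replicatively senescent fibroblasts (27 genes, 7 distinct miRNAs), as a
#' published example of the triad filter's expected output shape.
#'
#' @return Data.frame with columns `gene_id`, `fc`, `mirnas`
#'   (comma-separated supporting miRNAs).
#' @export
reference_triad_table <- function() {
  path <- system.file("extdata", "senescence_triad_reference.tsv",
                      package = "senemeth", mustWork = TRUE)
  df <- utils::read.delim(path, colClasses = "character")
  df$fc <- as.numeric(df$fc)
  df
}
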