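#' Read a methylation-probe annotation table
#'
#' Two dialects are supported:
#'
#' * `"illumina450k"` — a manifest-style CSV with (at minimum) columns
#'   `IlmnID`, `CHR`, `MAPINFO`, `STRAND`, `RELATION_TO_UCSC_CPG_ISLAND`,
#'   `UCSC_REFGENE_NAME`, `UCSC_REFGENE_GROUP`. `MAPINFO` is 1-based and is
#'   converted to the package's 0-based convention on read (position minus
#'   one); a blank island relation means open sea; gene name/group cells hold
#'   semicolon-separated parallel lists.
#' * `"simple"` — a tab-separated table with the package's own columns
#'   `probe_id`, `chrom`, `pos` (0-based), `strand`, `cpg_context`,
#'   `refgene_names`, `refgene_groups` (semicolon-separated).
#'
#' Readers are strict: unknown CpG-context strings, duplicated probe ids,
#' mismatched gene/feature list lengths and malformed rows are errors that
#' name the offending line. Gzip-compressed files are read transparently.
#'
#' @param path Path to the annotation file (optionally `.gz`).
#' @param dialect `"illumina450k"` or `"simple"`.
#' @return A data.frame with columns `probe_id`, `chrom`, `pos` (0-based),
#'   `strand`, `cpg_context` (one of Island, N_Shore, S_Shore, N_Shelf,
#'   S_Shelf, OpenSea), `refgene_names`, `refgene_groups`
#'   (semicolon-separated, empty string for intergenic probes). Use
#'   [probe_gene_features()] to explode the per-gene annotations.
#' @export
read_probe_annotation <- function(path, dialect = c("simple", "illumina450k")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "illumina450k") {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
    required <- c("IlmnID", "CHR", "MAPINFO", "RELATION_TO_UCSC_CPG_ISLAND",
                  "UCSC_REFGENE_NAME", "UCSC_REFGENE_GROUP")
    missing_col <- setdiff(required, names(df))
    if (length(missing_col)) {
      stop("manifest lacks required columns: ", paste(missing_col, collapse = ", "))
    }
    pos <- suppressWarnings(as.numeric(df$MAPINFO))
    bad <- which(is.na(pos) | pos < 1)
    if (length(bad)) {
      stop("malformed MAPINFO at line ", bad[1] + 1L)
    }
    ctx <- df$RELATION_TO_UCSC_CPG_ISLAND
    ctx[ctx == ""] <- "OpenSea"
    strand <- if ("STRAND" %in% names(df)) df$STRAND else rep("+", nrow(df))
    strand[strand %in% c("F", "")] <- "+"
    strand[strand == "R"] <- "-"
    chrom <- ifelse(grepl("^chr", df$CHR), df$CHR, paste0("chr", df$CHR))
    out <- data.frame(
      probe_id = df$IlmnID,
      chrom = chrom,
      pos = as.integer(pos) - 1L,     # manifest is 1-based; internal is 0-based
      strand = strand,
      cpg_context = ctx,
      refgene_names = df$UCSC_REFGENE_NAME,
      refgene_groups = df$UCSC_REFGENE_GROUP,
      row.names = NULL
    )
  } else {
    df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
    required <- c("probe_id", "chrom", "pos", "strand", "cpg_context",
                  "refgene_names", "refgene_groups")
    missing_col <- setdiff(required, names(df))
    if (length(missing_col)) {
      stop("annotation lacks required columns: ", paste(missing_col, collapse = ", "))
    }
    pos <- suppressWarnings(as.numeric(df$pos))
    bad <- which(is.na(pos) | pos < 0)
    if (length(bad)) stop("malformed pos at line ", bad[1] + 1L)
    out <- df[required]
    out$pos <- as.integer(pos)
  }
  validate_probe_annotation(out)
  out
}

validate_probe_annotation <- function(probes) {
  dup <- which(duplicated(probes$probe_id))
  if (length(dup)) stop("duplicate probe_id: ", probes$probe_id[dup[1]])
  bad_ctx <- which(!probes$cpg_context %in% CPG_CONTEXTS)
  if (length(bad_ctx)) {
    stop("unknown CpG context '", probes$cpg_context[bad_ctx[1]],
         "' at line ", bad_ctx[1] + 1L)
  }
  bad_strand <- which(!probes$strand %in% c("+", "-"))
  if (length(bad_strand)) stop("bad strand at line ", bad_strand[1] + 1L)
  n_genes <- lengths(strsplit(probes$refgene_names, ";", fixed = TRUE))
  n_feat <- lengths(strsplit(probes$refgene_groups, ";", fixed = TRUE))
  bad_len <- which(n_genes != n_feat)
  if (length(bad_len)) {
    stop("gene/feature list length mismatch at line ", bad_len[1] + 1L)
  }
  invisible(probes)
}

#' Explode per-gene feature annotations of probes
#'
#' Splits the semicolon-separated `refgene_names` / `refgene_groups` columns
#' into one row per (probe, gene, feature) annotation. Probes with no gene
#' annotation yield a single row with the seventh gene-feature subcategory,
#' `Intergenic` (and `gene = NA`).
#'
#' @param probes Probe annotation data.frame.
#' @return Data.frame with columns `probe_id`, `gene`, `feature`.
#' @export
probe_gene_features <- function(probes) {
  genes <- strsplit(probes$refgene_names, ";", fixed = TRUE)
  feats <- strsplit(probes$refgene_groups, ";", fixed = TRUE)
  inter <- lengths(genes) == 0
  genes[inter] <- list(NA_character_)
  feats[inter] <- list("Intergenic")
  out <- data.frame(
    probe_id = rep(probes$probe_id, lengths(genes)),
    gene = unlist(genes, use.names = FALSE),
    feature = unlist(feats, use.names = FALSE),
    row.names = NULL
  )
  bad <- which(!out$feature %in% GENE_FEATURES_ALL)
  if (length(bad)) stop("unknown gene feature: ", out$feature[bad[1]])
  out
}

#' Write a probe annotation table
#'
#' @param probes Probe annotation data.frame.
#' @param path Output path.
#' @param dialect `"simple"` (tab-separated, 0-based) or `"illumina450k"`
#'   (manifest-style CSV, 1-based `MAPINFO`).
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(probes, path, dialect = c("simple", "illumina450k")) {
  dialect <- match.arg(dialect)
  if (dialect == "simple") {
    cols <- c("probe_id", "chrom", "pos", "strand", "cpg_context",
              "refgene_names", "refgene_groups")
    utils::write.table(probes[cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    ctx <- probes$cpg_context
    ctx[ctx == "OpenSea"] <- ""
    out <- data.frame(
      IlmnID = probes$probe_id,
      CHR = sub("^chr", "", probes$chrom),
      MAPINFO = probes$pos + 1L,
      STRAND = ifelse(probes$strand == "+", "F", "R"),
      RELATION_TO_UCSC_CPG_ISLAND = ctx,
      UCSC_REFGENE_NAME = probes$refgene_names,
      UCSC_REFGENE_GROUP = probes$refgene_groups
    )
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read gene models in UCSC refGene layout
#'
#' Parses the 16-column tab-separated `refGene.txt` layout (no header):
#' bin, name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd, exonCount,
#' exonStarts, exonEnds, score, name2, cdsStartStat, cdsEndStat, exonFrames.
#' Coordinates are 0-based half-open as deposited. The transcription start
#' site is derived per strand: `txStart` on `+`, `txEnd - 1` on `-`.
#' Duplicate accessions (isoforms with distinct coordinates) are retained as
#' separate rows; records on unplaced contigs are retained and flagged.
#'
#' @param path Path to a refGene-layout file (optionally `.gz`).
#' @return Data.frame with columns `gene_id`, `symbol`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `tss`, `unplaced`.
#' @export
read_refgene <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 13) stop("refGene layout requires at least 13 columns")
  tx_start <- suppressWarnings(as.integer(df[[5]]))
  tx_end <- suppressWarnings(as.integer(df[[6]]))
  bad <- which(is.na(tx_start) | is.na(tx_end))
  if (length(bad)) stop("malformed coordinates at line ", bad[1])
  bad <- which(tx_start >= tx_end)
  if (length(bad)) stop("txStart >= txEnd at line ", bad[1])
  strand <- df[[4]]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) stop("bad strand at line ", bad[1])
  data.frame(
    gene_id = df[[2]],
    symbol = df[[13]],
    chrom = df[[3]],
    strand = strand,
    tx_start = tx_start,
    tx_end = tx_end,
    tss = ifelse(strand == "+", tx_start, tx_end - 1L),
    unplaced = grepl("_", df[[3]]),
    row.names = NULL
  )
}

#' Write gene models in UCSC refGene layout
#'
#' Emits a minimal 16-column refGene.txt-layout file that [read_refgene()]
#' reads back identically (unused columns are filled with placeholders).
#'
#' @param genes Gene model data.frame (as from [read_refgene()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refgene <- function(genes, path) {
  out <- data.frame(
    bin = 0L,
    name = genes$gene_id,
    chrom = genes$chrom,
    strand = genes$strand,
    txStart = genes$tx_start,
    txEnd = genes$tx_end,
    cdsStart = genes$tx_start,
    cdsEnd = genes$tx_end,
    exonCount = 1L,
    exonStarts = paste0(genes$tx_start, ","),
    exonEnds = paste0(genes$tx_end, ","),
    score = 0L,
    name2 = genes$symbol,
    cdsStartStat = "cmpl",
    cdsEndStat = "cmpl",
    exonFrames = "0,"
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a tab-separated numeric matrix
#'
#' Reads a probes/genes x samples table: first column holds row ids, header
#' row holds sample labels. Blank cells become `NA` (missing), never zero.
#' Ragged rows and non-numeric cells are errors naming the line; with
#' `kind = "beta"` any value outside `[0, 1]` is an error.
#'
#' @param path Path to the file (optionally `.gz`).
#' @param kind `"numeric"` (any finite values) or `"beta"` (values must lie
#'   in `[0, 1]`).
#' @return Numeric matrix with row and column names.
#' @export
read_matrix <- function(path, kind = c("numeric", "beta")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # trailing blank cells are dropped by strsplit; pad to declared width
  header <- fields[[1]]
  ncol_expected <- length(header)
  body <- fields[-1]
  widths <- lengths(body)
  short_by_one <- widths == ncol_expected - 1L
  body[short_by_one] <- lapply(body[short_by_one], function(x) c(x, ""))
  widths <- lengths(body)
  bad <- which(widths != ncol_expected)
  if (length(bad)) stop("ragged row at line ", bad[1] + 1L)
  ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate row id: ", ids[duplicated(ids)][1])
  cells <- t(vapply(body, function(x) x[-1], character(ncol_expected - 1L)))
  if (ncol_expected == 2L) cells <- matrix(cells, ncol = 1L)
  vals <- suppressWarnings(as.numeric(cells))
  blank <- cells == "" | cells == "NA"
  bad_cell <- which(is.na(vals) & !blank)
  if (length(bad_cell)) {
    stop("non-numeric cell at line ",
         (bad_cell[1] - 1L) %% nrow(cells) + 2L)
  }
  m <- matrix(vals, nrow = nrow(cells), ncol = ncol(cells),
              dimnames = list(ids, header[-1]))
  if (kind == "beta") {
    v <- m[!is.na(m)]
    if (length(v) && (min(v) < 0 || max(v) > 1)) {
      stop("beta value out of [0, 1] range")
    }
  }
  m
}

#' Write a numeric matrix as tab-separated text
#'
#' Inverse of [read_matrix()]: row ids in the first column (header `id`),
#' `NA` written as empty cells. Numbers are written with full precision so
#' the write/read round trip is bit-identical.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  txt <- matrix(vapply(m, function(x) {
    if (is.na(x)) "" else format(x, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1)), nrow = nrow(m))
  lines <- c(
    paste(c("id", colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], txt[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a beta_set from a beta-value and a detection-p matrix file
#'
#' @param beta_path Path to the beta-value matrix (see [read_matrix()]).
#' @param detection_path Optional path to the detection p-value matrix with
#'   identical dimensions; if `NULL` all probes are treated as detected.
#' @return A [beta_set()].
#' @export
read_beta_set <- function(beta_path, detection_path = NULL) {
  beta <- read_matrix(beta_path, kind = "beta")
  detp <- if (is.null(detection_path)) NULL else read_matrix(detection_path)
  beta_set(beta, detp)
}

#' Write a beta_set to a pair of matrix files
#'
#' @param bs A [beta_set()].
#' @param beta_path,detection_path Output paths.
#' @return `beta_path`, invisibly.
#' @export
write_beta_set <- function(bs, beta_path, detection_path) {
  write_matrix(bs$beta, beta_path)
  write_matrix(bs$detection_p, detection_path)
  invisible(beta_path)
}
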