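#' Promoter window around a transcription start site
#'
#' Returns the genomic window used for promoter classification. On the plus
#' strand the window is `[tss - upstream, tss + downstream)`; on the minus
#' strand it is mirrored to `[tss - downstream, tss + upstream + 1)` so that
#' the same number of bases lies transcriptionally upstream. Windows are
#' clipped at contig bounds; a window falling entirely outside its contig is
#' an error. Coordinates are 0-based half-open throughout.
#'
#' @param genes Gene model data.frame (see [read_refgene()]) with columns
#'   `gene_id`, `chrom`, `strand`, `tss`.
#' @param upstream,downstream Window extent in bp relative to transcription
#'   direction (defaults 1000 and 500).
#' @param contig_lengths Named integer vector of contig lengths used for
#'   clipping; if `NULL` no right clipping is applied.
#' @return Data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_window <- function(genes, upstream = 1000, downstream = 500,
                            contig_lengths = NULL) {
  if (upstream < 0 || downstream < 0) stop("window extents must be non-negative")
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1L)
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[genes$chrom]
    if (anyNA(len)) {
      stop("contig length missing for: ",
           genes$chrom[is.na(len)][1])
    }
    outside <- start >= len | end <= 0
    if (any(outside)) {
      stop("promoter window entirely outside contig for gene ",
           genes$gene_id[outside][1])
    }
    end <- pmin(end, len)
  }
  start <- pmax(start, 0L)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             row.names = NULL)
}

#' Sequence composition statistics for CpG-island classification
#'
#' Computes, for each sequence, the GC fraction and the observed/expected
#' CpG ratio in the Gardiner-Garden convention,
#' \deqn{O/E = (\#CpG \times L) / (\#C \times \#G)}
#' with `L` the effective length (N bases excluded). If a sequence contains
#' no C or no G the ratio is defined as 0. Lowercase (soft-masked) bases are
#' counted; an all-N sequence is an error.
#'
#' @param seqs A [Biostrings::DNAStringSet], `DNAString`, or character
#'   vector of sequences over `{A, C, G, T, N}`.
#' @param max_n_frac Maximum tolerated fraction of N bases per sequence.
#' @return Data.frame with columns `length`, `effective_length`,
#'   `gc_fraction`, `oe_ratio`.
#' @export
cpg_composition <- function(seqs, max_n_frac = 0.5) {
  if (is.character(seqs) || inherits(seqs, "DNAString")) {
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  }
  stopifnot(inherits(seqs, "DNAStringSet"))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  freq <- Biostrings::letterFrequency(seqs, c("C", "G", "N"))
  len <- Biostrings::width(seqs)
  n_frac <- freq[, "N"] / pmax(len, 1L)
  if (any(n_frac == 1)) stop("all-N sequence cannot be classified")
  if (any(n_frac > max_n_frac)) {
    stop("sequence exceeds the tolerated N fraction (",
         max_n_frac, ")")
  }
  eff_len <- len - freq[, "N"]
  n_cg <- Biostrings::vcountPattern("CG", seqs)
  cxg <- freq[, "C"] * freq[, "G"]
  oe <- ifelse(cxg > 0, n_cg * eff_len / cxg, 0)
  data.frame(
    length = len,
    effective_length = eff_len,
    gc_fraction = (freq[, "C"] + freq[, "G"]) / eff_len,
    oe_ratio = oe,
    row.names = NULL
  )
}

#' Classify promoter windows as CGI or non-CGI
#'
#' A promoter is a CpG-island (CGI) promoter when its window satisfies both
#' compositional criteria (inclusive): GC content >= `gc_min` (default 50%)
#' and observed/expected CpG ratio >= `oe_min` (default 0.6). Statistics are
#' computed over the whole window on the plus strand; because the CpG
#' dinucleotide is its own reverse complement, the classification is
#' strand-symmetric.
#'
#' @param genome A [Biostrings::DNAStringSet] of contigs (names matching
#'   `genes$chrom`) or a path to a FASTA file.
#' @param genes Gene model data.frame with `gene_id`, `chrom`, `strand`,
#'   `tss`.
#' @param upstream,downstream Promoter window extent (see
#'   [promoter_window()]).
#' @param gc_min,oe_min Inclusive classification thresholds.
#' @param max_n_frac Maximum tolerated N fraction per window.
#' @return Data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `gc_fraction`, `oe_ratio`, `class` (factor CGI/nonCGI).
#' @export
classify_promoters <- function(genome, genes, upstream = 1000,
                               downstream = 500, gc_min = 0.5, oe_min = 0.6,
                               max_n_frac = 0.5) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(inherits(genome, "DNAStringSet"))
  contig_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  win <- promoter_window(genes, upstream, downstream, contig_lengths)
  seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(win)), function(i) {
    Biostrings::subseq(genome[[win$chrom[i]]], win$start[i] + 1L, win$end[i])
  }))
  comp <- cpg_composition(seqs, max_n_frac = max_n_frac)
  cls <- ifelse(comp$gc_fraction >= gc_min & comp$oe_ratio >= oe_min,
                "CGI", "nonCGI")
  data.frame(
    win,
    gc_fraction = comp$gc_fraction,
    oe_ratio = comp$oe_ratio,
    class = factor(cls, levels = c("CGI", "nonCGI")),
    row.names = NULL
  )
}

#' Write classified promoter windows as BED-like text
#'
#' Columns: chrom, start, end, gene_id, class, gc_fraction, oe_ratio
#' (tab-separated, 0-based half-open, with header).
#'
#' @param promoters Data.frame from [classify_promoters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoter_bed <- function(promoters, path) {
  out <- promoters[, c("chrom", "start", "end", "gene_id", "class",
                       "gc_fraction", "oe_ratio")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
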