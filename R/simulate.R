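#' Configuration for the synthetic-data generator
#'
#' Bundles and validates every knob of the simulation. The defaults emulate
#' the study design the pipeline was written for: a fibroblast passage
#' series profiled at four population-doubling levels with a minority of
#' CpG sites drifting monotonically towards hyper- or hypomethylation, a
#' toy genome carrying non-overlapping planted CGI and non-CGI promoters,
#' and expression tables with planted up/down genes and a miRNA axis
#' (concordant miRNAs plus target links) mirroring the published triad
#' structure.
#'
#' @param n_probes Number of methylation probes.
#' @param n_genes Number of genes (shared by the genome and expression
#'   generators).
#' @param n_mirnas Number of miRNAs on the expression array.
#' @param passage_labels Ordered sample labels of the passage series; any
#'   numeric suffixes must be strictly increasing.
#' @param frac_hyper_drift,frac_hypo_drift Fractions of probes planted with
#'   monotone hyper-/hypomethylation drift (their sum must not exceed 1).
#' @param drift_step Beta increment per passage step for drifting probes
#'   (must be positive).
#' @param beta_noise_sd Standard deviation of the truncated Gaussian noise
#'   added to beta values (0 for noise-free data).
#' @param frac_detection_fail Fraction of probes given one detection
#'   p-value above 0.05 to exercise filtering. Good entries draw their p
#'   from Uniform(0, 0.04) and planted failures from Uniform(0.06, 1), so
#'   no mass sits on the 0.05 boundary.
#' @param n_planted_cgi Number of genes given a planted CGI promoter; the
#'   remaining genes get non-CGI promoters.
#' @param genome_length Toy genome length in bp (must allow
#'   non-overlapping promoters: at least 1000 bp per planted CGI and
#'   3000 bp per gene overall).
#' @param expr_effect_log2 Planted log2 expression effect for up/down genes.
#' @param expr_noise_log2 Log2-scale noise s.d. for expression intensities.
#' @param n_concordant_mirnas Number of miRNAs planted with a
#'   hypermethylated promoter and down-regulated expression.
#' @param n_triad,n_decoy Number of planted triad genes (up-regulated,
#'   targeted by >= 2 concordant miRNAs) and of decoy genes (targeted by
#'   exactly one concordant miRNA).
#' @param seed Integer seed; fixing it reproduces every output exactly.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 1000,
                       n_genes = 50,
                       n_mirnas = 40,
                       passage_labels = c("PDL36", "PDL49", "PDL69", "PDL85"),
                       frac_hyper_drift = 0.1,
                       frac_hypo_drift = 0.1,
                       drift_step = 0.1,
                       beta_noise_sd = 0.01,
                       frac_detection_fail = 0.01,
                       n_planted_cgi = 25,
                       genome_length = 250000,
                       expr_effect_log2 = 2,
                       expr_noise_log2 = 0.1,
                       n_concordant_mirnas = 7,
                       n_triad = 5,
                       n_decoy = 5,
                       seed = 1L) {
  cfg <- list(n_probes = n_probes, n_genes = n_genes, n_mirnas = n_mirnas,
              passage_labels = passage_labels,
              frac_hyper_drift = frac_hyper_drift,
              frac_hypo_drift = frac_hypo_drift,
              drift_step = drift_step, beta_noise_sd = beta_noise_sd,
              frac_detection_fail = frac_detection_fail,
              n_planted_cgi = n_planted_cgi, genome_length = genome_length,
              expr_effect_log2 = expr_effect_log2,
              expr_noise_log2 = expr_noise_log2,
              n_concordant_mirnas = n_concordant_mirnas,
              n_triad = n_triad, n_decoy = n_decoy, seed = as.integer(seed))
  counts <- c(n_probes, n_genes, n_mirnas, genome_length)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (drift_step <= 0) stop("'drift_step' must be positive")
  if (beta_noise_sd < 0) stop("'beta_noise_sd' must be non-negative")
  if (frac_hyper_drift < 0 || frac_hypo_drift < 0 ||
      frac_hyper_drift + frac_hypo_drift > 1) {
    stop("drift fractions must be non-negative and sum to at most 1")
  }
  if (n_planted_cgi < 0 || n_planted_cgi > n_genes) {
    stop("'n_planted_cgi' must lie in [0, n_genes]")
  }
  if (genome_length < 1000 * max(n_planted_cgi, 1)) {
    stop("'genome_length' must be at least 1000 bp per planted CGI")
  }
  if (length(passage_labels) < 3) stop("need at least 3 passage labels")
  if (anyDuplicated(passage_labels)) stop("passage labels must be unique")
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", passage_labels)))
  if (!anyNA(num) && any(diff(num) <= 0)) {
    stop("passage labels must be in increasing order")
  }
  if (n_concordant_mirnas > n_mirnas) {
    stop("'n_concordant_mirnas' exceeds 'n_mirnas'")
  }
  if (n_triad + n_decoy > n_genes) stop("too many triad/decoy genes")
  class(cfg) <- "sim_config"
  cfg
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate a methylation passage series with planted drift
#'
#' Generates a beta-value matrix over the configured passage series. A
#' fraction of probes drifts monotonically upwards (hyper) or downwards
#' (hypo) by `drift_step` per passage, clipped to `[0, 1]`; the remainder
#' stays at a constant level. Truncated Gaussian noise of s.d.
#' `beta_noise_sd` is added to every entry. Probes carry CpG-context labels
#' from all six subcategories and gene-feature annotations covering all
#' seven subcategories (including intergenic probes with no gene); a small
#' fraction of probes receives one detection p-value above 0.05 so that
#' probe filtering has something to remove.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `beta` (a [beta_set()] over the passage
#'   labels), `probes` (annotation data.frame) and `truth` (data.frame
#'   with `probe_id`, `meth_class` in hyper_drift/hypo_drift/stable and
#'   `detection_fail`).
#' @export
generate_methylation_series <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_probes
  k <- length(cfg$passage_labels)
  n_hyper <- round(cfg$frac_hyper_drift * n)
  n_hypo <- round(cfg$frac_hypo_drift * n)
  meth_class <- sample(rep(c("hyper_drift", "hypo_drift", "stable"),
                           c(n_hyper, n_hypo, n - n_hyper - n_hypo)))
  probe_id <- sprintf("cg%07d", seq_len(n))

  start <- numeric(n)
  start[meth_class == "hyper_drift"] <- stats::runif(n_hyper, 0.05, 0.25)
  start[meth_class == "hypo_drift"] <- stats::runif(n_hypo, 0.75, 0.95)
  start[meth_class == "stable"] <- stats::runif(n - n_hyper - n_hypo, 0.05, 0.95)
  direction <- c(hyper_drift = 1, hypo_drift = -1, stable = 0)[meth_class]
  mu <- clip01(outer(start, rep(1, k)) +
                 outer(direction * cfg$drift_step, 0:(k - 1)))
  beta <- mu
  if (cfg$beta_noise_sd > 0) {
    beta <- clip01(mu + matrix(stats::rnorm(n * k, 0, cfg$beta_noise_sd), n, k))
  }
  dimnames(beta) <- list(probe_id, cfg$passage_labels)

  detp <- matrix(stats::runif(n * k, 0, 0.04), n, k,
                 dimnames = dimnames(beta))
  n_fail <- round(cfg$frac_detection_fail * n)
  fail_probes <- if (n_fail > 0) sample(n, n_fail) else integer(0)
  for (i in fail_probes) {
    detp[i, sample(k, 1)] <- stats::runif(1, 0.06, 1)
  }

  # annotation: contexts from all six subcategories, manifest-like mix
  ctx <- sample(CPG_CONTEXTS, n, replace = TRUE,
                prob = c(0.31, 0.13, 0.10, 0.05, 0.05, 0.36))
  ctx[seq_len(6)] <- CPG_CONTEXTS
  gene_pool <- sprintf("NM_%06d", seq_len(cfg$n_genes))
  is_intergenic <- stats::runif(n) < 0.25
  two_genes <- !is_intergenic & stats::runif(n) < 0.05
  g1 <- sample(gene_pool, n, replace = TRUE)
  g2 <- sample(gene_pool, n, replace = TRUE)
  f1 <- sample(GENE_FEATURES, n, replace = TRUE)
  f2 <- sample(GENE_FEATURES, n, replace = TRUE)
  refgene_names <- ifelse(is_intergenic, "",
                          ifelse(two_genes, paste(g1, g2, sep = ";"), g1))
  refgene_groups <- ifelse(is_intergenic, "",
                           ifelse(two_genes, paste(f1, f2, sep = ";"), f1))
  # guarantee all seven gene-feature subcategories are present
  is_intergenic[1] <- TRUE
  refgene_names[1] <- ""
  refgene_groups[1] <- ""
  for (j in seq_along(GENE_FEATURES)) {
    refgene_names[j + 1] <- g1[j + 1]
    refgene_groups[j + 1] <- GENE_FEATURES[j]
  }
  probes <- data.frame(
    probe_id = probe_id,
    chrom = "chr1",
    pos = sort(sample.int(2e8, n)),
    strand = "+",
    cpg_context = ctx,
    refgene_names = refgene_names,
    refgene_groups = refgene_groups,
    row.names = NULL
  )
  truth <- data.frame(
    probe_id = probe_id,
    meth_class = meth_class,
    detection_fail = seq_len(n) %in% fail_probes,
    row.names = NULL
  )
  list(beta = beta_set(beta, detp), probes = probes, truth = truth)
}

# 10-bp tiles used to build promoter windows with exact composition.
# All tiles end in A and start with C or G, so tile junctions never create
# a CpG dinucleotide and shuffling tile order leaves all counts unchanged.
TILE_CGI_CG <- "CGTAGCTGCA"   # GC 6/10, one CpG
TILE_CGI_NOCG <- "GACTGCTGCA" # GC 6/10, no CpG
TILE_NON_NOCG <- "GATTACTGCA" # GC 4/10, no CpG
TILE_NON_CG <- "CGATTAGTCA"   # GC 4/10, one CpG

build_promoter_sequence <- function(n_tiles, n_cg_tiles, cg_tile, nocg_tile,
                                    extra_base = FALSE) {
  tiles <- sample(rep(c(cg_tile, nocg_tile),
                      c(n_cg_tiles, n_tiles - n_cg_tiles)))
  paste0(paste(tiles, collapse = ""), if (extra_base) "A" else "")
}

#' Simulate a toy genome with planted CGI and non-CGI promoters
#'
#' Builds a single-contig genome of AT-rich background sequence and plants
#' one promoter window per gene, constructed compositionally from 10-bp
#' tiles so the ground truth is guaranteed rather than sampled: CGI
#' promoters have GC content 0.60 and observed/expected CpG ratio 1.0;
#' non-CGI promoters have GC 0.40 and O/E 0.2. Each gene's TSS is placed
#' so that its default promoter window (1000 bp upstream, 500 bp
#' downstream) coincides exactly with the planted window; strands
#' alternate so both orientations are represented. Planted windows never
#' overlap (this is checked and is an error if violated).
#'
#' @param cfg A [sim_config()].
#' @return List with elements `genome` (a [Biostrings::DNAStringSet] with
#'   one contig `chr1`), `genes` (gene model data.frame as from
#'   [read_refgene()]) and `truth` (data.frame `gene_id`,
#'   `promoter_class`).
#' @export
generate_genome_with_cgis <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n_genes <- cfg$n_genes
  cell <- as.integer(cfg$genome_length / n_genes)
  if (cell < 3000) {
    stop("genome too short: planted promoters would overlap")
  }
  promoter_class <- rep("nonCGI", n_genes)
  promoter_class[sample(n_genes, cfg$n_planted_cgi)] <- "CGI"
  strand <- rep(c("+", "-"), length.out = n_genes)

  genome <- sample(c("A", "T", "G", "C"), cfg$genome_length, replace = TRUE,
                   prob = c(0.42, 0.42, 0.08, 0.08))
  gene_id <- sprintf("NM_%06d", seq_len(n_genes))
  tss <- integer(n_genes)
  tx_start <- integer(n_genes)
  tx_end <- integer(n_genes)
  win_start <- integer(n_genes)
  win_end <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    ws <- (i - 1L) * cell + 1000L
    minus <- strand[i] == "-"
    n_tiles <- 150L
    if (promoter_class[i] == "CGI") {
      seq_i <- build_promoter_sequence(n_tiles, 135L, TILE_CGI_CG,
                                       TILE_CGI_NOCG, extra_base = minus)
    } else {
      seq_i <- build_promoter_sequence(n_tiles, 12L, TILE_NON_CG,
                                       TILE_NON_NOCG, extra_base = minus)
    }
    len <- nchar(seq_i)
    genome[(ws + 1L):(ws + len)] <- strsplit(seq_i, "")[[1]]
    win_start[i] <- ws
    win_end[i] <- ws + len
    if (minus) {
      tss[i] <- ws + 500L
      tx_end[i] <- tss[i] + 1L
      tx_start[i] <- tx_end[i] - 800L
    } else {
      tss[i] <- ws + 1000L
      tx_start[i] <- tss[i]
      tx_end[i] <- tss[i] + 800L
    }
  }
  ord <- order(win_start)
  if (any(win_start[ord][-1] < win_end[ord][-length(ord)])) {
    stop("planted promoter windows overlap")
  }
  genes <- data.frame(
    gene_id = gene_id,
    symbol = sprintf("GENE%03d", seq_len(n_genes)),
    chrom = "chr1",
    strand = strand,
    tx_start = tx_start,
    tx_end = tx_end,
    tss = tss,
    unplaced = FALSE,
    row.names = NULL
  )
  truth <- data.frame(gene_id = gene_id, promoter_class = promoter_class,
                      row.names = NULL)
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(genome, collapse = ""), "chr1"))
  list(genome = genome, genes = genes, truth = truth)
}

#' Simulate expression, miRNA and target tables with planted structure
#'
#' Generates (i) a raw gene-expression intensity table over a control and a
#' senescent sample, with planted up/down genes differing by
#' `expr_effect_log2` on the log2 scale and a subset of genes measured by
#' two probes to exercise probe-to-gene aggregation; (ii) a raw miRNA
#' intensity table plus a promoter beta_set and probe annotation in which
#' the planted concordant miRNAs are down-regulated >= 1.5-fold with a
#' hypermethylated promoter probe; (iii) a miRNA-to-target link table in
#' which planted triad genes (themselves up-regulated) are targeted by at
#' least two concordant miRNAs while decoy genes are targeted by exactly
#' one; and (iv) the ground-truth tables for all of it.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `expr` (list: `raw` matrix, `probe_to_gene`),
#'   `mirna` (list: `raw` matrix of mature-miRNA intensities, `alias`
#'   data.frame `mirna_symbol`/`mirna_id`), `mirna_meth` (list: `beta`
#'   beta_set over control/senescent, `probes` annotation), `targets`
#'   (data.frame `mirna_id`, `gene_id`) and `truth` (list: `genes` with
#'   `expr_class` and `triad`, `mirnas` with `concordant`).
#' @export
generate_expression_tables <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n_genes <- cfg$n_genes
  gene_id <- sprintf("NM_%06d", seq_len(n_genes))
  samples <- c("control", "senescent")

  n_up <- max(ceiling(0.2 * n_genes), cfg$n_triad + cfg$n_decoy)
  n_down <- ceiling(0.2 * n_genes)
  if (n_up + n_down > n_genes) stop("too many planted up/down genes")
  expr_class <- sample(rep(c("up", "down", "null"),
                           c(n_up, n_down, n_genes - n_up - n_down)))
  effect <- c(up = cfg$expr_effect_log2, down = -cfg$expr_effect_log2,
              null = 0)[expr_class]

  # probe layer: ~20% of genes carry two expression probes
  n_probes_per_gene <- ifelse(seq_len(n_genes) %% 5 == 0, 2L, 1L)
  probe_gene <- rep(gene_id, n_probes_per_gene)
  probe_effect <- rep(effect, n_probes_per_gene)
  n_ep <- length(probe_gene)
  probe_id <- sprintf("EXP_%05d", seq_len(n_ep))
  base <- stats::runif(n_ep, 4, 10)
  noise <- matrix(stats::rnorm(2 * n_ep, 0, cfg$expr_noise_log2), n_ep, 2)
  log2_expr <- cbind(base, base + probe_effect) + noise
  raw_expr <- 2^log2_expr
  dimnames(raw_expr) <- list(probe_id, samples)
  probe_to_gene <- data.frame(probe_id = probe_id, gene_id = probe_gene,
                              row.names = NULL)

  # miRNA layer
  n_mi <- cfg$n_mirnas
  mirna_symbol <- sprintf("MIR%d", 100 + seq_len(n_mi))
  mirna_id <- sprintf("hsa-miR-%d-5p", 100 + seq_len(n_mi))
  alias <- data.frame(mirna_symbol = mirna_symbol, mirna_id = mirna_id,
                      row.names = NULL)
  concordant <- rep(FALSE, n_mi)
  concordant[sample(n_mi, cfg$n_concordant_mirnas)] <- TRUE
  # non-concordant decoys: some hypermethylated but flat expression,
  # some down-regulated without methylation change
  other <- which(!concordant)
  meth_only <- other[seq_len(min(3, length(other)))]
  expr_only <- setdiff(other, meth_only)[seq_len(min(3, length(other) - length(meth_only)))]

  beta_control <- stats::runif(n_mi, 0.2, 0.4)
  dbeta <- numeric(n_mi)
  dbeta[concordant] <- 0.3
  dbeta[meth_only] <- 0.3
  beta_sen <- clip01(beta_control + dbeta +
                       stats::rnorm(n_mi, 0, cfg$beta_noise_sd))
  beta_control <- clip01(beta_control +
                           stats::rnorm(n_mi, 0, cfg$beta_noise_sd))
  mprobe_id <- sprintf("cgM%05d", seq_len(n_mi))
  mbeta <- cbind(control = beta_control, senescent = beta_sen)
  rownames(mbeta) <- mprobe_id
  mirna_probes <- data.frame(
    probe_id = mprobe_id,
    chrom = "chr2",
    pos = sort(sample.int(1e7, n_mi)),
    strand = "+",
    cpg_context = "Island",
    refgene_names = mirna_symbol,
    refgene_groups = "TSS200",
    row.names = NULL
  )

  mi_lfc <- numeric(n_mi)
  mi_lfc[concordant] <- -log2(2.5)
  mi_lfc[expr_only] <- -log2(2.5)
  mi_base <- stats::runif(n_mi, 4, 8)
  mi_noise <- matrix(stats::rnorm(2 * n_mi, 0, cfg$expr_noise_log2), n_mi, 2)
  raw_mirna <- 2^(cbind(mi_base, mi_base + mi_lfc) + mi_noise)
  dimnames(raw_mirna) <- list(mirna_id, samples)

  # target links: triad genes get >= 2 concordant miRNAs, decoys exactly 1
  up_genes <- gene_id[expr_class == "up"]
  triad_genes <- up_genes[seq_len(cfg$n_triad)]
  decoy_genes <- up_genes[cfg$n_triad + seq_len(cfg$n_decoy)]
  conc_ids <- mirna_id[concordant]
  links <- list()
  for (g in triad_genes) {
    supp <- sample(conc_ids, sample(2:min(3, length(conc_ids)), 1))
    links[[g]] <- data.frame(mirna_id = supp, gene_id = g)
  }
  for (g in decoy_genes) {
    supp <- c(sample(conc_ids, 1),
              sample(mirna_id[!concordant], 2))
    links[[g]] <- data.frame(mirna_id = supp, gene_id = g)
  }
  # a flat gene targeted by many concordant miRNAs fails the expression cut
  flat_gene <- gene_id[expr_class == "null"][1]
  if (!is.na(flat_gene) && length(conc_ids) >= 2) {
    links[[flat_gene]] <- data.frame(
      mirna_id = sample(conc_ids, 2), gene_id = flat_gene)
  }
  targets <- do.call(rbind, links)
  rownames(targets) <- NULL

  truth_genes <- data.frame(
    gene_id = gene_id,
    expr_class = expr_class,
    triad = gene_id %in% triad_genes,
    row.names = NULL
  )
  truth_mirnas <- data.frame(mirna_id = mirna_id, concordant = concordant,
                             row.names = NULL)
  list(
    expr = list(raw = raw_expr, probe_to_gene = probe_to_gene),
    mirna = list(raw = raw_mirna, alias = alias),
    mirna_meth = list(beta = beta_set(mbeta), probes = mirna_probes),
    targets = targets,
    truth = list(genes = truth_genes, mirnas = truth_mirnas)
  )
}

#' Write a complete simulated fixture set to disk
#'
#' Materialises the outputs of the three generators in the standard on-disk
#' formats the readers consume: simple-dialect probe annotation,
#' tab-separated beta/detection-p/intensity matrices, refGene-layout gene
#' models, FASTA genome, and tab-separated truth tables.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_fixture_set <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meth <- generate_methylation_series(cfg)
  gen <- generate_genome_with_cgis(cfg)
  expr <- generate_expression_tables(cfg)
  p <- function(f) file.path(dir, f)
  write_probe_annotation(meth$probes, p("probes.tsv"))
  write_beta_set(meth$beta, p("beta.tsv"), p("detection_p.tsv"))
  utils::write.table(meth$truth, p("truth_probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_refgene(gen$genes, p("refgene.txt"))
  Biostrings::writeXStringSet(gen$genome, p("genome.fa"))
  utils::write.table(gen$truth, p("truth_promoters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix(expr$expr$raw, p("expression_raw.tsv"))
  utils::write.table(expr$expr$probe_to_gene, p("expression_probe_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix(expr$mirna$raw, p("mirna_raw.tsv"))
  utils::write.table(expr$mirna$alias, p("mirna_alias.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_beta_set(expr$mirna_meth$beta, p("mirna_beta.tsv"),
                 p("mirna_detection_p.tsv"))
  write_probe_annotation(expr$mirna_meth$probes, p("mirna_probes.tsv"))
  utils::write.table(expr$targets, p("mirna_targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(expr$truth$genes, p("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(expr$truth$mirnas, p("truth_mirnas.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list.files(dir, full.names = TRUE))
}
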