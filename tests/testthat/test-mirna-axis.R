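mirna_annotation <- function(names, groups) {
  data.frame(probe_id = sprintf("cg%03d", seq_along(names)), chrom = "chr1",
             pos = seq_along(names) * 100L, strand = "+",
             cpg_context = "Island", refgene_names = names,
             refgene_groups = groups)
}

test_that("miRNA probe selection is word-boundary aware and feature-restricted", {
  ann <- mirna_annotation(
    names = c("MIR7-1", "MIRROR1", "MIRLET7A", "TP53;MIR505", "MIR17"),
    groups = c("TSS200", "TSS200", "TSS1500", "Body;TSS200", "Body"))
  sel <- select_mirna_probes(ann)
  expect_setequal(sel$mirna_symbol, c("MIR7-1", "MIRLET7A", "MIR505"))
  # MIRROR1 must never match; MIR17 has only a Body annotation
  expect_false("MIRROR1" %in% sel$mirna_symbol)
  expect_false("MIR17" %in% sel$mirna_symbol)
  sel_any <- select_mirna_probes(ann, features = NULL)
  expect_true("MIR17" %in% sel_any$mirna_symbol)

  # planted count on a larger fixture
  n <- 60
  names <- c(sprintf("MIR%d", 100 + 1:20), sprintf("GENE%d", 1:(n - 20)))
  ann <- mirna_annotation(names, rep("TSS200", n))
  expect_equal(nrow(select_mirna_probes(ann)), 20)
})

test_that("miRNA normalization zeroes the 90th percentile and is shift-invariant", {
  allsame <- matrix(16, 5, 1, dimnames = list(1:5, "s"))
  expect_equal(unname(normalize_mirna(allsame)[, 1]), rep(0, 5))

  set.seed(15)
  raw <- matrix(2^runif(200, 1, 10), 100, 2,
                dimnames = list(sprintf("m%03d", 1:100), c("a", "b")))
  out <- normalize_mirna(raw)
  p90 <- apply(out, 2, quantile, probs = 0.9, names = FALSE)
  expect_equal(unname(p90), c(0, 0))
  # brute-force percentile-subtract oracle
  expect_equal(out[, "a"],
               log2(raw[, "a"]) - quantile(log2(raw[, "a"]), 0.9, names = FALSE))
  # doubling every intensity in a sample changes nothing
  raw2 <- raw
  raw2[, "b"] <- raw2[, "b"] * 2
  expect_equal(normalize_mirna(raw2), out)
  expect_error(normalize_mirna(raw - 2^10), "positive")
})

test_that("concordance combines promoter methylation with expression change", {
  ann <- mirna_annotation(c("MIR1", "MIR2", "MIR3", "MIR4"),
                          rep("TSS200", 4))
  mp <- select_mirna_probes(ann)
  meth <- data.frame(probe_id = ann$probe_id,
                     delta_beta = c(0.25, 0.25, -0.3, 0.25),
                     call = factor(c("hyper", "hyper", "hypo", "hyper"),
                                   levels = c("hyper", "hypo", "none")))
  fc <- data.frame(mirna_id = c("hsa-miR-1", "hsa-miR-2", "hsa-miR-3"),
                   fc = c(0.5, 0.9, 1.8))
  alias <- data.frame(mirna_symbol = c("MIR1", "MIR2", "MIR3", "MIR4"),
                      mirna_id = c("hsa-miR-1", "hsa-miR-2", "hsa-miR-3",
                                   "hsa-miR-4"))
  cc <- call_concordance(mp, meth, fc, alias = alias)
  expect_equal(as.character(cc$concordance[cc$mirna_id == "hsa-miR-1"]),
               "hyper_down")
  # |fc| below the 1.5 cutoff: no concordance despite hypermethylation
  expect_equal(as.character(cc$concordance[cc$mirna_id == "hsa-miR-2"]),
               "none")
  # hypomethylated and up-regulated: the mirror direction is supported
  expect_equal(as.character(cc$concordance[cc$mirna_id == "hsa-miR-3"]),
               "hypo_up")
  # methylation but no expression measurement: unevaluable
  row4 <- cc[cc$mirna_id == "hsa-miR-4", ]
  expect_false(row4$evaluable)
  expect_true(is.na(row4$concordance))
})

test_that("triad filter enforces miRNA support and opposite gene regulation", {
  conc <- data.frame(
    mirna_id = c("miR-a", "miR-b", "miR-c"),
    n_probes = 1L, max_delta_beta = 0.3, min_delta_beta = 0.3,
    fc = 0.5, evaluable = TRUE,
    concordance = factor(c("hyper_down", "hyper_down", "none"),
                         levels = c("hyper_down", "hypo_up", "none")))
  gene_fc <- data.frame(gene_id = c("IL6ST", "ONE", "WEAK"),
                        fc = c(2.2, 2.2, 1.2))
  targets <- data.frame(
    mirna_id = c("miR-a", "miR-b", "miR-a", "miR-c", "miR-a", "miR-b"),
    gene_id = c("IL6ST", "IL6ST", "ONE", "ONE", "WEAK", "WEAK"))
  tri <- triad_filter(conc, targets, gene_fc)
  expect_equal(tri$gene_id, "IL6ST")      # two concordant miRNAs, fc 2.2
  expect_equal(tri$mirnas, "miR-a,miR-b")
  # ONE: only one *concordant* supporter; WEAK: fc below the 2-fold cut

  # removing a concordant miRNA can only shrink the result set
  conc_less <- conc[conc$mirna_id != "miR-b", ]
  tri_less <- triad_filter(conc_less, targets, gene_fc)
  expect_true(all(tri_less$gene_id %in% tri$gene_id))
  expect_equal(nrow(tri_less), 0)
})

test_that("the planted triad set is recovered exactly from the generator", {
  cfg <- sim_config(seed = 16)
  ex <- generate_expression_tables(cfg)
  gm <- aggregate_probes_to_genes(normalize_expression(ex$expr$raw),
                                  ex$expr$probe_to_gene)
  gene_fc <- call_fold_changes(gm, "senescent", "control")
  mfc <- call_fold_changes(normalize_mirna(ex$mirna$raw),
                           "senescent", "control", up_fc = 1.5)
  names(mfc)[names(mfc) == "gene_id"] <- "mirna_id"
  meth <- call_differential(ex$mirna_meth$beta, "senescent", "control")
  mp <- select_mirna_probes(ex$mirna_meth$probes)
  cc <- call_concordance(mp, meth, mfc, alias = ex$mirna$alias)
  expect_setequal(cc$mirna_id[which(cc$concordance == "hyper_down")],
                  ex$truth$mirnas$mirna_id[ex$truth$mirnas$concordant])
  tri <- triad_filter(cc, ex$targets, gene_fc)
  expect_setequal(tri$gene_id,
                  ex$truth$genes$gene_id[ex$truth$genes$triad])
  # supporting miRNAs are a subset of the concordant set
  supp <- unlist(strsplit(tri$mirnas, ","))
  expect_true(all(supp %in% cc$mirna_id[which(cc$concordance != "none")]))
})
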