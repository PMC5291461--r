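simple_probes <- function(pos, chrom = "chr1") {
  data.frame(probe_id = sprintf("cg%03d", seq_along(pos)), chrom = chrom,
             pos = pos, strand = "+", cpg_context = "Island",
             refgene_names = "", refgene_groups = "")
}

simple_genes <- function(tss, ids = sprintf("NM_%03d", seq_along(tss)),
                         chrom = "chr1") {
  data.frame(gene_id = ids, symbol = ids, chrom = chrom, strand = "+",
             tx_start = tss, tx_end = tss + 10L, tss = tss, unplaced = FALSE)
}

test_that("probes map to the nearest TSS within the 8 kb window", {
  probes <- simple_probes(c(1000L, 21000L))
  genes <- simple_genes(c(5000L, 12000L))
  m <- map_probes_to_nearest_tss(probes, genes)
  expect_equal(m$gene_id[1], "NM_001")
  expect_equal(m$distance[1], 4000L)
  # nearest TSS at 9 kb: beyond the window, probe stays unmapped
  expect_true(is.na(m$gene_id[2]))
  # a TSS at exactly 8 kb is still within the (inclusive) window
  m8 <- map_probes_to_nearest_tss(simple_probes(20000L), genes)
  expect_equal(m8$distance, 8000L)
  expect_equal(m$probe_id, probes$probe_id)
})

test_that("equidistant ties break to the smallest gene id, regardless of row order", {
  probes <- simple_probes(1000L)
  genes <- simple_genes(c(900L, 1100L), ids = c("NM_ZZZ", "NM_AAA"))
  m1 <- map_probes_to_nearest_tss(probes, genes)
  m2 <- map_probes_to_nearest_tss(probes, genes[2:1, ])
  expect_equal(m1$gene_id, "NM_AAA")
  expect_identical(m1, m2)

  # two isoforms sharing a TSS: smallest accession is reported
  genes2 <- simple_genes(c(1200L, 1200L), ids = c("NM_B", "NM_A"))
  expect_equal(map_probes_to_nearest_tss(probes, genes2)$gene_id, "NM_A")
})

test_that("nearest-TSS mapping equals an all-pairs brute-force scan", {
  for (seed in 1:5) {
    set.seed(seed)
    probes <- simple_probes(sample.int(60000, 300),
                            chrom = sample(c("chr1", "chr2"), 300, TRUE))
    genes <- simple_genes(sample.int(60000, 40),
                          chrom = "chr1")
    genes2 <- simple_genes(sample.int(60000, 40),
                           ids = sprintf("NM_B%02d", 1:40), chrom = "chr2")
    genes <- rbind(genes, genes2)
    got <- map_probes_to_nearest_tss(probes, genes)
    want <- oracle_nearest_tss(probes, genes)
    expect_identical(got$gene_id, want$gene_id)
    expect_identical(got$distance, want$distance)
    # conservation: mapped + unmapped = input probes
    expect_equal(sum(!is.na(got$gene_id)) + sum(is.na(got$gene_id)),
                 nrow(probes))
    expect_true(all(got$distance <= 8000, na.rm = TRUE))
  }
})

test_that("joint calls combine delta-beta and fold-change thresholds", {
  mapped <- data.frame(probe_id = c("cg1", "cg2", "cg3", "cg4"),
                       gene_id = c("g1", "g2", "g3", "g4"),
                       tss = 0L, distance = c(100L, 200L, 300L, 400L),
                       signed_distance = 0L)
  meth <- data.frame(probe_id = mapped$probe_id,
                     delta_beta = c(0.3, 0.3, -0.25, 0.3),
                     call = factor(c("hyper", "hyper", "hypo", "hyper"),
                                   levels = c("hyper", "hypo", "none")))
  fc <- data.frame(gene_id = c("g1", "g2", "g3"), fc = c(0.4, 1.0, 2.5))
  expect_message(jc <- joint_call(mapped, meth, fc), "without expression")
  expect_equal(as.character(jc$joint_call),
               c("hyper_down", "none", "hypo_up", "none"))
  expect_false(jc$has_expression[4])
  # conservation of joint-call counts over mapped pairs with both data types
  expect_equal(sum(table(jc$joint_call)), nrow(jc))
})

test_that("planted concordant pairs are recovered exactly", {
  # probes placed 100 bp from alternating gene TSSs; plant j hyper_down pairs
  n <- 40
  genes <- simple_genes(seq(10000L, by = 20000L, length.out = n))
  probes <- simple_probes(genes$tss + 100L)
  truth_joint <- rep("none", n)
  truth_joint[seq(1, n, 4)] <- "hyper_down"
  truth_joint[seq(2, n, 4)] <- "hypo_up"
  meth <- data.frame(
    probe_id = probes$probe_id,
    delta_beta = ifelse(truth_joint == "hyper_down", 0.35,
                        ifelse(truth_joint == "hypo_up", -0.35, 0.05)),
    call = factor(ifelse(truth_joint == "hyper_down", "hyper",
                         ifelse(truth_joint == "hypo_up", "hypo", "none")),
                  levels = c("hyper", "hypo", "none")))
  fc <- data.frame(gene_id = genes$gene_id,
                   fc = ifelse(truth_joint == "hyper_down", 0.3,
                               ifelse(truth_joint == "hypo_up", 3.0, 1.0)))
  mapped <- map_probes_to_nearest_tss(probes, genes)
  jc <- joint_call(mapped, meth, fc)
  expect_equal(as.character(jc$joint_call), truth_joint)
})

test_that("distance histograms match a direct binning oracle", {
  mapped <- data.frame(probe_id = c("a", "b", "c"),
                       gene_id = c("g1", "g1", "g2"),
                       distance = c(100L, 900L, 1100L))
  cls <- data.frame(gene_id = c("g1", "g2"),
                    class = factor(c("CGI", "nonCGI")))
  dd <- distance_distribution(mapped, cls)
  expect_equal(dd$within_1kb$count[dd$within_1kb$class == "CGI"], 2)
  expect_equal(dd$within_1kb$count[dd$within_1kb$class == "nonCGI"], 0)

  # all pairs in one class leaves the other histogram empty
  cls1 <- data.frame(gene_id = c("g1", "g2"), class = factor(c("CGI", "CGI")))
  dd1 <- distance_distribution(mapped, cls1)
  expect_true(all(dd1$histogram$count[dd1$histogram$class == "nonCGI"] == 0))

  for (seed in 1:5) {
    set.seed(seed)
    n <- 500
    mapped <- data.frame(probe_id = sprintf("p%03d", 1:n),
                         gene_id = sample(c("g1", "g2"), n, TRUE),
                         distance = sample(0:8000, n, TRUE))
    dd <- distance_distribution(mapped, cls)
    breaks <- seq(0, 8000, 250)
    o <- oracle_distance_histogram(
      mapped$distance,
      ifelse(mapped$gene_id == "g1", "CGI", "nonCGI"), breaks)
    h <- dd$histogram
    expect_equal(h$count[h$class == "CGI"], o$CGI)
    expect_equal(h$count[h$class == "nonCGI"], o$nonCGI)
    expect_equal(sum(h$count), n)
  }
})

test_that("functional-group ratios cross-tabulate with an 'others' fallback", {
  map <- data.frame(gene_id = sprintf("g%02d", 1:10),
                    group = "immune response")
  sets <- list(TSS200_hypo = sprintf("g%02d", 1:10),
               Body_hyper = c("g01", "unknown_gene"),
               empty = character(0))
  r <- functional_group_ratios(sets, map)
  cell <- r[r$set == "TSS200_hypo" & r$group == "immune response", ]
  expect_equal(cell$fraction, 1.0)
  expect_equal(r$count[r$set == "Body_hyper" & r$group == "others"], 1)
  expect_true(all(is.na(r$fraction[r$set == "empty"])))

  set.seed(14)
  genes <- sprintf("g%03d", 1:100)
  map <- data.frame(gene_id = genes,
                    group = sample(FUNCTIONAL_GROUPS[-8], 100, TRUE))
  sets <- list(s1 = sample(genes, 40), s2 = sample(genes, 25))
  r <- functional_group_ratios(sets, map)
  for (nm in names(sets)) {
    for (gp in setdiff(FUNCTIONAL_GROUPS, "others")) {
      want <- sum(map$group[map$gene_id %in% sets[[nm]]] == gp)
      expect_equal(r$count[r$set == nm & r$group == gp], want)
    }
    expect_equal(sum(r$count[r$set == nm]), length(sets[[nm]]))
  }
})
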