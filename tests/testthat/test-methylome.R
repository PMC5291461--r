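test_that("beta values follow the offset intensity formula", {
  expect_equal(beta_from_intensities(400, 500), 0.4)
  expect_equal(beta_from_intensities(0, 1234), 0)
  expect_equal(beta_from_intensities(900, 0), 0.9)
  # the offset keeps beta strictly below 1 even at u = 0
  expect_true(all(beta_from_intensities(10^(0:6), 0) < 1))
  expect_error(beta_from_intensities(-1, 5), "non-negative")
})

test_that("probe filtering removes p > 0.05 strictly and blank betas", {
  beta <- matrix(0.5, 4, 2)
  detp <- matrix(0.01, 4, 2)
  detp[1, 2] <- 0.06     # fails: above threshold
  detp[2, 1] <- 0.05     # retained: boundary is inclusive
  beta[3, 1] <- NA       # fails: blank beta
  bs <- make_beta_set(beta, detp)
  out <- filter_probes(bs)
  expect_equal(rownames(out$beta), c("cg002", "cg004"))
  expect_equal(attr(out, "n_removed"), 2L)

  # restricting the analysis set can rescue a probe failing elsewhere
  out2 <- filter_probes(bs, samples = "s1")
  expect_true("cg001" %in% rownames(out2$beta))
})

test_that("planted detection failures are exactly the removed probes", {
  cfg <- sim_config(n_probes = 500, frac_detection_fail = 0.04, seed = 5)
  meth <- generate_methylation_series(cfg)
  out <- filter_probes(meth$beta)
  k <- sum(meth$truth$detection_fail)
  expect_equal(nrow(out$beta), cfg$n_probes - k)
  expect_setequal(setdiff(meth$truth$probe_id, rownames(out$beta)),
                  meth$truth$probe_id[meth$truth$detection_fail])
})

test_that("differential calls use inclusive +-0.2 delta-beta thresholds", {
  beta <- cbind(ctrl = c(0.5, 0.5, 0.5, 0.5, 0.9),
                sen = c(0.8, 0.7, 0.31, 0.3, 0.6))
  rownames(beta) <- sprintf("cg%d", 1:5)
  calls <- call_differential(beta, "sen", "ctrl")
  expect_equal(as.character(calls$call),
               c("hyper", "hyper", "none", "hypo", "hypo"))
  expect_equal(calls$delta_beta, c(0.3, 0.2, -0.19, -0.2, -0.3))
})

test_that("swapping test and control negates delta-beta and swaps calls", {
  set.seed(6)
  beta <- matrix(runif(400), 200, 2, dimnames = list(sprintf("cg%03d", 1:200),
                                                     c("a", "b")))
  fwd <- call_differential(beta, "b", "a")
  rev <- call_differential(beta, "a", "b")
  expect_equal(rev$delta_beta, -fwd$delta_beta)
  expect_equal(sum(fwd$call == "hyper"), sum(rev$call == "hypo"))
  expect_equal(sum(fwd$call == "hypo"), sum(rev$call == "hyper"))
  # conservation: every filtered probe is called exactly once
  expect_equal(sum(table(fwd$call)), nrow(beta))
})

test_that("sequential change requires monotone beta across passages", {
  beta <- rbind(mono = c(0.2, 0.3, 0.5, 0.6),
                dip = c(0.2, 0.5, 0.4, 0.6),
                down = c(0.8, 0.6, 0.5, 0.4),
                flat = c(0.5, 0.5, 0.5, 0.5))
  colnames(beta) <- paste0("P", 1:4)
  calls <- call_differential(beta, "P4", "P1")
  out <- classify_sequential(beta, colnames(beta), calls)
  expect_true(out$sequential[out$probe_id == "mono"])
  expect_false(out$sequential[out$probe_id == "dip"])
  expect_true(out$sequential[out$probe_id == "down"])
  expect_true(is.na(out$sequential[out$probe_id == "flat"]))

  # the dip is forgiven with a tolerance at least as large as its depth
  out_eps <- classify_sequential(beta, colnames(beta), calls, epsilon = 0.1)
  expect_true(out_eps$sequential[out_eps$probe_id == "dip"])
  expect_error(classify_sequential(beta, c("P1", "P9", "P4"), calls),
               "not present")
})

test_that("sequential flags equal a pairwise-comparison oracle", {
  set.seed(7)
  k <- 4
  beta <- matrix(runif(150 * k), 150, k,
                 dimnames = list(sprintf("cg%03d", 1:150), paste0("P", 1:k)))
  calls <- call_differential(beta, "P4", "P1", delta_beta = 0.1)
  out <- classify_sequential(beta, colnames(beta), calls)
  for (i in seq_len(nrow(out))) {
    b <- beta[out$probe_id[i], ]
    expected <- switch(as.character(out$call[i]),
      hyper = all(b[-1] >= b[-k]),
      hypo = all(b[-1] <= b[-k]),
      NA)
    expect_identical(out$sequential[i], expected)
  }
})

test_that("subcategory summaries match direct tallies and conserve totals", {
  probes <- data.frame(
    probe_id = sprintf("cg%02d", 1:10),
    chrom = "chr1", pos = 1:10, strand = "+",
    cpg_context = "Island",
    refgene_names = "", refgene_groups = ""
  )
  calls <- data.frame(
    probe_id = probes$probe_id,
    delta_beta = c(rep(0.3, 4), -0.3, rep(0, 5)),
    call = factor(c(rep("hyper", 4), "hypo", rep("none", 5)),
                  levels = c("hyper", "hypo", "none"))
  )
  sm <- summarize_subcategories(calls, probes)
  isl <- sm$cpg_context[sm$cpg_context$subcategory == "Island", ]
  expect_equal(isl$hyper_rate, 0.4)
  expect_equal(isl$hypo_rate, 0.1)
  expect_equal(isl$rate_ratio, 4)
  expect_equal(sm$gene_feature$total[sm$gene_feature$subcategory == "Intergenic"], 10)

  # no calls anywhere -> every ratio missing
  calls$call[] <- "none"
  sm0 <- summarize_subcategories(calls, probes)
  expect_true(all(is.na(sm0$cpg_context$rate_ratio)))

  cfg <- sim_config(n_probes = 400, seed = 8)
  meth <- generate_methylation_series(cfg)
  calls <- call_differential(meth$beta, "PDL85", "PDL36")
  sm <- summarize_subcategories(calls, meth$probes)
  # context axis partitions the analysed probes
  expect_equal(sum(sm$cpg_context$total), nrow(calls))
  ctx <- meth$probes$cpg_context[match(calls$probe_id, meth$probes$probe_id)]
  for (lv in sm$cpg_context$subcategory) {
    o <- oracle_subcategory_counts(calls$call, ctx, lv)
    row <- sm$cpg_context[sm$cpg_context$subcategory == lv, ]
    expect_equal(unname(unlist(row[c("total", "n_hyper", "n_hypo")])),
                 unname(o))
  }
  # gene-feature axis multi-counts multi-annotated probes
  feat <- probe_gene_features(meth$probes)
  expect_equal(sum(sm$gene_feature$total), nrow(feat))
})

test_that("scatter r-squared equals the textbook correlation formula", {
  set.seed(9)
  a <- runif(100)
  expect_equal(beta_scatter_stats(a, a)$r_squared, 1)
  expect_equal(beta_scatter_stats(a, 1 - a)$r_squared, 1)
  b <- a + rnorm(100, 0, 0.2)
  b <- pmin(pmax(b, 0), 1)
  got <- beta_scatter_stats(a, b)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r_squared, (num / den)^2)
  expect_equal(got$n_pairs, 100L)
  expect_error(beta_scatter_stats(a, rep(0.5, 100)), "constant")
})
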