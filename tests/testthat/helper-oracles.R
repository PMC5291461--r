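# Brute-force oracles, deliberately independent of the package internals:
# plain loops and direct formula evaluation on small inputs.

oracle_nearest_tss <- function(probes, genes, window = 8000) {
  res <- data.frame(probe_id = probes$probe_id, gene_id = NA_character_,
                    distance = NA_integer_)
  for (i in seq_len(nrow(probes))) {
    g <- genes[genes$chrom == probes$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    d <- abs(probes$pos[i] - g$tss)
    dmin <- min(d)
    if (dmin > window) next
    cand <- g$gene_id[d == dmin]
    res$gene_id[i] <- sort(cand)[1]
    res$distance[i] <- dmin
  }
  res
}

oracle_venn <- function(sets) {
  ids <- unique(unlist(sets))
  counts <- integer(7)
  nm <- names(sets)
  labels <- character(7)
  j <- 0
  for (a in c(TRUE, FALSE)) for (b in c(TRUE, FALSE)) for (cc in c(TRUE, FALSE)) {
    if (!a && !b && !cc) next
    j <- j + 1
    labels[j] <- paste(nm[c(a, b, cc)], collapse = "&")
    n <- 0
    for (id in ids) {
      if ((id %in% sets[[1]]) == a && (id %in% sets[[2]]) == b &&
          (id %in% sets[[3]]) == cc) {
        n <- n + 1
      }
    }
    counts[j] <- n
  }
  stats::setNames(counts, labels)
}

oracle_uncentered_distance <- function(mat) {
  n <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    x <- mat[, i]; y <- mat[, j]
    d[i, j] <- 1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  }
  d
}

oracle_subcategory_counts <- function(calls, groups, level) {
  idx <- groups == level
  c(total = sum(idx),
    n_hyper = sum(idx & calls == "hyper"),
    n_hypo = sum(idx & calls == "hypo"))
}

oracle_distance_histogram <- function(distance, class, breaks) {
  out <- list()
  for (cl in c("CGI", "nonCGI")) {
    counts <- integer(length(breaks) - 1)
    for (b in seq_len(length(breaks) - 1)) {
      lo <- breaks[b]; hi <- breaks[b + 1]
      last <- b == length(breaks) - 1
      for (i in seq_along(distance)) {
        if (class[i] != cl) next
        x <- distance[i]
        if (x >= lo && (x < hi || (last && x == hi))) counts[b] <- counts[b] + 1
      }
    }
    out[[cl]] <- counts
  }
  out
}

# direct Gardiner-Garden computation by character counting
oracle_cpg_stats <- function(seq) {
  s <- toupper(seq)
  chars <- strsplit(s, "")[[1]]
  n_c <- sum(chars == "C"); n_g <- sum(chars == "G")
  n_n <- sum(chars == "N")
  L <- length(chars) - n_n
  n_cg <- 0
  for (i in seq_len(length(chars) - 1)) {
    if (chars[i] == "C" && chars[i + 1] == "G") n_cg <- n_cg + 1
  }
  list(gc = (n_c + n_g) / L,
       oe = if (n_c > 0 && n_g > 0) n_cg * L / (n_c * n_g) else 0)
}

# small beta_set builder for unit tests
make_beta_set <- function(beta, detp = NULL, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- sprintf("cg%03d", seq_len(nrow(beta)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(beta)))
  dimnames(beta) <- list(probes, samples)
  if (!is.null(detp)) dimnames(detp) <- dimnames(beta)
  beta_set(beta, detp)
}
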