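#' Beta-value matrix with detection p-values
#'
#' Container for BeadChip-style methylation data: a probes x samples matrix
#' of beta values (methylation fraction estimates in `[0, 1]`, `NA` for blank
#' entries) paired with a matrix of per-entry detection p-values of identical
#' dimensions and dimnames.
#'
#' @param beta Numeric matrix of beta values with probe rownames and sample
#'   colnames. Non-missing entries must lie in `[0, 1]`.
#' @param detection_p Numeric matrix of detection p-values, same dimensions
#'   and dimnames as `beta`. If `NULL`, all entries are set to 0 (every probe
#'   detected).
#' @return An object of class `beta_set`: a list with elements `beta` and
#'   `detection_p`.
#' @examples
#' b <- matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' bs <- beta_set(b)
#' dim(bs)
#' @export
beta_set <- function(beta, detection_p = NULL) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("'beta' must have probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(beta))) {
    stop("duplicate probe ids in 'beta'")
  }
  bad <- beta[!is.na(beta)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 1)) {
    stop("beta values must lie in [0, 1]")
  }
  if (is.null(detection_p)) {
    detection_p <- beta
    detection_p[] <- 0
  }
  detection_p <- as.matrix(detection_p)
  if (!identical(dim(beta), dim(detection_p))) {
    stop("'beta' and 'detection_p' must have identical dimensions")
  }
  if (!identical(dimnames(beta), dimnames(detection_p))) {
    stop("'beta' and 'detection_p' must have identical dimnames")
  }
  p <- detection_p[!is.na(detection_p)]
  if (length(p) && (min(p) < 0 || max(p) > 1)) {
    stop("detection p-values must lie in [0, 1]")
  }
  structure(list(beta = beta, detection_p = detection_p), class = "beta_set")
}

#' @export
dim.beta_set <- function(x) dim(x$beta)

#' @export
dimnames.beta_set <- function(x) dimnames(x$beta)

#' @export
print.beta_set <- function(x, ...) {
  cat(sprintf("<beta_set> %d probes x %d samples\n", nrow(x$beta), ncol(x$beta)))
  cat("samples:", paste(colnames(x$beta), collapse = ", "), "\n")
  n_na <- sum(is.na(x$beta))
  if (n_na > 0) cat(sprintf("missing beta entries: %d\n", n_na))
  invisible(x)
}

#' Subset a beta_set by probes and/or samples
#'
#' @param x A [beta_set()].
#' @param i Probe index (row) selector.
#' @param j Sample (column) selector.
#' @param ... Ignored.
#' @return A `beta_set` restricted to the selected probes and samples.
#' @export
`[.beta_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$beta))
  if (missing(j)) j <- seq_len(ncol(x$beta))
  beta_set(x$beta[i, j, drop = FALSE], x$detection_p[i, j, drop = FALSE])
}

# Accept either a beta_set or a bare beta matrix in analysis functions.
as_beta_matrix <- function(x) {
  if (inherits(x, "beta_set")) return(x$beta)
  if (is.matrix(x)) return(x)
  stop("expected a beta_set or a numeric matrix")
}
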