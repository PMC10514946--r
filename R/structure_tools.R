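#' Principal component analysis of a genotype matrix
#'
#' Missing dosages are imputed with the site mean, sites are centred, and the
#' sample configuration is decomposed by singular value decomposition (the
#' eigendecomposition of the sample covariance). With
#' `scaling = "patterson"` each site is additionally divided by its binomial
#' standard deviation `sqrt(p * (1 - p))`, `p` being half the mean dosage, the
#' normalisation customary for SNP PCA; sites fixed after imputation are
#' dropped under that scaling. The variance fraction of an axis is its
#' eigenvalue over the trace, in percent, summing to 100 over all non-zero
#' axes.
#'
#' @param g A [geno()] object.
#' @param scaling `"center"` (default) or `"patterson"`.
#' @param max_axes Number of axes to return coordinates for (default 10).
#' @return An object of class `divscan_pca`: list with `scores` (tibble
#'   `sample`, `PC1`, ...), `var_fraction` (percent per axis, all axes),
#'   `sdev`, and `scaling`.
#' @export
geno_pca <- function(g, scaling = c("center", "patterson"), max_axes = 10) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(g, "geno"))
  if (n_samples(g) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  x <- t(g$dosage)            # samples x sites
  mu <- colMeans(x, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mu[j]
  }
  keep <- matrixStats_colVars(x) > 0
  if (!any(keep)) stop("all sites monomorphic; PCA undefined", call. = FALSE)
  x <- x[, keep, drop = FALSE]
  mu <- mu[keep]
  x <- sweep(x, 2, mu)
  if (scaling == "patterson") {
    p <- mu / 2
    sdv <- sqrt(p * (1 - p))
    ok <- sdv > 0
    x <- sweep(x[, ok, drop = FALSE], 2, sdv[ok], "/")
  }
  sv <- svd(x)
  ev <- sv$d^2 / (nrow(x) - 1)
  nz <- ev > max(ev) * 1e-12
  vf <- 100 * ev / sum(ev[nz])
  vf[!nz] <- 0
  m <- min(max_axes, sum(nz))
  scores <- sv$u[, seq_len(m), drop = FALSE] %*% diag(sv$d[seq_len(m)], m, m)
  # deterministic axis orientation: largest-|score| sample loads positive
  for (k in seq_len(m)) {
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) scores[, k] <- -scores[, k]
  }
  colnames(scores) <- paste0("PC", seq_len(m))
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample = g$samples),
                              tibble::as_tibble(scores)),
    var_fraction = vf,
    sdev = sqrt(ev),
    scaling = scaling
  ), class = "divscan_pca")
}

# column variances without matrixStats; keeps the PCA dependency-free
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  colSums(sweep(x, 2, mu)^2) / (n - 1)
}

#' @export
print.divscan_pca <- function(x, ...) {
  m <- min(3, length(x$var_fraction))
  cat(sprintf("<divscan_pca> %d samples; first axes explain %s%%\n",
              nrow(x$scores),
              paste(sprintf("%.1f", x$var_fraction[seq_len(m)]), collapse = " / ")))
  invisible(x)
}

#' @rdname geno_pca
#' @param x A `divscan_pca` object.
#' @param ... Ignored.
#' @export
tidy.divscan_pca <- function(x, ...) x$scores

#' @rdname geno_pca
#' @export
glance.divscan_pca <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$var_fraction),
                 var_fraction = x$var_fraction)
}

#' Evanno delta-K from replicated clustering log-likelihoods
#'
#' Given log-likelihoods `L(K)` from repeated runs at successive `K`,
#' `delta_K(K)` is the mean over replicate runs of the absolute second
#' difference `|L(K+1) - 2 L(K) + L(K-1)|`, divided by the standard deviation
#' (sample, n-1) of `L(K)` across replicates. Second differences are formed
#' within each replicate, so the table must contain the same replicate ids at
#' every K. Endpoints are undefined; a K with zero replicate SD gets
#' `delta_k = NA` and `sd_zero = TRUE` rather than an error.
#'
#' @param table Tibble with columns `K`, `replicate`, `loglik`.
#' @return A tibble with one row per K: `K`, `n_replicates`, `mean_loglik`,
#'   `sd_loglik`, `delta_k`, `sd_zero`.
#' @export
#' @examples
#' tab <- tidyr::expand_grid(K = 1:5, replicate = 1:3)
#' tab$loglik <- -1000 - 50 * abs(tab$K - 2) + 0.1 * tab$replicate
#' evanno_delta_k(tab)
evanno_delta_k <- function(table) {
  stopifnot(all(c("K", "replicate", "loglik") %in% names(table)))
  ks <- sort(unique(table$K))
  if (length(ks) < 3) stop("delta-K needs at least 3 successive K values", call. = FALSE)
  if (!all(diff(ks) == 1)) stop("K values must be contiguous", call. = FALSE)
  wide <- tidyr::pivot_wider(table[c("K", "replicate", "loglik")],
                             names_from = "K", values_from = "loglik")
  wide <- wide[order(wide$replicate), ]
  L <- as.matrix(wide[, as.character(ks)])
  if (anyNA(L)) stop("every replicate needs a loglik at every K", call. = FALSE)
  if (nrow(L) < 2) stop("delta-K needs >= 2 replicates per K", call. = FALSE)
  sdv <- apply(L, 2, stats::sd)
  dk <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1, length(ks))]) {
    second <- abs(L[, i + 1] - 2 * L[, i] + L[, i - 1])
    dk[i] <- if (sdv[i] > 0) mean(second) / sdv[i] else NA_real_
  }
  tibble::tibble(K = ks,
                 n_replicates = nrow(L),
                 mean_loglik = colMeans(L),
                 sd_loglik = sdv,
                 delta_k = dk,
                 sd_zero = sdv == 0)
}

#' Parse clustering log-likelihoods from program output or TSV
#'
#' Accepts either a TSV with columns `K`, `replicate`, `loglik`, or a set of
#' STRUCTURE-style result files from which the
#' `Estimated Ln Prob of Data` line is extracted (K and replicate are then
#' taken from the arguments, recycled along `paths`).
#'
#' @param paths File path(s).
#' @param K,replicate Integer vectors aligned with `paths` for raw result
#'   files; ignored for TSV input.
#' @return A tibble with columns `K`, `replicate`, `loglik`.
#' @export
read_structure_loglik <- function(paths, K = NULL, replicate = NULL) {
  if (length(paths) == 1 && is.null(K)) {
    tab <- readr::read_tsv(paths, col_types = readr::cols(), progress = FALSE)
    names(tab) <- tolower(names(tab))
    stopifnot(all(c("k", "replicate", "loglik") %in% names(tab)))
    return(tibble::tibble(K = as.integer(tab$k),
                          replicate = as.integer(tab$replicate),
                          loglik = as.numeric(tab$loglik)))
  }
  stopifnot(!is.null(K), !is.null(replicate))
  ll <- vapply(paths, function(p) {
    ln <- grep("Estimated Ln Prob of Data", readLines(p), value = TRUE)
    if (!length(ln)) stop("no 'Estimated Ln Prob of Data' line in ", p,
                          call. = FALSE)
    as.numeric(sub(".*=\\s*", "", ln[1]))
  }, numeric(1))
  tibble::tibble(K = as.integer(K), replicate = as.integer(replicate),
                 loglik = unname(ll))
}

#' Membership-threshold assignment summary
#'
#' A sample is assigned to a cluster when its maximum membership coefficient
#' strictly exceeds `threshold`; the summary reports how many samples are
#' assigned, the percentage (2 decimals), and per-cluster counts.
#'
#' @param membership Numeric matrix or data frame, samples by clusters; rows
#'   must sum to 1 within `1e-6`.
#' @param threshold Membership threshold (default 0.85, strict `>`).
#' @return A list of class `divscan_assignment`: `n_samples`, `n_assigned`,
#'   `percent_assigned`, and `per_cluster` (tibble `cluster`, `n_assigned`).
#' @export
#' @examples
#' m <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.05, 0.95))
#' assignment_summary(m)
assignment_summary <- function(membership, threshold = 0.85) {
  m <- as.matrix(membership)
  if (!is.numeric(m)) stop("membership must be numeric", call. = FALSE)
  if (any(m < -1e-9 | m > 1 + 1e-9)) {
    stop("membership coefficients must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(m) - 1) > 1e-6)) {
    stop("membership rows must sum to 1", call. = FALSE)
  }
  best <- max.col(m, ties.method = "first")
  assigned <- m[cbind(seq_len(nrow(m)), best)] > threshold
  per <- tibble::tibble(
    cluster = seq_len(ncol(m)),
    n_assigned = vapply(seq_len(ncol(m)),
                        function(k) sum(assigned & best == k), integer(1)))
  structure(list(
    n_samples = nrow(m),
    n_assigned = sum(assigned),
    percent_assigned = round(100 * sum(assigned) / nrow(m), 2),
    per_cluster = per
  ), class = "divscan_assignment")
}

#' @export
print.divscan_assignment <- function(x, ...) {
  cat(sprintf("<divscan_assignment> %d / %d samples assigned (%.2f%%)\n",
              x$n_assigned, x$n_samples, x$percent_assigned))
  invisible(x)
}

#' Read a membership matrix from TSV
#'
#' First column sample id, remaining columns cluster memberships.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with sample rownames.
#' @export
read_membership <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}
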