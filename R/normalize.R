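# Shared abundance helpers. All pooled abundances in the package go through
# .pooledAveLogCPM so that bin-pair filters and the background ligation
# estimate are on one scale.

.effectiveLib <- function(lib.size, norm.factors = NULL) {
    if (is.null(norm.factors)) norm.factors <- rep(1, length(lib.size))
    lib.size * norm.factors
}

# log2 CPM of a pooled count (summed over samples) against the pooled library.
.pooledAveLogCPM <- function(pooled, total_lib, prior = 0.5) {
    log2((pooled + prior) / (total_lib + 1) * 1e6)
}

#' CPM matrix
#'
#' Counts per million against effective library sizes (`lib.size *
#' norm.factors`), without log transformation.
#'
#' @param counts Feature x sample matrix.
#' @param lib.size Per-sample library sizes (default column sums).
#' @param norm.factors Optional multiplicative normalization factors.
#' @return Matrix of CPM values.
#' @export
cpmMatrix <- function(counts, lib.size = colSums(counts), norm.factors = NULL) {
    eff <- .effectiveLib(lib.size, norm.factors)
    sweep(counts, 2L, eff / 1e6, "/")
}

#' Average log2-CPM per feature
#'
#' Pooled-count abundance: log2 CPM of the feature's total count over all
#' samples against the summed effective library size, with a small prior.
#' This is the abundance measure used by the dispersion trend, the bin-pair
#' filters and the background-ligation comparison.
#'
#' @inheritParams cpmMatrix
#' @param prior Prior count added to the pooled count.
#' @return Numeric vector, one value per feature.
#' @export
aveLogCPM <- function(counts, lib.size = colSums(counts), norm.factors = NULL,
                      prior = 0.5) {
    eff <- .effectiveLib(lib.size, norm.factors)
    .pooledAveLogCPM(rowSums(counts), sum(eff), prior = prior)
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample scaling factors that multiply the library sizes, by
#' the classic TMM recipe: choose the reference sample whose upper-quartile
#' CPM is closest to the mean upper quartile; for every other sample compute
#' feature-wise M (log2 ratio vs reference, both CPM-scaled) and A (average
#' log2 abundance) over features with positive counts in both; doubly trim
#' (30% of M, 5% of A by default); combine the retained M values by a
#' precision-weighted mean (delta-method weights); finally rescale so the
#' factors have geometric mean 1.
#'
#' @inheritParams cpmMatrix
#' @param ref Optional reference sample (column index); chosen automatically
#'   when `NULL`.
#' @param trimM,trimA Two-sided trim fractions for M and A values.
#' @return Numeric vector of factors, one per sample, geometric mean 1.
#' @export
tmmFactors <- function(counts, lib.size = colSums(counts), ref = NULL,
                       trimM = 0.3, trimA = 0.05) {
    counts <- as.matrix(counts)
    if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
    if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
    if (is.null(ref)) {
        uq <- apply(counts, 2L, function(y) quantile(y, 0.75)) / lib.size
        ref <- which.min(abs(uq - mean(uq)))
    }
    yr <- counts[, ref]
    lr <- lib.size[ref]
    f <- vapply(seq_len(ncol(counts)), function(s) {
        if (s == ref) return(1)
        y <- counts[, s]
        l <- lib.size[s]
        ok <- y > 0 & yr > 0
        if (!any(ok)) return(1)
        y <- y[ok]; yo <- yr[ok]
        M <- log2((y / l) / (yo / lr))
        A <- 0.5 * log2((y / l) * (yo / lr))
        # delta-method variance of M
        v <- (l - y) / (l * y) + (lr - yo) / (lr * yo)
        n <- length(M)
        loM <- floor(n * trimM) + 1L; hiM <- n + 1L - loM
        loA <- floor(n * trimA) + 1L; hiA <- n + 1L - loA
        rM <- rank(M, ties.method = "first")
        rA <- rank(A, ties.method = "first")
        keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
        if (!any(keep)) return(1)
        2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
    }, numeric(1))
    f / exp(mean(log(f)))
}

#' Filter features on CPM
#'
#' A feature is retained iff its CPM is strictly greater than `threshold` in
#' at least `min_samples` samples. CPM uses the effective library size
#' (`lib.size * norm.factors`) unless `fixed_lib` supplies externally fixed
#' library sizes (e.g. total genome-aligned reads, the eRNA convention).
#'
#' @inheritParams cpmMatrix
#' @param threshold CPM cut-off (strict).
#' @param min_samples Minimum number of samples exceeding the cut-off.
#' @param fixed_lib Optional fixed per-sample library sizes overriding
#'   `lib.size`/`norm.factors`.
#' @return Logical vector, `TRUE` for retained features.
#' @export
cpmFilter <- function(counts, threshold, min_samples,
                      lib.size = colSums(counts), norm.factors = NULL,
                      fixed_lib = NULL) {
    eff <- if (is.null(fixed_lib)) .effectiveLib(lib.size, norm.factors)
           else fixed_lib
    if (any(eff <= 0)) stop("library sizes must be > 0")
    cpm <- sweep(as.matrix(counts), 2L, eff / 1e6, "/")
    rowSums(cpm > threshold) >= min_samples
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment; output order matches input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (FDR) in input order.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1)) {
        stop("p-values must lie in [0, 1]")
    }
    p.adjust(p, method = "BH")
}

#' Leading log-fold-change distances between samples
#'
#' For each pair of samples, the root-mean-square of the `top_n` largest
#' absolute log2 differences between their expression profiles (the
#' "leading logFC" distance used for MDS ordination of sequencing samples).
#' Optionally removes a batch covariate (e.g. donor) by regressing it out of
#' each feature before computing distances.
#'
#' @param logcpm Feature x sample matrix of log2 values.
#' @param top_n Number of most divergent features per sample pair.
#' @param batch Optional factor/vector of batch labels per sample to regress
#'   out first.
#' @return Symmetric sample x sample distance matrix with zero diagonal.
#' @export
leadingLogFCDistance <- function(logcpm, top_n, batch = NULL) {
    logcpm <- as.matrix(logcpm)
    if (top_n > nrow(logcpm)) stop("'top_n' exceeds number of features")
    if (!is.null(batch)) {
        b <- factor(batch)
        X <- model.matrix(~b)
        H <- X %*% solve(crossprod(X), t(X))
        logcpm <- logcpm - logcpm %*% t(H) + rowMeans(logcpm)
    }
    ns <- ncol(logcpm)
    D <- matrix(0, ns, ns, dimnames = list(colnames(logcpm), colnames(logcpm)))
    for (i in seq_len(ns - 1L)) {
        for (j in (i + 1L):ns) {
            d2 <- sort((logcpm[, i] - logcpm[, j])^2, decreasing = TRUE)
            D[i, j] <- D[j, i] <- sqrt(mean(d2[seq_len(top_n)]))
        }
    }
    D
}
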