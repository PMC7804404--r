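# Precision-weighted linear modelling of log2-CPM with moderated t.
# Mirrors the mean-variance modelling idea: log2-CPM values are fitted by
# ordinary least squares, the sqrt residual standard deviation is smoothed
# against average log2 count, per-observation weights are the inverse of the
# predicted variance, and the weighted-LS residual variances are squeezed by
# empirical Bayes before forming moderated t statistics.

#' Weighted linear-model test with moderated t
#'
#' @inheritParams qlTest
#' @param span `lowess` span for the mean-variance trend.
#' @param prior.count Count added before the log2-CPM transform.
#' @return data.frame per feature: `logFC` (log2), `ave_logcpm`, `t`, `p`,
#'   `fdr`; attributes `df_prior`, `df_residual`, `weights`, `logcpm`.
#' @export
voomModeratedTest <- function(counts, design, contrast,
                              lib.size = colSums(counts), norm.factors = NULL,
                              span = 0.5, prior.count = 0.5, robust = TRUE,
                              prior.df = NULL) {
    Y <- as.matrix(counts)
    X <- as.matrix(design)
    ns <- ncol(Y); p <- ncol(X)
    df1 <- ns - p
    if (df1 < 1L) stop("need at least 1 residual degree of freedom")
    cv <- .contrastVector(X, contrast)
    eff <- .effectiveLib(lib.size, norm.factors)
    logcpm <- t(log2((t(Y) + prior.count) / (eff + 1) * 1e6))

    # pass 1: unweighted LS for the mean-variance trend
    XtXi <- solve(crossprod(X))
    B <- logcpm %*% X %*% XtXi
    E <- logcpm - B %*% t(X)
    sigma <- sqrt(rowSums(E^2) / df1)
    sx <- rowMeans(logcpm) + mean(log2(eff + 1)) - log2(1e6)
    sy <- sqrt(sigma)
    ok <- is.finite(sx) & is.finite(sy)
    lo <- lowess(sx[ok], sy[ok], f = span)
    predSd <- function(x) approx(lo$x, lo$y, xout = x, rule = 2)$y

    fitted_logcount <- B %*% t(X) +
        matrix(log2(eff + 1) - log2(1e6), nrow(Y), ns, byrow = TRUE)
    W <- pmax(predSd(fitted_logcount), 1e-4)^-4
    dim(W) <- dim(Y)

    # pass 2: weighted LS per feature
    ut <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
    Xprod <- X[, ut[, 1L], drop = FALSE] * X[, ut[, 2L], drop = FALSE]
    XtWX <- W %*% Xprod
    XtWy <- (W * logcpm) %*% X
    nf <- nrow(Y)
    Bw <- matrix(0, nf, p)
    unscaled <- numeric(nf)  # c' (X'WX)^-1 c
    for (g in seq_len(nf)) {
        A <- matrix(0, p, p)
        A[upper.tri(A, diag = TRUE)] <- XtWX[g, ]
        A <- A + t(A) - diag(diag(A), p)
        Ai <- tryCatch(solve(A), error = function(e) solve(A + diag(1e-8, p)))
        Bw[g, ] <- Ai %*% XtWy[g, ]
        unscaled[g] <- drop(t(cv) %*% Ai %*% cv)
    }
    Ew <- logcpm - Bw %*% t(X)
    s2 <- rowSums(W * Ew^2) / df1

    if (!is.null(prior.df) && prior.df == 0) {
        s2.post <- s2
        d0 <- 0
    } else {
        trendfun <- .qlTrend(s2, sx, df1)
        sq <- .squeezeVar(s2, df1, trendfun(sx), robust = robust)
        d0 <- if (!is.null(prior.df)) prior.df else sq$df.prior
        s2.post <- if (!is.null(prior.df)) {
            (df1 * s2 + d0 * sq$var.prior) / (df1 + d0)
        } else sq$var.post
    }
    logFC <- as.numeric(Bw %*% cv)
    tstat <- logFC / sqrt(unscaled * s2.post)
    df2 <- df1 + d0
    pval <- 2 * pt(abs(tstat), df2, lower.tail = FALSE)
    res <- data.frame(logFC = logFC,
                      ave_logcpm = aveLogCPM(Y, lib.size = lib.size,
                                             norm.factors = norm.factors),
                      t = tstat, p = pval, fdr = bhAdjust(pval))
    rownames(res) <- rownames(Y)
    attr(res, "df_prior") <- d0
    attr(res, "df_residual") <- df1
    attr(res, "weights") <- W
    attr(res, "logcpm") <- logcpm
    res
}
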