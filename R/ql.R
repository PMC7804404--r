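# Quasi-likelihood F-testing with robust empirical-Bayes squeezing of the
# QL dispersions toward a second abundance trend. The squeeze treats each
# per-feature QL dispersion s^2 (deviance / residual df) as scaled chi-square
# around a feature-specific prior value; prior df and scale are estimated by
# matching moments of log(s^2 / trend), with winsorized (outlier-resistant)
# moments when robust = TRUE.

.trigammaInverse <- function(x) {
    # Newton iteration for y with trigamma(y) = x
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in seq_len(50L)) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2L)
        y <- y + dif
        if (abs(dif) / y < 1e-8) break
    }
    y
}

# Squeeze per-feature variances s2 (on df1 df) toward trend values s2_trend.
# Returns list(df.prior, var.prior, var.post).
.squeezeVar <- function(s2, df1, s2_trend, robust = TRUE) {
    s2 <- pmax(s2, 1e-10)
    s2_trend <- pmax(s2_trend, 1e-10)
    z <- log(s2 / s2_trend)
    bias1 <- digamma(df1 / 2) - log(df1 / 2)   # E log(chisq_d/d)
    if (length(z) <= 2L) {
        warning("too few features to estimate a prior; using infinite prior df")
        return(list(df.prior = Inf, var.prior = s2_trend, var.post = s2_trend))
    }
    # location by the plain mean (exact chi-square bias correction below);
    # winsorization is applied to the spread moment only, where outlying
    # features would otherwise inflate the prior variance
    e <- z
    me <- mean(e)
    if (robust) {
        ctr <- median(e)
        sc <- mad(e)
        if (sc > 0) {
            cl <- qnorm(0.975)
            pin <- pmin(pmax((e - ctr) / sc, -cl), cl)
            # variance deflation of winsorizing a standard normal at +-cl
            vw <- 1 - 2 * (cl * dnorm(cl) + (1 - pnorm(cl))) + 2 * (1 - pnorm(cl)) * cl^2
            ve <- var(pin * sc) / vw
        } else {
            ve <- var(e)
        }
    } else {
        ve <- var(e)
    }
    gvar <- ve - trigamma(df1 / 2)
    if (is.na(gvar) || gvar < 1e-8) {
        df.prior <- Inf
        lprior <- me - bias1
    } else {
        df.prior <- 2 * .trigammaInverse(gvar)
        lprior <- me - bias1 + (digamma(df.prior / 2) - log(df.prior / 2))
    }
    var.prior <- exp(lprior) * s2_trend
    if (is.infinite(df.prior)) {
        var.post <- var.prior
    } else {
        var.post <- (df1 * s2 + df.prior * var.prior) / (df1 + df.prior)
    }
    list(df.prior = df.prior, var.prior = var.prior, var.post = var.post)
}

# Trend of QL dispersions vs abundance: binned means (unbiased for the
# chi-square sampling of s^2), lowess-smoothed on the log scale.
.qlTrend <- function(s2, ab, df1, nbins = 15L, span = 0.5) {
    if (length(unique(ab)) < 2L || length(s2) < 2L * nbins) {
        const <- mean(s2)
        return(function(a) rep(max(const, 1e-10), length(a)))
    }
    br <- unique(quantile(ab, probs = seq(0, 1, length.out = nbins + 1L)))
    grp <- cut(ab, breaks = br, include.lowest = TRUE)
    centers <- tapply(ab, grp, median)
    mns <- tapply(s2, grp, mean)
    ok <- !is.na(centers) & !is.na(mns) & mns > 0
    centers <- centers[ok]; mns <- mns[ok]
    if (length(centers) < 3L) {
        const <- mean(s2)
        return(function(a) rep(max(const, 1e-10), length(a)))
    }
    sm <- lowess(centers, log(mns), f = span)
    xs <- sm$x; ys <- sm$y
    function(a) exp(approx(xs, ys, xout = a, rule = 2)$y)
}

#' Quasi-likelihood F-test for a contrast
#'
#' Fits the full and null NB GLMs per feature (trended NB dispersions), forms
#' the QL dispersion from the full-model deviance, squeezes it toward a
#' second mean-dependent trend by robust empirical Bayes, and tests the
#' contrast with a moderated F statistic on `(1, df_residual + prior_df)`
#' degrees of freedom.
#'
#' @inheritParams fitNbGlm
#' @param contrast Coefficient name or numeric contrast vector.
#' @param dispersion Per-feature trended NB dispersions (e.g. from
#'   [estimateDispersionTrend()]); a scalar is recycled.
#' @param robust Winsorize the moment estimation of the prior df.
#' @param prior.df Override the estimated prior df (0 gives the unmoderated
#'   F-test).
#' @return A data.frame with one row per feature: `logFC` (log2),
#'   `ave_logcpm`, `F`, `p`, `fdr`, plus `df_prior` as an attribute.
#' @export
qlTest <- function(counts, design, contrast, dispersion, offsets = NULL,
                   lib.size = colSums(counts), norm.factors = NULL,
                   robust = TRUE, prior.df = NULL) {
    Y <- as.matrix(counts)
    X <- as.matrix(design)
    df1 <- ncol(Y) - ncol(X)
    if (df1 < 1L) stop("need at least 1 residual degree of freedom")
    cv <- .contrastVector(X, contrast)
    X0 <- .nullDesign(X, cv)
    full <- fitNbGlm(Y, X, dispersion, offsets = offsets, lib.size = lib.size,
                     norm.factors = norm.factors)
    null <- fitNbGlm(Y, X0, dispersion, offsets = full$offsets)
    ab <- aveLogCPM(Y, lib.size = lib.size, norm.factors = norm.factors)
    s2 <- pmax(full$deviance / df1, 1e-10)

    if (!is.null(prior.df) && prior.df == 0) {
        s2.post <- s2
        d0 <- 0
    } else {
        trendfun <- .qlTrend(s2, ab, df1)
        sq <- .squeezeVar(s2, df1, trendfun(ab), robust = robust)
        d0 <- if (!is.null(prior.df)) prior.df else sq$df.prior
        if (!is.null(prior.df)) {
            s2.post <- (df1 * s2 + d0 * sq$var.prior) / (df1 + d0)
        } else {
            s2.post <- sq$var.post
        }
    }
    drop <- pmax(null$deviance - full$deviance, 0)
    Fstat <- drop / s2.post
    df2 <- df1 + d0
    p <- pf(Fstat, 1, df2, lower.tail = FALSE)
    res <- data.frame(
        logFC = as.numeric(full$coefficients %*% cv) / log(2),
        ave_logcpm = ab,
        F = Fstat,
        p = p,
        fdr = bhAdjust(p))
    rownames(res) <- rownames(Y)
    attr(res, "df_prior") <- d0
    attr(res, "df_residual") <- df1
    res
}
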