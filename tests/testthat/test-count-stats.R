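# The statistical engine: normalization, GLM fitting, dispersion trends,
# QL testing, voom-style moderated t, and the small utility tests.

test_that("TMM factors behave on identities and match independent oracles", {
    set.seed(31)
    cc <- matrix(rpois(2000, 60), 1000, 2)
    cc[, 2] <- cc[, 1]
    expect_equal(tmmFactors(cc), c(1, 1))

    # a pure depth change is absorbed by the library size
    c2 <- cbind(cc[, 1], cc[, 1] * 2L)
    f <- tmmFactors(c2)
    expect_lt(abs(f[2] / f[1] - 1), 1e-8)

    # planted composition bias: explicit-sort oracle and edgeR cross-check
    cc <- matrix(rnbinom(4000, mu = 100, size = 2), 1000, 4)
    idx <- sample(1000, 100)
    cc[idx, 2] <- cc[idx, 2] * 8L
    lib <- colSums(cc)
    uq <- apply(cc, 2, quantile, 0.75) / lib
    ref <- which.min(abs(uq - mean(uq)))
    expect_equal(tmmFactors(cc, lib.size = lib), brute_tmm(cc, lib, ref))
    expect_equal(tmmFactors(cc), unname(edgeR::calcNormFactors(cc)),
                 tolerance = 1e-10)
    expect_error(tmmFactors(cbind(cc[, 1], 0L)), "all-zero")
})

test_that("CPM filtering is strict and equals per-feature evaluation", {
    cc <- matrix(0L, 5, 3)
    expect_false(any(cpmFilter(cc, 1.5, 2, lib.size = rep(1e7, 3))))
    # CPM exactly at the threshold fails the strict comparison
    cc <- matrix(15L, 1, 3)
    expect_false(cpmFilter(cc, 1.5, 2, lib.size = rep(1e7, 3)))
    cc <- matrix(16L, 1, 3)
    expect_true(cpmFilter(cc, 1.5, 2, lib.size = rep(1e7, 3)))

    set.seed(5)
    cc <- matrix(rpois(600, 5), 100, 6)
    lib <- runif(6, 1e6, 3e6)
    mask <- cpmFilter(cc, 2, 3, lib.size = lib)
    brute <- vapply(seq_len(nrow(cc)), function(i) {
        sum(cc[i, ] / lib * 1e6 > 2) >= 3
    }, logical(1))
    expect_equal(mask, brute)

    # eRNA mode: a fixed library size overrides the effective one
    expect_equal(cpmFilter(cc, 2, 3, lib.size = lib * 10, fixed_lib = lib),
                 brute)
})

test_that("NB GLM recovers closed forms and its deviance matches the likelihood", {
    Y <- matrix(rep(10L, 4), 1)
    X <- matrix(1, 4, 1)
    f <- fitNbGlm(Y, X, dispersion = 0.1, offsets = matrix(2, 1, 4))
    expect_equal(f$coefficients[1, 1], log(10) - 2, tolerance = 1e-7)

    Y <- matrix(c(10, 10, 10, 10, 40, 40, 40, 40), 1)
    X <- cbind(1, rep(c(0, 1), each = 4))
    f <- fitNbGlm(Y, X, dispersion = 0.1, offsets = matrix(0, 1, 8))
    expect_equal(f$coefficients[1, 2] / log(2), 2, tolerance = 1e-7)

    set.seed(41)
    for (i in 1:20) {
        y <- rnbinom(6, mu = runif(1, 5, 200), size = 5)
        phi <- runif(1, 0.01, 0.5)
        X <- cbind(1, c(0, 0, 0, 1, 1, 1))
        ft <- fitNbGlm(matrix(y, 1), X, dispersion = phi,
                       offsets = matrix(0, 1, 6))
        ll_fit <- sum(dnbinom(y, size = 1 / phi, mu = ft$fitted[1, ], log = TRUE))
        ll_sat <- sum(dnbinom(y, size = 1 / phi, mu = pmax(y, 1e-10), log = TRUE))
        expect_equal(ft$deviance, 2 * (ll_sat - ll_fit), tolerance = 1e-6)
    }
})

test_that("the dispersion trend recovers simulated dispersions", {
    set.seed(42)
    n <- 2000; ns <- 8
    mu0 <- rlnorm(n, log(100), 1)
    X <- cbind(1, rep(c(0, 1), each = 4))
    Y <- matrix(rnbinom(n * ns, mu = rep(mu0, ns), size = 1 / 0.05), n, ns)
    dt <- estimateDispersionTrend(Y, X, lib.size = rep(1e6, ns))
    expect_true(all(abs(dt$dispersion - 0.05) < 0.3 * 0.05))

    Yp <- matrix(rpois(n * ns, rep(mu0, ns)), n, ns)
    dtp <- estimateDispersionTrend(Yp, X, lib.size = rep(1e6, ns))
    expect_true(all(dtp$dispersion[mu0 > 100] <= 0.02))

    # deterministic: same data, same curve
    dt2 <- estimateDispersionTrend(Y, X, lib.size = rep(1e6, ns))
    expect_identical(dt$dispersion, dt2$dispersion)
})

null_counts <- function(n, ns, seed, dispersion = 0.05, donor_sd = 0.3) {
    set.seed(seed)
    lib <- rep(2e7, ns)
    q <- rlnorm(n, log(50), 1.2); q <- q / sum(q)
    don <- matrix(rnorm(n * 2, 0, donor_sd), n, 2)
    dcol <- rep(c(1, 2), ns / 2)
    mu <- sapply(seq_len(ns), function(s) lib[s] * q * 2^don[, dcol[s]])
    list(Y = matrix(rnbinom(n * ns, mu = mu, size = 1 / dispersion), n, ns),
         lib = lib,
         X = cbind(1, act = rep(c(0, 1), each = ns / 2),
                   donor = rep(c(0, 1), ns / 2)))
}

test_that("the QL F-test is calibrated under the null", {
    d <- null_counts(5000, 8, seed = 43)
    dtr <- estimateDispersionTrend(d$Y, d$X, lib.size = d$lib)
    tt <- qlTest(d$Y, d$X, "act", dispersion = dtr$dispersion,
                 lib.size = d$lib)
    expect_gt(mean(tt$p < 0.05), 0.035)
    expect_lt(mean(tt$p < 0.05), 0.065)
    expect_lt(suppressWarnings(ks.test(tt$p, "punif")$statistic), 0.03)
    expect_lte(mean(tt$fdr < 0.05), 0.07)
})

test_that("prior df 0 reduces the QL test to the unmoderated deviance F-test", {
    d <- null_counts(300, 6, seed = 44)
    disp <- rep(0.05, 300)
    tt <- qlTest(d$Y, d$X, "act", dispersion = disp, lib.size = d$lib,
                 prior.df = 0)
    # oracle: deviances from two explicit fits
    full <- fitNbGlm(d$Y, d$X, disp, lib.size = d$lib)
    X0 <- d$X[, c(1, 3)]
    null <- fitNbGlm(d$Y, X0, disp, lib.size = d$lib)
    df1 <- ncol(d$Y) - ncol(d$X)
    Fo <- pmax(null$deviance - full$deviance, 0) / (full$deviance / df1)
    expect_equal(tt$F, Fo, tolerance = 1e-8)
    expect_equal(tt$p, pf(Fo, 1, df1, lower.tail = FALSE), tolerance = 1e-8)
})

test_that("planted effects separate cleanly from null features", {
    set.seed(45)
    n <- 3000
    q <- rlnorm(n, log(80), 1); q <- q / sum(q)
    lfc <- numeric(n); lfc[1:100] <- 2
    act <- rep(c(0, 1), each = 4)
    lib <- rep(1e7, 8)
    mu <- sapply(1:8, function(s) lib[s] * q * 2^(act[s] * lfc))
    Y <- matrix(rnbinom(n * 8, mu = mu, size = 10), n, 8)
    X <- cbind(1, act = act)
    dtr <- estimateDispersionTrend(Y, X, lib.size = lib)
    tt <- qlTest(Y, X, "act", dispersion = dtr$dispersion, lib.size = lib)
    r <- rank(tt$p)
    auroc <- 1 - (mean(r[1:100]) - 50.5) / (n - 100)
    expect_gte(auroc, 0.9)
    expect_lt(median(tt$p[1:100]), median(tt$p[-(1:100)]) / 100)
    # squeezing property: posterior between raw and trend
    d <- attr(tt, "df_prior")
    expect_true(is.finite(d) || d == Inf)
})

test_that("empirical-Bayes squeezing moves dispersions toward the trend", {
    set.seed(55)
    d1 <- 4
    trend <- rep(1.2, 500)
    s2 <- trend * rchisq(500, d1) / d1 * exp(rnorm(500, 0, 0.3))
    sq <- chromshift:::.squeezeVar(s2, d1, trend, robust = TRUE)
    expect_true(all(abs(sq$var.post - sq$var.prior) <=
                    abs(s2 - sq$var.prior) + 1e-12))
    # the posterior lies between the raw value and the prior
    expect_true(all((sq$var.post - s2) * (sq$var.post - sq$var.prior) <= 1e-12))
})

test_that("planted log fold changes are estimated with small bias", {
    set.seed(56)
    n <- 1500; ns <- 16
    q <- rlnorm(n, log(80), 1); q <- q / sum(q)
    lfc <- numeric(n); lfc[1:150] <- 2
    act <- rep(c(0, 1), each = 8)
    lib <- rep(1e7, ns)
    mu <- sapply(seq_len(ns), function(s) lib[s] * q * 2^(act[s] * lfc))
    Y <- matrix(rnbinom(n * ns, mu = mu, size = 1 / 0.05), n, ns)
    X <- cbind(1, act = act)
    dtr <- estimateDispersionTrend(Y, X, lib.size = lib)
    tt <- qlTest(Y, X, "act", dispersion = dtr$dispersion, lib.size = lib)
    expect_lt(abs(median(tt$logFC[1:150]) - 2), 0.1)
})

test_that("BH adjustment matches the step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.37), 0.37)
    set.seed(46)
    for (i in 1:20) {
        p <- runif(sample(2:50, 1))
        expect_equal(bhAdjust(p), brute_bh(p))
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("voom-style moderated t is calibrated and reduces to weighted LS", {
    d <- null_counts(5000, 8, seed = 47)
    vt <- voomModeratedTest(d$Y, d$X, "act", lib.size = d$lib)
    expect_lt(suppressWarnings(ks.test(vt$p, "punif")$statistic), 0.03)
    expect_lte(mean(vt$fdr < 0.05), 0.07)

    # prior df 0: ordinary weighted least squares, by direct linear algebra
    d <- null_counts(200, 6, seed = 48)
    vt <- voomModeratedTest(d$Y, d$X, "act", lib.size = d$lib, prior.df = 0)
    W <- attr(vt, "weights")
    L <- attr(vt, "logcpm")
    cv <- c(0, 1, 0)
    for (g in c(1, 50, 200)) {
        A <- t(d$X) %*% (W[g, ] * d$X)
        b <- solve(A, t(d$X) %*% (W[g, ] * L[g, ]))
        res <- L[g, ] - d$X %*% b
        s2 <- sum(W[g, ] * res^2) / (6 - 3)
        tg <- (cv %*% b) / sqrt(drop(t(cv) %*% solve(A) %*% cv) * s2)
        expect_equal(vt$t[g], drop(tg), tolerance = 1e-8)
    }

    # near-equal weights: logFC is the difference of group mean log2-CPM
    set.seed(49)
    Y <- matrix(rnbinom(200 * 6, mu = 300, size = 20), 200, 6)
    X <- cbind(1, act = rep(c(0, 1), each = 3))
    vt <- voomModeratedTest(Y, X, "act", lib.size = rep(1e6, 6))
    lc <- attr(vt, "logcpm")
    direct <- rowMeans(lc[, 4:6]) - rowMeans(lc[, 1:3])
    expect_equal(vt$logFC, direct, tolerance = 1e-2)
})

test_that("tests are invariant to feature order and global library rescaling", {
    d <- null_counts(400, 6, seed = 50)
    disp <- rep(0.08, 400)
    tt <- qlTest(d$Y, d$X, "act", dispersion = disp, lib.size = d$lib)
    perm <- sample(400)
    tp <- qlTest(d$Y[perm, ], d$X, "act", dispersion = disp[perm],
                 lib.size = d$lib)
    expect_equal(tp$p, tt$p[perm], tolerance = 1e-10)
    ts <- qlTest(d$Y, d$X, "act", dispersion = disp, lib.size = d$lib * 7)
    expect_equal(ts$p, tt$p, tolerance = 1e-6)
})

test_that("leading logFC distances match sort-and-RMS by hand", {
    x <- matrix(rnorm(50 * 4), 50, 4)
    x[, 2] <- x[, 1]
    D <- leadingLogFCDistance(x, top_n = 10)
    expect_equal(D[1, 2], 0)
    expect_equal(diag(D), rep(0, 4))
    expect_equal(D, t(D))

    y <- x
    y[1:10, 3] <- x[1:10, 3]   # unchanged
    z <- cbind(x[, 1], x[, 1])
    z[1:10, 2] <- z[1:10, 2] + 1
    Dz <- leadingLogFCDistance(z, top_n = 10)
    expect_equal(Dz[1, 2], 1)

    set.seed(51)
    m <- matrix(rnorm(200 * 3), 200, 3)
    D <- leadingLogFCDistance(m, top_n = 25)
    for (i in 1:2) for (j in (i + 1):3) {
        d2 <- sort((m[, i] - m[, j])^2, decreasing = TRUE)[1:25]
        expect_equal(D[i, j], sqrt(mean(d2)))
    }
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
    r <- fisherExact2x2(matrix(c(5, 0, 0, 5), 2))
    expect_equal(r$p, 2 / 252, tolerance = 1e-10)
    expect_equal(fisherExact2x2(matrix(1, 2, 2))$p, 1)
    set.seed(52)
    for (i in 1:40) {
        tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
        expect_equal(fisherExact2x2(tab)$p, brute_fisher_p(tab),
                     tolerance = 1e-8)
    }
    expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("the rank-sum test is exact for small samples", {
    r <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r$p, 0.1, tolerance = 1e-10)
    expect_gt(wilcoxonRankSum(c(1, 2, 5, 9), c(9, 5, 2, 1))$p, 0.9)
    set.seed(53)
    for (i in 1:20) {
        x <- round(rnorm(sample(3:4, 1)), 4)
        y <- round(rnorm(sample(3:4, 1)), 4)
        expect_equal(wilcoxonRankSum(x, y)$p, brute_wilcox_p(x, y),
                     tolerance = 1e-8)
    }
    expect_error(wilcoxonRankSum(numeric(0), 1), "empty")
})
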