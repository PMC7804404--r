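# Negative binomial GLM engine. Fits log-link NB models to every feature of a
# count matrix by Fisher scoring (IRLS), vectorised across features: the
# weighted cross-products X'WX and X'Wz are computed for all features at once
# as matrix products, leaving only a small p x p solve per feature and
# iteration.

.nbDeviance <- function(y, mu, phi) {
    # unit deviances summed per feature; phi (length nrow) recycles per row
    mu <- pmax(mu, 1e-10)
    pois <- phi < 1e-12
    ylogy <- y * log(ifelse(y > 0, y / mu, 1))
    dp <- 2 * (ylogy - (y - mu))
    if (all(pois)) {
        d <- dp
    } else {
        phis <- pmax(phi, 1e-12)
        d <- 2 * (ylogy - (y + 1 / phis) * (log1p(phis * y) - log1p(phis * mu)))
        if (any(pois)) {
            if (is.matrix(d)) d[pois, ] <- dp[pois, ] else d[pois] <- dp[pois]
        }
    }
    if (is.matrix(d)) rowSums(d) else sum(d)
}

# NB log-likelihood at fitted means (for oracle cross-checks).
.nbLogLik <- function(y, mu, phi) {
    mu <- pmax(mu, 1e-10)
    if (phi < 1e-12) return(sum(dpois(y, mu, log = TRUE)))
    sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

#' Fit negative binomial GLMs feature-wise
#'
#' Fits a log-link NB generalized linear model with known per-feature
#' dispersion to every row of `counts`, with per-observation offsets
#' (natural-log scale) defaulting to the log effective library sizes.
#' Estimation is Fisher scoring to convergence (relative deviance change
#' below `tol` or `maxit` iterations); non-converged features are flagged,
#' not fatal.
#'
#' @param counts Feature x sample count matrix.
#' @param design Sample x coefficient model matrix (full column rank).
#' @param dispersion Scalar or per-feature NB dispersion (0 = Poisson).
#' @param offsets Optional feature x sample matrix of natural-log offsets;
#'   defaults to `log(lib.size * norm.factors)` per sample.
#' @param lib.size,norm.factors Used only to build default offsets.
#' @param maxit,tol IRLS iteration cap and relative deviance tolerance.
#' @return List with `coefficients` (feature x p, natural-log scale),
#'   `fitted` (means), `deviance`, `df.residual`, `converged`, `offsets`.
#' @export
fitNbGlm <- function(counts, design, dispersion, offsets = NULL,
                     lib.size = colSums(counts), norm.factors = NULL,
                     maxit = 50L, tol = 1e-8) {
    Y <- as.matrix(counts)
    X <- as.matrix(design)
    nf <- nrow(Y); ns <- ncol(Y); p <- ncol(X)
    if (nrow(X) != ns) stop("design rows must match samples")
    if (qr(X)$rank < p) stop("design matrix is not of full column rank")
    if (ns - p < 0L) stop("more coefficients than samples")
    if (is.null(offsets)) {
        eff <- .effectiveLib(lib.size, norm.factors)
        offsets <- matrix(log(eff), nf, ns, byrow = TRUE)
    }
    O <- as.matrix(offsets)
    phi <- rep_len(dispersion, nf)

    # initial coefficients from OLS on shifted log counts
    Z0 <- log(Y + 0.5) - O
    XtXi <- solve(crossprod(X))
    B <- Z0 %*% X %*% XtXi

    # index pairs for the symmetric X'WX blocks
    ut <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
    Xprod <- X[, ut[, 1L], drop = FALSE] * X[, ut[, 2L], drop = FALSE]

    dev <- rep(Inf, nf)
    active <- rep(TRUE, nf)
    converged <- rep(FALSE, nf)
    for (it in seq_len(maxit)) {
        Eta <- B %*% t(X) + O
        Eta <- pmin(pmax(Eta, -700), 700)
        Mu <- pmax(exp(Eta), 1e-10)
        W <- Mu / (1 + phi * Mu)
        Zw <- (Eta - O) + (Y - Mu) / Mu
        XtWX <- W %*% Xprod                      # nf x p(p+1)/2
        XtWz <- (W * Zw) %*% X                   # nf x p
        idx_active <- which(active)
        for (g in idx_active) {
            A <- matrix(0, p, p)
            A[upper.tri(A, diag = TRUE)] <- XtWX[g, ]
            A <- A + t(A) - diag(diag(A), p)
            bg <- tryCatch(solve(A, XtWz[g, ]), error = function(e) {
                solve(A + diag(1e-8, p), XtWz[g, ])
            })
            B[g, ] <- bg
        }
        Eta <- B %*% t(X) + O
        Mu <- pmax(exp(pmin(pmax(Eta, -700), 700)), 1e-10)
        newdev <- .nbDeviance(Y, Mu, phi)
        done <- abs(newdev - dev) < tol * (abs(dev) + 0.1)
        converged[active & done] <- TRUE
        dev <- newdev
        active <- active & !done
        if (!any(active)) break
    }
    Eta <- B %*% t(X) + O
    Mu <- pmax(exp(pmin(pmax(Eta, -700), 700)), 1e-10)
    list(coefficients = B, fitted = Mu, deviance = dev,
         df.residual = ns - p, converged = converged, offsets = O)
}

# Resolve a contrast specification (coefficient name or numeric vector)
# into a numeric coefficient combination.
.contrastVector <- function(design, contrast) {
    p <- ncol(design)
    if (is.character(contrast)) {
        stopifnot(length(contrast) == 1L)
        j <- match(contrast, colnames(design))
        if (is.na(j)) stop("unknown coefficient: ", contrast)
        cv <- numeric(p); cv[j] <- 1
        return(cv)
    }
    cv <- as.numeric(contrast)
    if (length(cv) != p) stop("contrast length must equal ncol(design)")
    if (all(cv == 0)) stop("contrast is all zero")
    cv
}

# Null design spanning the subspace where the contrast is zero.
.nullDesign <- function(design, cv) {
    p <- ncol(design)
    cv <- cv / sqrt(sum(cv^2))
    M <- diag(p) - tcrossprod(cv)
    sv <- svd(M)
    N <- sv$u[, sv$d > 1e-8, drop = FALSE]
    as.matrix(design) %*% N
}
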