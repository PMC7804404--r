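#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test by hypergeometric enumeration (tables with
#' probability at most that of the observed table are summed).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio` (conditional MLE) and `p`.
#' @export
fisherExact2x2 <- function(tab) {
    tab <- as.matrix(tab)
    if (!all(dim(tab) == c(2L, 2L))) stop("'tab' must be 2x2")
    if (any(tab < 0) || any(tab != round(tab))) {
        stop("table entries must be non-negative integers")
    }
    ft <- fisher.test(tab)
    list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with tie correction; exact p for combined n <= 20
#' without ties, normal approximation otherwise.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return List with `W` (rank-sum statistic for `x`) and `p`.
#' @export
wilcoxonRankSum <- function(x, y) {
    if (length(x) == 0L || length(y) == 0L) stop("empty group")
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- !ties && (length(x) + length(y)) <= 20L
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
    list(W = unname(wt$statistic), p = wt$p.value)
}

#' Welch two-sample t-test on interaction spans
#'
#' @param x,y Numeric vectors.
#' @return List with `t`, `df`, `p` (x minus y).
#' @keywords internal
.welchT <- function(x, y) {
    tt <- t.test(x, y)
    list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

# Simes combination of a vector of p-values.
.simes <- function(p) {
    m <- length(p)
    min(1, min(m * sort(p) / seq_len(m)))
}
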