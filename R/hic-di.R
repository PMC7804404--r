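# LOESS offsets and differential interaction testing.

#' Abundance-dependent LOESS normalization offsets
#'
#' For each sample, fits a robust local regression (`lowess`, default span
#' 0.3 with 3 robustifying iterations) of the sample's M-value (log2 ratio to
#' the across-sample mean profile) against A-value (average log2 abundance),
#' separately for bin pairs closer to the diagonal than `near_cutoff` and for
#' the rest (short-range interactions have their own bias regime). Returned
#' offsets are on the natural-log scale and row-centred so that the mean
#' offset of every bin pair equals the mean log effective library size;
#' supplying them to the GLM removes the trended bias.
#'
#' @param bp A filtered [BinPairs-class] object.
#' @param near_cutoff Gap (bp) separating the near-diagonal stratum.
#' @param span,iters `lowess` span and robustifying iterations.
#' @param min_stratum Minimum bin pairs per stratum; below it the stratum
#'   falls back to a constant (median M) offset with a warning.
#' @return Feature x sample matrix of natural-log offsets.
#' @export
loessOffsets <- function(bp, near_cutoff = 150000, span = 0.3, iters = 3L,
                         min_stratum = 50L) {
    cnt <- SummarizedExperiment::assay(bp, "counts")
    lib <- SummarizedExperiment::colData(bp)$lib.size
    ns <- ncol(cnt)
    if (ns < 2L) stop("offset normalization needs >= 2 samples")
    gap <- pairGaps(bp)
    L <- log2(t((t(cnt) + 0.5) / (lib + 1) * 1e6))
    A <- rowMeans(L)
    M <- L - A
    fit <- matrix(0, nrow(cnt), ns)
    near <- gap < near_cutoff
    for (stratum in list(which(near), which(!near))) {
        if (length(stratum) == 0L) next
        if (length(stratum) < min_stratum) {
            warning("stratum with fewer than ", min_stratum,
                    " bin pairs: falling back to median offsets")
            for (s in seq_len(ns)) {
                fit[stratum, s] <- median(M[stratum, s])
            }
            next
        }
        a <- A[stratum]
        # fit on the abundance bulk only: the extreme tail is dominated by a
        # handful of (possibly genuinely differential) bin pairs whose own
        # signal must not be absorbed into the normalization; beyond the
        # bulk the trend is extended as a constant
        qa <- quantile(a, c(0.01, 0.95))
        use <- a >= qa[1] & a <= qa[2]
        if (sum(use) < 10L) use <- rep(TRUE, length(a))
        o <- order(a[use])
        for (s in seq_len(ns)) {
            lo <- lowess(a[use][o], M[stratum, s][use][o], f = span,
                         iter = iters)
            fit[stratum, s] <- approx(lo$x, lo$y, xout = a, rule = 2,
                                      ties = "ordered")$y
        }
    }
    fit <- fit - rowMeans(fit)
    sweep(fit * log(2), 2L, log(lib), "+")
}

#' Test bin pairs for differential interactions
#'
#' Estimates a mean-dependent NB dispersion trend on the offset-normalized
#' counts and applies the quasi-likelihood F-test ([qlTest()]) to the given
#' contrast. Bin pairs with FDR < 0.05 are the differential interactions;
#' `direction` is "gained" for positive and "lost" for negative log fold
#' change.
#'
#' @param bp A filtered [BinPairs-class] object.
#' @param design Model matrix (samples x coefficients).
#' @param contrast Coefficient name or numeric contrast.
#' @param offsets Optional natural-log offset matrix; computed by
#'   [loessOffsets()] when `NULL`.
#' @param fdr_cut FDR threshold defining a DI.
#' @param ... Passed to [qlTest()].
#' @return A data.frame (one row per bin pair) with anchor coordinates, bin
#'   indices, `gap`, `logFC`, `ave_logcpm`, `F`, `p`, `fdr`, `direction`.
#' @export
testDifferentialInteractions <- function(bp, design, contrast, offsets = NULL,
                                         fdr_cut = 0.05, ...) {
    cnt <- SummarizedExperiment::assay(bp, "counts")
    lib <- SummarizedExperiment::colData(bp)$lib.size
    if (is.null(offsets)) offsets <- loessOffsets(bp)
    dtr <- estimateDispersionTrend(cnt, design, offsets = offsets,
                                   lib.size = lib)
    tt <- qlTest(cnt, design, contrast, dispersion = dtr$dispersion,
                 offsets = offsets, lib.size = lib, ...)
    a1 <- anchors(bp, 1); a2 <- anchors(bp, 2)
    rd <- SummarizedExperiment::rowData(bp)
    res <- data.frame(
        chrom1 = as.character(GenomeInfoDb::seqnames(a1)),
        start1 = BiocGenerics::start(a1), end1 = BiocGenerics::end(a1),
        chrom2 = as.character(GenomeInfoDb::seqnames(a2)),
        start2 = BiocGenerics::start(a2), end2 = BiocGenerics::end(a2),
        anchor1 = rd$anchor1, anchor2 = rd$anchor2, gap = rd$gap,
        tt, stringsAsFactors = FALSE)
    res$direction <- ifelse(res$fdr < fdr_cut,
                            ifelse(res$logFC > 0, "gained", "lost"), "ns")
    attr(res, "df_prior") <- attr(tt, "df_prior")
    attr(res, "bin_width") <- max(BiocGenerics::width(binGrid(bp)))
    res
}

#' Span contrast between gained and lost interactions
#'
#' Compares the genomic spans (anchor mid-point distances) of gained and
#' lost differential interactions with a Welch t-test.
#'
#' @param di A DI table from [testDifferentialInteractions()].
#' @return List with per-direction span summaries (`summary`), and `t`,
#'   `df`, `p` for the gained-minus-lost mean difference; `t` is `NA` with a
#'   flag when either direction is empty.
#' @export
interactionSpanContrast <- function(di) {
    g <- di$gap[di$direction == "gained"]
    l <- di$gap[di$direction == "lost"]
    summ <- data.frame(direction = c("gained", "lost"),
                       n = c(length(g), length(l)),
                       mean_span = c(mean(g), mean(l)),
                       median_span = c(median(g), median(l)))
    if (length(g) < 2L || length(l) < 2L) {
        return(list(summary = summ, t = NA_real_, df = NA_real_, p = NA_real_,
                    degenerate = TRUE))
    }
    wt <- .welchT(g, l)
    list(summary = summ, t = wt$t, df = wt$df, p = wt$p, degenerate = FALSE)
}
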