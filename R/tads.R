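# TAD segmentation from insulation profiles and cross-condition domain
# statistics. Replicate contact matrices are summed per condition before
# calling; per-sample counts are reserved for the boundary-strength test.

#' Inflate bin-pair counts to a dense contact matrix
#'
#' @param bp A [BinPairs-class] object (unfiltered recommended).
#' @param chrom Chromosome to inflate.
#' @param samples Optional column names/indices to sum (default all).
#' @return Dense symmetric matrix (bins of `chrom` x bins of `chrom`).
#' @export
inflateContacts <- function(bp, chrom, samples = NULL) {
    bins <- binGrid(bp)
    sel <- which(as.character(GenomeInfoDb::seqnames(bins)) == chrom)
    if (!length(sel)) stop("unknown chromosome: ", chrom)
    off <- min(sel) - 1L
    n <- length(sel)
    cnt <- SummarizedExperiment::assay(bp, "counts")
    if (!is.null(samples)) cnt <- cnt[, samples, drop = FALSE]
    v <- rowSums(cnt)
    rd <- SummarizedExperiment::rowData(bp)
    on_ch <- rd$anchor1 %in% sel
    M <- matrix(0, n, n)
    i <- rd$anchor1[on_ch] - off
    j <- rd$anchor2[on_ch] - off
    M[cbind(i, j)] <- v[on_ch]
    M[cbind(j, i)] <- v[on_ch]
    M
}

#' Insulation profile of a contact matrix
#'
#' For each bin boundary position b (the left edge of bin b), the score is
#' `log2` of the total contact count in the `window x window` square spanning
#' the boundary (rows `b-window .. b-1`, columns `b .. b+window-1`) over the
#' expectation of the same square from the chromosome-wide per-distance mean
#' counts. Lower scores mean stronger insulation; positions whose window is
#' incomplete at the chromosome ends are `NA`.
#'
#' @param mat Square symmetric contact matrix.
#' @param window Window size in bins.
#' @return Numeric vector (length `nrow(mat)`) of scores, `NA` at the ends.
#' @export
insulationProfile <- function(mat, window = 10L) {
    n <- nrow(mat)
    if (!is.matrix(mat) || n != ncol(mat)) stop("'mat' must be square")
    if (window < 1L || 2L * window > n) stop("window exceeds matrix")
    # per-distance expected counts
    dm <- vapply(0:(n - 1L), function(d) {
        mean(mat[cbind(seq_len(n - d), seq_len(n - d) + d)])
    }, numeric(1))
    # distances present in the crossing square are fixed: v - u for
    # u in -window..-1 (rows b+u), v in 0..window-1 (cols b+v)
    dists <- outer(1:window, 0:(window - 1L), "+")
    exp_sum <- sum(dm[pmin(dists, n - 1L) + 1L])
    score <- rep(NA_real_, n)
    for (b in (window + 1L):(n - window + 1L)) {
        obs <- sum(mat[(b - window):(b - 1L), b:(b + window - 1L)])
        # a zero observed square is maximal insulation, not missing data
        score[b] <- if (exp_sum > 0) log2(obs / exp_sum) else NA_real_
    }
    score
}

#' @describeIn insulationProfile Convenience wrapper: per-chromosome profiles
#'   from a [BinPairs-class] object (summing `samples`).
#' @inheritParams inflateContacts
#' @export
insulationProfiles <- function(bp, window = 10L, samples = NULL) {
    chroms <- GenomeInfoDb::seqlevels(binGrid(bp))
    out <- lapply(chroms, function(ch) {
        insulationProfile(inflateContacts(bp, ch, samples), window = window)
    })
    names(out) <- chroms
    out
}

# Prominence of local minima: depth below the lower of the two enclosing
# ridges, walking outwards until a strictly lower value is met.
.minimaProminence <- function(x) {
    n <- length(x)
    idx <- which(!is.na(x))
    v <- x[idx]
    m <- length(v)
    is_min <- which(diff(sign(diff(v))) > 0) + 1L  # strict local minima
    out <- data.frame(pos = integer(0), prominence = numeric(0))
    for (k in is_min) {
        left_max <- -Inf
        i <- k - 1L
        while (i >= 1L) {
            if (v[i] < v[k]) break
            left_max <- max(left_max, v[i])
            i <- i - 1L
        }
        if (i < 1L) left_max <- max(v[seq_len(k - 1L)])
        right_max <- -Inf
        i <- k + 1L
        while (i <= m) {
            if (v[i] < v[k]) break
            right_max <- max(right_max, v[i])
            i <- i + 1L
        }
        if (i > m) right_max <- max(v[(k + 1L):m])
        out <- rbind(out, data.frame(pos = idx[k],
                                     prominence = min(left_max, right_max) - v[k]))
    }
    out
}

#' Call TADs from insulation profiles
#'
#' Boundaries are local minima of the insulation profile whose prominence
#' (depth below the lower enclosing ridge) reaches `min_depth`; TADs are the
#' intervals between successive boundaries and the chromosome ends. The
#' boundary region reported for a boundary at bin b is bin b itself: the
#' first bin of the downstream TAD.
#'
#' @param insulation Named list of per-chromosome insulation profiles (from
#'   [insulationProfile()]).
#' @param bins Genome-wide bins matching the profiles.
#' @param min_depth Minimum prominence (log2 units) of a boundary.
#' @param condition Label stored in the result.
#' @return A [TADSet-class].
#' @export
callTads <- function(insulation, bins, min_depth = 0.5,
                     condition = "unspecified") {
    if (!is.numeric(min_depth)) stop("'min_depth' must be numeric")
    chroms <- names(insulation)
    all_tads <- NULL
    all_bounds <- NULL
    ch_bins <- split(seq_along(bins),
                     as.character(GenomeInfoDb::seqnames(bins)))
    for (ch in chroms) {
        prof <- insulation[[ch]]
        sel <- ch_bins[[ch]]
        mins <- .minimaProminence(prof)
        bl <- sort(mins$pos[mins$prominence >= min_depth])
        edges <- c(1L, bl, length(prof) + 1L)
        g <- bins[sel]
        starts <- BiocGenerics::start(g)[edges[-length(edges)]]
        ends <- BiocGenerics::end(g)[edges[-1L] - 1L]
        all_tads <- c(all_tads, list(GenomicRanges::GRanges(
            ch, IRanges::IRanges(starts, ends))))
        if (length(bl)) {
            all_bounds <- c(all_bounds, list(g[bl]))
        }
    }
    tads <- suppressWarnings(do.call(c, all_tads))
    bounds <- if (is.null(all_bounds)) GenomicRanges::GRanges()
              else suppressWarnings(do.call(c, all_bounds))
    TADSet(tads = tads, boundaries = bounds, condition = condition)
}

#' Cross-condition TAD intersection statistics
#'
#' A TAD of `a` "intersects" `b` when some TAD of `b` has reciprocal overlap
#' above `frac`; it "multi-overlaps" when it shares any bases with two or
#' more TADs of `b`.
#'
#' @param a,b [TADSet-class] objects on the same genome.
#' @param frac Reciprocal-overlap threshold (strict).
#' @return List with `intersect_fraction`, `multi_overlap_fraction` (over
#'   `length(tads(a))`), and a per-TAD `mapping` data.frame (best reciprocal
#'   overlap and overlap count).
#' @export
tadIntersectionStats <- function(a, b, frac = 0.75) {
    ta <- tads(a); tb <- tads(b)
    if (!length(ta) || !length(tb)) {
        return(list(intersect_fraction = NA_real_,
                    multi_overlap_fraction = NA_real_,
                    mapping = data.frame(), degenerate = TRUE))
    }
    ov <- GenomicRanges::findOverlaps(ta, tb)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    ro <- reciprocalOverlap(ta[qh], tb[sh])
    best <- rep(0, length(ta))
    cnt <- rep(0L, length(ta))
    for (k in seq_along(qh)) {
        best[qh[k]] <- max(best[qh[k]], ro[k])
        cnt[qh[k]] <- cnt[qh[k]] + 1L
    }
    list(intersect_fraction = mean(best > frac),
         multi_overlap_fraction = mean(cnt >= 2L),
         mapping = data.frame(tad = seq_along(ta), best_reciprocal = best,
                              n_overlaps = cnt),
         degenerate = FALSE)
}
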