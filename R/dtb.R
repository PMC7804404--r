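# Differential TAD boundary strength. Boundary strength is the ratio of
# upstream to downstream read pairs anchored at a 50 kbp boundary region;
# activation-induced changes in that ratio are tested with the QL framework
# on the paired (up, down) counts, with per-sample intercepts absorbing
# depth and regional coverage so only the condition x direction interaction
# is tested.

#' Count read pairs upstream and downstream of boundary regions
#'
#' For every boundary region and sample, counts read pairs with exactly one
#' anchor inside the region and the other anchor within `flank` bp upstream
#' (respectively downstream) of the region. Pairs with both anchors inside
#' the region count for neither direction; partners beyond the flank are
#' ignored.
#'
#' @param read_pairs Named list of per-sample read-pair tables
#'   (`chrom1, pos1, chrom2, pos2`).
#' @param regions GRanges of boundary regions (typically 50 kbp bins).
#' @param flank Flank width in bp (default 1 Mbp).
#' @return List with `regions`, `up` and `down` (region x sample count
#'   matrices).
#' @export
boundaryUpDownCounts <- function(read_pairs, regions, flank = 1e6) {
    if (is.data.frame(read_pairs)) read_pairs <- list(sample1 = read_pairs)
    ns <- length(read_pairs)
    nr <- length(regions)
    up <- matrix(0L, nr, ns, dimnames = list(NULL, names(read_pairs)))
    down <- matrix(0L, nr, ns, dimnames = list(NULL, names(read_pairs)))
    if (length(GenomicRanges::reduce(regions)) != length(regions)) {
        stop("boundary regions must be disjoint")
    }
    rs <- BiocGenerics::start(regions)
    re <- BiocGenerics::end(regions)
    for (s in seq_len(ns)) {
        rp <- read_pairs[[s]]
        intra <- rp$chrom1 == rp$chrom2
        ch <- rp$chrom1[intra]
        p1 <- rp$pos1[intra]
        p2 <- rp$pos2[intra]
        g1 <- GenomicRanges::GRanges(ch, IRanges::IRanges(p1, p1))
        g2 <- GenomicRanges::GRanges(ch, IRanges::IRanges(p2, p2))
        r1 <- GenomicRanges::findOverlaps(g1, regions, select = "first")
        r2 <- GenomicRanges::findOverlaps(g2, regions, select = "first")
        same <- !is.na(r1) & !is.na(r2) & r1 == r2
        count_side <- function(r_self, other_pos) {
            valid <- !is.na(r_self) & !same
            rr <- r_self[valid]; op <- other_pos[valid]
            upc <- op < rs[rr] & op >= rs[rr] - flank
            dnc <- op > re[rr] & op <= re[rr] + flank
            list(up = tabulate(rr[upc], nbins = nr),
                 down = tabulate(rr[dnc], nbins = nr))
        }
        c1 <- count_side(r1, p2)
        c2 <- count_side(r2, p1)
        up[, s] <- c1$up + c2$up
        down[, s] <- c1$down + c2$down
    }
    list(regions = regions, up = up, down = down)
}

#' Test boundaries for differential strength
#'
#' Models the paired (up, down) counts of every boundary region across
#' samples with per-sample intercepts, a direction effect per condition, and
#' tests the condition x direction interaction: the change, upon activation,
#' of the log2 downstream/upstream ratio. With boundary regions defined as
#' the first bin of the downstream TAD (the [callTads()] convention),
#' upstream counts are the cross-boundary ones, so a positive interaction
#' (ratio increase) means the boundary strengthened.
#'
#' Regions with average log2-CPM below `min_logcpm` (against the per-sample
#' library sizes) are removed before testing.
#'
#' @param bct Result of [boundaryUpDownCounts()].
#' @param condition Factor of per-sample conditions (2 levels, second =
#'   activated).
#' @param lib.size Per-sample total read pairs (abundance filtering scale).
#' @param min_logcpm Abundance filter threshold.
#' @param fdr_cut FDR threshold for the strengthened/weakened classes.
#' @param ... Passed to [qlTest()].
#' @return data.frame per retained region: coordinates, `logFC` (change in
#'   log2 down/up), `ave_logcpm`, `F`, `p`, `fdr`, `class` in
#'   strengthened/weakened/stable.
#' @export
testBoundaryStrength <- function(bct, condition, lib.size, min_logcpm = 0.8,
                                 fdr_cut = 0.05, ...) {
    condition <- factor(condition)
    if (nlevels(condition) != 2L) stop("need exactly 2 conditions")
    ns <- ncol(bct$up)
    if (min(table(condition)) < 2L) stop("need >= 2 samples per condition")
    counts <- cbind(bct$up, bct$down)
    colnames(counts) <- c(paste0(colnames(bct$up), "_up"),
                          paste0(colnames(bct$down), "_down"))
    samp <- factor(rep(seq_len(ns), 2L))
    dir_down <- rep(c(0, 1), each = ns)
    act <- as.integer(condition == levels(condition)[2L])
    X <- cbind(model.matrix(~0 + samp),
               dir = dir_down,
               dir_act = dir_down * rep(act, 2L))
    ab <- aveLogCPM(counts, lib.size = rep(lib.size, 2L))
    keep <- ab >= min_logcpm
    if (!any(keep)) stop("no boundary region passes the abundance filter")
    cnt <- counts[keep, , drop = FALSE]
    dtr <- estimateDispersionTrend(cnt, X, lib.size = rep(lib.size, 2L))
    tt <- qlTest(cnt, X, contrast = "dir_act", dispersion = dtr$dispersion,
                 lib.size = rep(lib.size, 2L), ...)
    reg <- bct$regions[keep]
    res <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(reg)),
        start = BiocGenerics::start(reg), end = BiocGenerics::end(reg),
        tt, stringsAsFactors = FALSE)
    res$class <- ifelse(res$fdr < fdr_cut,
                        ifelse(res$logFC > 0, "strengthened", "weakened"),
                        "stable")
    attr(res, "kept") <- which(keep)
    res
}

#' Feature profiles across differential boundary classes
#'
#' Averages per-bin tracks (e.g. chromatin accessibility logCPM, nucleosome
#' occupancy) over each boundary region, assigns genes to regions by
#' TSS-in-region, and compares strengthened vs weakened boundary classes
#' with the rank-sum test.
#'
#' @param dtb Result of [testBoundaryStrength()].
#' @param tracks Named list of GRanges with a `score` column (bin-level
#'   tracks), and optionally `expression`: a GRanges of TSS positions with
#'   `score` = expression logCPM.
#' @return List with `values` (region x track data.frame with `class`) and
#'   `tests` (per-track Wilcoxon p, strengthened vs weakened).
#' @export
boundaryFeatureProfiles <- function(dtb, tracks) {
    reg <- GenomicRanges::GRanges(dtb$chrom,
                                  IRanges::IRanges(dtb$start, dtb$end))
    vals <- data.frame(class = dtb$class)
    for (nm in names(tracks)) {
        tr <- tracks[[nm]]
        ov <- GenomicRanges::findOverlaps(reg, tr)
        m <- tapply(tr$score[S4Vectors::subjectHits(ov)],
                    factor(S4Vectors::queryHits(ov), levels = seq_along(reg)),
                    mean)
        vals[[nm]] <- as.numeric(m)
    }
    tests <- lapply(names(tracks), function(nm) {
        x <- vals[[nm]][vals$class == "strengthened"]
        y <- vals[[nm]][vals$class == "weakened"]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (!length(x) || !length(y)) {
            return(data.frame(track = nm, W = NA_real_, p = NA_real_))
        }
        w <- wilcoxonRankSum(x, y)
        data.frame(track = nm, W = w$W, p = w$p)
    })
    list(values = vals, tests = do.call(rbind, tests))
}
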