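# From read pairs to bin-pair count tables. Positions are mapped to bins by
# integer arithmetic on the uniform grid (the terminal bin of a chromosome
# absorbs the remainder); inter-chromosomal pairs are never tabulated -- they
# are pooled per sample for background-ligation estimation.

# Map 1-based positions to global bin indices; attribute error includes the
# first offending record index.
.posToBin <- function(chrom, pos, bins) {
    ch_names <- GenomeInfoDb::seqlevels(bins)
    sl <- GenomeInfoDb::seqlengths(bins)
    width <- max(BiocGenerics::width(bins))
    nb <- ceiling(sl / width)
    offset <- setNames(c(0, cumsum(as.numeric(nb)))[seq_along(ch_names)],
                       ch_names)
    ci <- match(chrom, ch_names)
    bad <- which(is.na(ci))
    if (length(bad)) {
        stop("record ", bad[1L], ": unknown chromosome '", chrom[bad[1L]], "'")
    }
    bad <- which(pos < 1 | pos > sl[ci])
    if (length(bad)) {
        stop("record ", bad[1L], ": position ", pos[bad[1L]],
             " outside chromosome ", chrom[bad[1L]])
    }
    as.integer(offset[ci] + (pos - 1) %/% width + 1)
}

#' Count Hi-C read pairs into bin pairs
#'
#' Maps both ends of every intra-chromosomal read pair to genome-wide bins
#' and accumulates counts per (anchor1 <= anchor2) bin pair and sample.
#' Inter-chromosomal pairs are not tabulated; their per-sample totals are
#' kept in the object's metadata for background-ligation estimation, and
#' `lib.size` is the full per-sample input count, so
#' `colSums(counts) + interCounts()` reproduces the input totals.
#'
#' @param read_pairs A data.frame (`chrom1, pos1, chrom2, pos2`; 1-based
#'   positions) or a named list of them (one per sample).
#' @param bins Genome-wide bins from [makeBins()].
#' @return A [BinPairs-class] object.
#' @export
countBinPairs <- function(read_pairs, bins) {
    if (is.data.frame(read_pairs)) read_pairs <- list(sample1 = read_pairs)
    if (is.null(names(read_pairs))) {
        names(read_pairs) <- paste0("sample", seq_along(read_pairs))
    }
    per <- lapply(read_pairs, function(rp) {
        intra <- rp$chrom1 == rp$chrom2
        b1 <- .posToBin(rp$chrom1[intra], rp$pos1[intra], bins)
        b2 <- .posToBin(rp$chrom2[intra], rp$pos2[intra], bins)
        a1 <- pmin(b1, b2); a2 <- pmax(b1, b2)
        dt <- data.table::data.table(a1 = a1, a2 = a2)
        dt <- dt[, list(n = .N), by = c("a1", "a2")]
        list(tab = dt, inter = sum(!intra), total = nrow(rp))
    })
    merged <- data.table::rbindlist(
        lapply(seq_along(per), function(s) {
            dt <- data.table::copy(per[[s]]$tab)
            dt$s <- s
            dt
        }))
    key <- merged[, list(dummy = 1L), by = c("a1", "a2")]
    data.table::setorderv(key, c("a1", "a2"))
    counts <- matrix(0L, nrow(key), length(per),
                     dimnames = list(NULL, names(read_pairs)))
    # fill sample-wise via match on the ordered key
    mk <- paste(merged$a1, merged$a2)
    kk <- paste(key$a1, key$a2)
    rows <- match(mk, kk)
    counts[cbind(rows, merged$s)] <- merged$n
    BinPairs(counts, anchor1 = key$a1, anchor2 = key$a2, bins = bins,
             lib.size = vapply(per, `[[`, numeric(1), "total"),
             inter = vapply(per, `[[`, numeric(1), "inter"))
}

#' Background ligation frequency from inter-chromosomal pairs
#'
#' Pools the inter-chromosomal read pairs of all samples, counts them into
#' coarse (default 2 Mbp) bin pairs and reports the average abundance of an
#' inter-chromosomal bin pair, rescaled to the bin width of the interaction
#' analysis so it is directly comparable with bin-pair `aveLogCPM`
#' abundances.
#'
#' @inheritParams countBinPairs
#' @param chrom_sizes Named chromosome lengths.
#' @param bg_width Coarse bin width for the estimate (default 2 Mbp).
#' @param target_width Bin width of the interaction analysis the estimate
#'   will be compared against.
#' @return List with `ave_logcpm` (abundance at `target_width` scale),
#'   `rate` (mean pooled inter count per `bg_width` bin pair), `n_inter_pairs`
#'   and `total_lib` (pooled library size).
#' @export
backgroundLigationFrequency <- function(read_pairs, chrom_sizes,
                                        bg_width = 2e6, target_width = bg_width) {
    if (is.data.frame(read_pairs)) read_pairs <- list(read_pairs)
    if (length(chrom_sizes) < 2L) stop("cannot estimate background: need >= 2 chromosomes")
    nb <- ceiling(chrom_sizes / bg_width)
    n_inter <- (sum(nb)^2 - sum(nb^2)) / 2
    inter_total <- 0
    total_lib <- 0
    for (rp in read_pairs) {
        total_lib <- total_lib + nrow(rp)
        inter_total <- inter_total + sum(rp$chrom1 != rp$chrom2)
    }
    if (inter_total == 0) stop("cannot estimate background: no inter-chromosomal pairs")
    rate <- inter_total / n_inter
    rate_target <- rate * (target_width / bg_width)^2
    list(ave_logcpm = .pooledAveLogCPM(rate_target, total_lib),
         rate = rate, n_inter_pairs = n_inter, total_lib = total_lib)
}

#' Filter bin pairs against background and artefact classes
#'
#' Applies, in a fixed documented order: (1) the per-bin marginal count
#' filter (bins whose pooled marginal count is below `min_bin_count` are
#' dropped with every pair touching them), (2) a chromosome blocklist (e.g.
#' sex chromosomes), (3) blacklist regions (any overlap of an anchor bin
#' drops the pair), (4) the first diagonal (pairs with
#' `|anchor2 - anchor1| <= diag_width` on the same chromosome), and (5) the
#' background abundance filter: a pair is retained only when its pooled
#' `aveLogCPM` is strictly more than `log2(fold)` above the background
#' ligation abundance.
#'
#' @param bp A [BinPairs-class] object.
#' @param background Result of [backgroundLigationFrequency()] computed at
#'   `target_width` matching the bin width of `bp`.
#' @param fold Required fold change over background (strict).
#' @param blacklist Optional GRanges of blacklisted regions.
#' @param exclude_chroms Optional character vector of chromosomes to drop.
#' @param min_bin_count Minimum pooled marginal count per bin.
#' @param diag_width Diagonal width to drop (0 = self pairs only).
#' @return The filtered `BinPairs`, with a `filter_stats` attribute counting
#'   removals per criterion.
#' @export
filterBinPairs <- function(bp, background, fold = 6, blacklist = NULL,
                           exclude_chroms = NULL, min_bin_count = 5L,
                           diag_width = 1L) {
    cnt <- SummarizedExperiment::assay(bp, "counts")
    rd <- SummarizedExperiment::rowData(bp)
    bins <- binGrid(bp)
    pooled <- rowSums(cnt)
    keep <- rep(TRUE, nrow(bp))
    stats <- c()

    # (1) marginal bin counts
    marg <- numeric(length(bins))
    tab1 <- tapply(pooled, rd$anchor1, sum)
    tab2 <- tapply(pooled, rd$anchor2, sum)
    marg[as.integer(names(tab1))] <- marg[as.integer(names(tab1))] + tab1
    marg[as.integer(names(tab2))] <- marg[as.integer(names(tab2))] + tab2
    bad_bin <- marg < min_bin_count
    drop <- bad_bin[rd$anchor1] | bad_bin[rd$anchor2]
    stats["low_bin_count"] <- sum(drop & keep)
    keep <- keep & !drop

    # (2) chromosome blocklist
    if (!is.null(exclude_chroms)) {
        ch <- as.character(GenomeInfoDb::seqnames(bins))
        drop <- ch[rd$anchor1] %in% exclude_chroms
        stats["excluded_chrom"] <- sum(drop & keep)
        keep <- keep & !drop
    }

    # (3) blacklist overlap
    if (!is.null(blacklist) && length(blacklist)) {
        bad <- IRanges::overlapsAny(bins, blacklist)
        drop <- bad[rd$anchor1] | bad[rd$anchor2]
        stats["blacklist"] <- sum(drop & keep)
        keep <- keep & !drop
    }

    # (4) first diagonal
    drop <- (rd$anchor2 - rd$anchor1) <= diag_width
    stats["diagonal"] <- sum(drop & keep)
    keep <- keep & !drop

    # (5) abundance over background
    ab <- aveLogCPM(cnt, lib.size = SummarizedExperiment::colData(bp)$lib.size)
    drop <- !(ab > background$ave_logcpm + log2(fold))
    stats["background"] <- sum(drop & keep)
    keep <- keep & !drop

    out <- bp[keep, ]
    attr(out, "filter_stats") <- stats
    out
}
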