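# Bin-pair counting, background filtering, LOESS offsets, DI testing and
# clustering.

test_that("bin-pair counting maps reads correctly and equals brute force", {
    bins <- makeBins(c(chr1 = 1e6, chr2 = 5e5), 25000)
    rp <- data.frame(chrom1 = c("chr1", "chr1"), pos1 = c(10, 10),
                     chrom2 = c("chr1", "chr1"), pos2 = c(30000, 12000))
    bp <- countBinPairs(rp, bins)
    rd <- SummarizedExperiment::rowData(bp)
    expect_equal(rd$anchor1, c(1L, 1L))
    expect_equal(rd$anchor2, c(1L, 2L))
    expect_equal(as.vector(SummarizedExperiment::assay(bp)), c(1L, 1L))

    set.seed(61)
    sizes <- c(chr1 = 1e6, chr2 = 5e5)
    n <- 1e4
    ch1 <- sample(names(sizes), n, replace = TRUE)
    ch2 <- sample(names(sizes), n, replace = TRUE)
    rp <- data.frame(chrom1 = ch1, pos1 = ceiling(runif(n) * sizes[ch1]),
                     chrom2 = ch2, pos2 = ceiling(runif(n) * sizes[ch2]))
    bp <- countBinPairs(rp, bins)
    oracle <- brute_bin_pairs(rp, sizes, 25000)
    rd <- SummarizedExperiment::rowData(bp)
    got <- data.frame(key = paste(rd$anchor1, rd$anchor2),
                      n = as.numeric(SummarizedExperiment::assay(bp)[, 1]))
    got <- got[order(got$key), ]
    oracle <- oracle[order(oracle$key), ]
    expect_equal(got$key, oracle$key)
    expect_equal(got$n, oracle$n)

    # conservation: tabulated intra + inter pool = input
    expect_equal(sum(SummarizedExperiment::assay(bp)) + interCounts(bp)[[1]],
                 n)

    rp_bad <- data.frame(chrom1 = "chr1", pos1 = 2e6, chrom2 = "chr1",
                         pos2 = 100)
    expect_error(countBinPairs(rp_bad, bins), "record 1")
})

test_that("background ligation frequency matches its closed-form expectation", {
    set.seed(62)
    sizes <- c(chr1 = 8e6, chr2 = 6e6)
    n <- 4e4
    ch1 <- sample(names(sizes), n, replace = TRUE, prob = sizes)
    ch2 <- sample(names(sizes), n, replace = TRUE, prob = sizes)
    rp <- data.frame(chrom1 = ch1, pos1 = ceiling(runif(n) * sizes[ch1]),
                     chrom2 = ch2, pos2 = ceiling(runif(n) * sizes[ch2]))
    bg <- backgroundLigationFrequency(rp, sizes, bg_width = 2e6)
    n_inter_reads <- sum(rp$chrom1 != rp$chrom2)
    expect_equal(bg$rate, n_inter_reads / (4 * 3))
    # doubling depth leaves the CPM-scale estimate essentially unchanged
    bg2 <- backgroundLigationFrequency(list(rp, rp), sizes, bg_width = 2e6)
    expect_lt(abs(bg2$ave_logcpm - bg$ave_logcpm), 0.01)
    expect_error(backgroundLigationFrequency(rp, sizes["chr1"]),
                 "2 chromosomes")
    rp_intra <- rp[rp$chrom1 == rp$chrom2, ]
    expect_error(backgroundLigationFrequency(rp_intra, sizes),
                 "no inter-chromosomal")
})

test_that("bin-pair filtering applies every criterion exactly", {
    h <- small_hic()
    bp <- h$bp100
    ab <- aveLogCPM(SummarizedExperiment::assay(bp),
                    lib.size = SummarizedExperiment::colData(bp)$lib.size)
    rd <- SummarizedExperiment::rowData(bp)

    # a pair exactly sixfold above background fails the strict filter
    fake_bg <- list(ave_logcpm = ab[100] - log2(6))
    f <- filterBinPairs(bp, fake_bg, min_bin_count = 0L)
    kept_keys <- paste(SummarizedExperiment::rowData(f)$anchor1,
                       SummarizedExperiment::rowData(f)$anchor2)
    expect_false(paste(rd$anchor1[100], rd$anchor2[100]) %in% kept_keys)

    # diagonal and adjacent pairs always dropped
    f <- filterBinPairs(bp, list(ave_logcpm = -100), min_bin_count = 0L)
    rdf <- SummarizedExperiment::rowData(f)
    expect_true(all(rdf$anchor2 - rdf$anchor1 > 1))

    # full predicate equals brute force
    bins <- binGrid(bp)
    bl <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 3e5))
    f <- filterBinPairs(bp, h$bg, fold = 6, blacklist = bl,
                        exclude_chroms = "chrB", min_bin_count = 5L)
    pooled <- rowSums(SummarizedExperiment::assay(bp))
    marg <- numeric(length(bins))
    for (i in seq_len(nrow(bp))) {
        marg[rd$anchor1[i]] <- marg[rd$anchor1[i]] + pooled[i]
        marg[rd$anchor2[i]] <- marg[rd$anchor2[i]] + pooled[i]
    }
    in_bl <- IRanges::overlapsAny(bins, bl)
    ch <- as.character(GenomeInfoDb::seqnames(bins))
    keep <- marg[rd$anchor1] >= 5 & marg[rd$anchor2] >= 5 &
        ch[rd$anchor1] != "chrB" &
        !in_bl[rd$anchor1] & !in_bl[rd$anchor2] &
        (rd$anchor2 - rd$anchor1) > 1 &
        ab > h$bg$ave_logcpm + log2(6)
    expect_equal(nrow(f), sum(keep))
    expect_equal(SummarizedExperiment::rowData(f)$anchor1, rd$anchor1[keep])
})

test_that("LOESS offsets are neutral on identical samples and remove planted bias", {
    h <- small_hic()
    bp <- h$fbp
    cnt <- SummarizedExperiment::assay(bp, "counts")
    lib <- SummarizedExperiment::colData(bp)$lib.size

    # identical samples: offsets equal the log library sizes
    twin <- BinPairs(cbind(a = cnt[, 1], b = cnt[, 1]),
                     SummarizedExperiment::rowData(bp)$anchor1,
                     SummarizedExperiment::rowData(bp)$anchor2,
                     bins = binGrid(bp), lib.size = c(lib[1], lib[1]))
    off <- loessOffsets(twin)
    expect_lt(max(abs(off - log(lib[1]))), 1e-8)

    # planted abundance-dependent bias: high-abundance pairs x2 in sample 2
    ab <- aveLogCPM(cnt[, 1:2], lib.size = lib[1:2])
    biased <- cnt[, 1:2]
    hi <- ab > median(ab)
    biased[hi, 2] <- biased[hi, 2] * 2L
    bb <- BinPairs(biased, SummarizedExperiment::rowData(bp)$anchor1,
                   SummarizedExperiment::rowData(bp)$anchor2,
                   bins = binGrid(bp), lib.size = lib[1:2])
    off <- loessOffsets(bb)
    # refit the M-vs-A slope after applying the offsets
    L <- log(biased + 0.5) - off
    M <- (L[, 2] - L[, 1]) / log(2)
    A <- aveLogCPM(biased, lib.size = lib[1:2])
    M0 <- log2((biased[, 2] + 0.5) / (biased[, 1] + 0.5)) -
        log2(lib[2] / lib[1])
    slope_raw <- coef(lm(M0 ~ A))[2]
    slope_corr <- coef(lm(M ~ A))[2]
    expect_lt(abs(slope_corr), 0.1 * abs(slope_raw))
    expect_lt(abs(median(M[hi]) - median(M[!hi])), 0.1)

    # row-centering: mean offset per pair = mean log effective size
    expect_equal(unname(rowMeans(off)), rep(mean(log(lib[1:2])), nrow(bb)),
                 tolerance = 1e-10)
})

test_that("differential interactions recover planted loops with correct sign", {
    scn <- small_loops_scenario()
    h <- small_loops_hic()
    keys <- loop_keys(scn)
    m <- match(keys, di_keys(h$di))
    tested <- !is.na(m)
    expect_gt(mean(tested), 0.6)
    hit <- h$di[stats::na.omit(m), ]
    cls <- scn$truth$loops$class[tested]
    sig <- hit$direction != "ns"
    expect_gt(mean(sig), 0.7)
    # sign convention: gained positive, lost negative
    expect_true(all(hit$logFC[sig & cls == "gained"] > 0))
    expect_true(all(hit$logFC[sig & cls == "lost"] < 0))
})

test_that("sample permutation permutes the pipeline outputs correspondingly", {
    h <- small_hic()
    scn <- small_scenario()
    perm <- c(2, 1, 4, 3)
    bp_perm <- countBinPairs(h$reads[perm], h$bins100)
    expect_equal(SummarizedExperiment::assay(bp_perm),
                 SummarizedExperiment::assay(h$bp100)[, perm])
    X_perm <- h$X[perm, ]
    di_perm <- testDifferentialInteractions(
        filterBinPairs(bp_perm, h$bg), X_perm, "act")
    expect_equal(di_perm$p, h$di$p, tolerance = 1e-8)
})

test_that("DI clusters combine by Simes and respect the size cap", {
    # single isolated DI: its own cluster, combined p = member p
    di <- data.frame(chrom1 = "chr1", start1 = 1, end1 = 1e5,
                     chrom2 = "chr1", start2 = 9e5, end2 = 1e6,
                     anchor1 = 1L, anchor2 = 9L, gap = 8e5,
                     logFC = 2, ave_logcpm = 3, F = 30,
                     p = 0.0001, fdr = 0.01, direction = "gained")
    extra <- di[rep(1, 30), ]
    extra$anchor1 <- 20L + seq_len(30); extra$anchor2 <- 60L + seq_len(30) * 3L
    extra$p <- 0.9; extra$fdr <- 0.9; extra$direction <- "ns"
    tab <- rbind(di, extra)
    attr(tab, "bin_width") <- 1e5
    cl <- clusterDifferentialInteractions(tab, max_size = 5e5)
    expect_equal(nrow(cl$clusters), 1L)
    expect_equal(cl$clusters$p_simes, 0.0001)

    # two adjacent DIs: Simes combination by hand
    di2 <- tab
    row2 <- di[1, ]; row2$anchor1 <- 2L; row2$anchor2 <- 9L
    row2$p <- 0.004; row2$fdr <- 0.02
    di2 <- rbind(di2, row2)
    di2$p[1] <- 0.001; di2$fdr[1] <- 0.02
    attr(di2, "bin_width") <- 1e5
    cl2 <- clusterDifferentialInteractions(di2, max_size = 5e5)
    expect_equal(nrow(cl2$clusters), 1L)
    expect_equal(cl2$clusters$p_simes, min(2 * 0.001 / 1, 2 * 0.004 / 2))
    expect_equal(cl2$clusters$p_simes, brute_simes(c(0.001, 0.004)))

    # a chain spanning three times the cap splits into >= 3 clusters
    n <- 31
    chain <- data.frame(chrom1 = "chr1", start1 = (0:(n - 1)) * 1e5 + 1,
                        end1 = (1:n) * 1e5,
                        chrom2 = "chr1", start2 = (0:(n - 1)) * 1e5 + 5e5 + 1,
                        end2 = (1:n) * 1e5 + 5e5,
                        anchor1 = 1:n, anchor2 = 6:(n + 5), gap = 5e5,
                        logFC = 1.5, ave_logcpm = 3, F = 25,
                        p = 1e-5, fdr = 1e-3, direction = "gained")
    attr(chain, "bin_width") <- 1e5
    clc <- clusterDifferentialInteractions(chain, max_size = 1e6)
    expect_gte(nrow(clc$clusters), 3L)
    side1 <- clc$clusters$end1 - clc$clusters$start1 + 1
    side2 <- clc$clusters$end2 - clc$clusters$start2 + 1
    expect_true(all(side1 <= 1e6 & side2 <= 1e6))
    # members' union equals the significant set
    expect_setequal(clc$members$row, seq_len(n))
})

test_that("interaction spans compare by Welch t with the documented sign", {
    h <- small_loops_hic()
    sp <- interactionSpanContrast(h$di)
    # spans equal the anchor mid-point distances by brute force
    g <- which(h$di$direction == "gained")
    mid1 <- (h$di$start1 + h$di$end1) / 2
    mid2 <- (h$di$start2 + h$di$end2) / 2
    expect_equal(h$di$gap, abs(mid2 - mid1))
    # planted design: gained short, lost long, so t (gained - lost) < 0
    expect_lt(sp$t, 0)
    expect_lt(sp$p, 0.01)

    # identical distributions: |t| small
    di0 <- h$di
    di0$direction <- rep(c("gained", "lost"), length.out = nrow(di0))
    di0 <- di0[order(di0$gap), ]
    sp0 <- interactionSpanContrast(di0)
    expect_lt(abs(sp0$t), 2)
})
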