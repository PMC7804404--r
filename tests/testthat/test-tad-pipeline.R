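# Insulation profiles, TAD calling, domain intersection statistics, and the
# differential boundary-strength machinery.

test_that("insulation profiles match the definition", {
    # uniform matrix: flat profile
    m <- matrix(5, 30, 30)
    s <- insulationProfile(m, window = 5)
    expect_true(all(abs(s[!is.na(s)]) < 1e-12))
    expect_true(all(is.na(s[1:5])))

    # two perfect blocks: global minimum exactly at the junction
    m <- matrix(0, 40, 40)
    m[1:20, 1:20] <- 10
    m[21:40, 21:40] <- 10
    s <- insulationProfile(m, window = 5)
    expect_equal(which.min(s), 21)

    # random matrices: equals the brute-force double loop
    set.seed(71)
    for (rep in 1:5) {
        n <- 25; w <- 4
        m <- matrix(rpois(n * n, 8), n, n)
        m[lower.tri(m)] <- t(m)[lower.tri(m)]
        s <- insulationProfile(m, window = w)
        dm <- brute_diag_means(m)
        for (b in (w + 1):(n - w + 1)) {
            obs <- 0; expv <- 0
            for (i in (b - w):(b - 1)) for (j in b:(b + w - 1)) {
                obs <- obs + m[i, j]
                expv <- expv + dm[j - i + 1]
            }
            expect_equal(s[b], log2(obs / expv), tolerance = 1e-10)
        }
    }
    expect_error(insulationProfile(matrix(1, 4, 4), window = 3), "window")
})

test_that("TAD calling recovers planted segmentations", {
    scn <- small_scenario()
    h <- small_hic()
    tadR <- callTads(insulationProfiles(h$bp50, 10, 1:2), h$bins50,
                     condition = "resting")
    # boundaries recovered within +-1 bin
    off <- setNames(c(0, cumsum(ceiling(scn$chrom_sizes / scn$bin_width)))[1:2],
                    names(scn$chrom_sizes))
    called <- off[as.character(GenomeInfoDb::seqnames(boundaries(tadR)))] +
        (BiocGenerics::start(boundaries(tadR)) - 1) / scn$bin_width + 1
    # only boundaries inside the scorable range (complete insulation
    # windows) are recoverable in principle
    nb <- ceiling(scn$chrom_sizes / scn$bin_width)
    scorable <- scn$truth$boundaries$bin >= 12 &
        scn$truth$boundaries$bin <= nb[scn$truth$boundaries$chrom] - 11
    tru <- (off[scn$truth$boundaries$chrom] + scn$truth$boundaries$bin)[scorable]
    hitrate <- mean(vapply(tru, function(b) any(abs(called - b) <= 1),
                           logical(1)))
    expect_gte(hitrate, 0.9)

    # TADs partition each chromosome
    tt <- tads(tadR)
    for (ch in names(scn$chrom_sizes)) {
        tch <- tt[as.character(GenomeInfoDb::seqnames(tt)) == ch]
        expect_equal(sum(BiocGenerics::width(tch)),
                     unname(floor(scn$chrom_sizes[[ch]] / scn$bin_width) *
                            scn$bin_width +
                            scn$chrom_sizes[[ch]] %% scn$bin_width))
        expect_equal(length(GenomicRanges::reduce(tch)), 1L)
    }

    # an infinite prominence threshold yields one TAD per chromosome
    tad1 <- callTads(insulationProfiles(h$bp50, 10, 1:2), h$bins50,
                     min_depth = Inf)
    expect_equal(length(tads(tad1)), length(scn$chrom_sizes))
    expect_length(boundaries(tad1), 0)
})

test_that("TAD intersection statistics match overlap arithmetic", {
    g <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 1000001, 2500001), c(1000000, 2500000, 4000000)))
    a <- TADSet(g, GenomicRanges::GRanges())
    s <- tadIntersectionStats(a, a)
    expect_equal(s$intersect_fraction, 1.0)
    expect_equal(s$multi_overlap_fraction, 0)

    # every TAD split in half: no reciprocal hit above 75%, all multi
    halves <- unlist(GenomicRanges::GRangesList(lapply(seq_along(g), function(i) {
        mid <- floor((BiocGenerics::start(g)[i] + BiocGenerics::end(g)[i]) / 2)
        GenomicRanges::GRanges("chr1", IRanges::IRanges(
            c(BiocGenerics::start(g)[i], mid + 1),
            c(mid, BiocGenerics::end(g)[i])))
    })))
    b <- TADSet(halves, GenomicRanges::GRanges())
    s <- tadIntersectionStats(a, b)
    expect_equal(s$intersect_fraction, 0)
    expect_equal(s$multi_overlap_fraction, 1)

    # random sets: equals all-pairs brute force
    set.seed(72)
    mk <- function(n) {
        st <- sort(sample.int(5e6, n))
        en <- st + sample.int(3e5, n) + 1e4
        TADSet(GenomicRanges::reduce(GenomicRanges::GRanges("chr1",
            IRanges::IRanges(st, en))), GenomicRanges::GRanges())
    }
    x <- mk(40); y <- mk(50)
    s <- tadIntersectionStats(x, y, frac = 0.5)
    tx <- tads(x); ty <- tads(y)
    bf_int <- bf_multi <- logical(length(tx))
    for (i in seq_along(tx)) {
        ro <- vapply(seq_along(ty), function(j) {
            reciprocalOverlap(tx[i], ty[j])
        }, numeric(1))
        bf_int[i] <- any(ro > 0.5)
        ov <- sum(IRanges::overlapsAny(ty, tx[i]))
        bf_multi[i] <- ov >= 2
    }
    expect_equal(s$intersect_fraction, mean(bf_int))
    expect_equal(s$multi_overlap_fraction, mean(bf_multi))
})

test_that("up/down read counting honours the region contract", {
    regions <- GenomicRanges::GRanges("chr1",
                                      IRanges::IRanges(1000001, 1050000))
    # downstream partner within the flank
    rp <- data.frame(chrom1 = "chr1", pos1 = 1010000, chrom2 = "chr1",
                     pos2 = 1550000)
    b <- boundaryUpDownCounts(rp, regions)
    expect_equal(unname(b$down[1, 1]), 1L)
    expect_equal(unname(b$up[1, 1]), 0L)
    # both anchors inside: neither direction
    rp <- data.frame(chrom1 = "chr1", pos1 = 1010000, chrom2 = "chr1",
                     pos2 = 1040000)
    b <- boundaryUpDownCounts(rp, regions)
    expect_equal(unname(b$down[1, 1] + b$up[1, 1]), 0L)
    # beyond the flank: ignored
    rp <- data.frame(chrom1 = "chr1", pos1 = 1010000, chrom2 = "chr1",
                     pos2 = 2100000)
    b <- boundaryUpDownCounts(rp, regions)
    expect_equal(unname(b$down[1, 1] + b$up[1, 1]), 0L)

    # random pairs equal brute-force classification
    set.seed(73)
    n <- 10000
    rp <- data.frame(chrom1 = "chr1", pos1 = sample.int(4e6, n, TRUE),
                     chrom2 = "chr1", pos2 = sample.int(4e6, n, TRUE))
    regions <- makeBins(c(chr1 = 4e6), 50000)[c(10, 30, 55)]
    b <- boundaryUpDownCounts(rp, regions, flank = 5e5)
    bf <- brute_updown(rp, regions, flank = 5e5)
    expect_equal(as.vector(b$up), bf$up)
    expect_equal(as.vector(b$down), bf$down)

    # mirror symmetry: reversing genome coordinates swaps up and down
    L <- 4e6
    rpm <- data.frame(chrom1 = "chr1", pos1 = L - rp$pos1 + 1,
                      chrom2 = "chr1", pos2 = L - rp$pos2 + 1)
    regm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        L - BiocGenerics::end(regions) + 1,
        L - BiocGenerics::start(regions) + 1))
    bm <- boundaryUpDownCounts(rpm, regm, flank = 5e5)
    expect_equal(as.vector(bm$up), as.vector(b$down))
    expect_equal(as.vector(bm$down), as.vector(b$up))
})

test_that("the boundary-strength test is a ratio test with nuisance absorption", {
    set.seed(74)
    ns <- 4
    nr <- 120
    cond <- factor(rep(c("resting", "activated"), each = 2),
                   levels = c("resting", "activated"))
    base_up <- rnbinom(nr, mu = 200, size = 20)
    base_dn <- rnbinom(nr, mu = 200, size = 20)
    mkbct <- function(up_mult, dn_mult) {
        up <- sapply(1:ns, function(s) {
            rnbinom(nr, mu = pmax(base_up, 1) * up_mult[s], size = 20)
        })
        dn <- sapply(1:ns, function(s) {
            rnbinom(nr, mu = pmax(base_dn, 1) * dn_mult[s], size = 20)
        })
        colnames(up) <- colnames(dn) <- paste0("s", 1:ns)
        list(regions = makeBins(c(chr1 = nr * 5e4), 5e4), up = up, down = dn)
    }
    # symmetric change: both directions x2 in activated -> ratio unchanged
    bct <- mkbct(c(1, 1, 2, 2), c(1, 1, 2, 2))
    dtb <- testBoundaryStrength(bct, cond, lib.size = rep(1e6, ns),
                                min_logcpm = -10)
    expect_lt(abs(median(dtb$logFC)), 0.15)
    expect_lte(mean(dtb$class != "stable"), 0.1)

    # doubling all counts leaves the test invariant
    bct2 <- bct
    bct2$up <- bct$up * 2L; bct2$down <- bct$down * 2L
    # (the dispersion trend is re-estimated, so equality is approximate)
    dtb2 <- testBoundaryStrength(bct2, cond, lib.size = rep(1e6, ns),
                                 min_logcpm = -10)
    expect_gt(cor(dtb2$logFC, dtb$logFC), 0.99)
    expect_lt(max(abs(dtb2$logFC - dtb$logFC)), 0.1)

    # upstream attenuated x3 in activated -> strengthened (positive logFC)
    bct3 <- mkbct(c(1, 1, 1 / 3, 1 / 3), c(1, 1, 1, 1))
    dtb3 <- testBoundaryStrength(bct3, cond, lib.size = rep(1e6, ns),
                                 min_logcpm = -10)
    expect_gt(mean(dtb3$class == "strengthened"), 0.7)
    expect_gt(median(dtb3$logFC), 1)
})

test_that("boundary feature profiles average tracks and compare classes", {
    dtb <- data.frame(chrom = "chr1",
                      start = seq(1, by = 5e4, length.out = 40),
                      end = seq(5e4, by = 5e4, length.out = 40),
                      class = rep(c("strengthened", "weakened"), 20))
    bins <- makeBins(c(chr1 = 40 * 5e4), 25000)
    tr <- bins
    set.seed(75)
    tr$score <- rnorm(length(tr), 1, 0.05)
    # plant occupancy on strengthened regions
    hit <- IRanges::overlapsAny(tr, GenomicRanges::GRanges(
        dtb$chrom[dtb$class == "strengthened"],
        IRanges::IRanges(dtb$start[dtb$class == "strengthened"],
                         dtb$end[dtb$class == "strengthened"])))
    tr$score[hit] <- tr$score[hit] + 0.5
    prof <- boundaryFeatureProfiles(dtb, list(occupancy = tr))
    expect_lt(prof$tests$p[1], 0.01)
    # per-region mean equals the brute-force average of covered bins
    for (r in c(1, 17, 40)) {
        reg <- GenomicRanges::GRanges(dtb$chrom[r],
                                      IRanges::IRanges(dtb$start[r], dtb$end[r]))
        ov <- IRanges::overlapsAny(tr, reg)
        expect_equal(prof$values$occupancy[r], mean(tr$score[ov]))
    }
    # identical tracks in both classes: no difference
    tr0 <- bins; tr0$score <- rnorm(length(tr0))
    prof0 <- boundaryFeatureProfiles(dtb, list(occupancy = tr0))
    expect_gt(prof0$tests$p[1], 0.05)
})
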