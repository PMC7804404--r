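# Shared simulated datasets, built once per test run and cached. The small
# bundle drives unit tests; the full-scale bundles drive the acceptance
# suite (several criteria share one activation scenario).

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
    if (!exists(key, envir = .cache)) {
        assign(key, force(expr), envir = .cache)
    }
    get(key, envir = .cache)
}

design_matrix <- function(design) {
    cbind(`(Intercept)` = 1,
          act = as.integer(design$condition == "activated"),
          donor = as.integer(design$donor == "d2"))
}

# end-to-end Hi-C analysis of a scenario at both resolutions
analyse_hic <- function(scn, depth = scn$hic_depth) {
    reads <- simulateScenarioHiC(scn, depth = depth)
    bins100 <- makeBins(scn$chrom_sizes, scn$di_binwidth)
    bins50 <- makeBins(scn$chrom_sizes, scn$bin_width)
    bp100 <- countBinPairs(reads, bins100)
    bp50 <- countBinPairs(reads, bins50)
    bg <- backgroundLigationFrequency(reads, scn$chrom_sizes,
                                      target_width = scn$di_binwidth)
    fbp <- filterBinPairs(bp100, bg)
    X <- design_matrix(scn$hic_design)
    di <- testDifferentialInteractions(fbp, X, "act")
    list(reads = reads, bins100 = bins100, bins50 = bins50, bp100 = bp100,
         bp50 = bp50, bg = bg, fbp = fbp, di = di, X = X,
         lib = vapply(reads, nrow, numeric(1)))
}

# map planted loops to the DI table's global 100 kbp bin-pair keys
loop_keys <- function(scn) {
    tr <- scn$truth$loops
    ratio <- scn$di_binwidth / scn$bin_width
    nb <- ceiling(scn$chrom_sizes / scn$di_binwidth)
    off <- setNames(c(0, cumsum(nb))[seq_along(nb)], names(nb))
    paste(off[tr$chrom] + (tr$a1_lo - 1) %/% ratio + 1,
          off[tr$chrom] + (tr$a2_lo - 1) %/% ratio + 1)
}

di_keys <- function(di) paste(di$anchor1, di$anchor2)

# small scenario for unit tests
small_scenario <- function() {
    memo("small_scn", buildActivationScenario(
        seed = 301, chrom_sizes = c(chrA = 8e6, chrB = 6e6),
        n_loops = 30L, n_genes = 800L, n_peaks = 800L, hic_depth = 6e5))
}

small_hic <- function() memo("small_hic", analyse_hic(small_scenario()))

# loops-only variant: the only planted differences are the loops, so DI
# calls can be judged against the loop truth alone
small_loops_scenario <- function() {
    memo("small_loops_scn", buildActivationScenario(
        seed = 302, chrom_sizes = c(chrA = 8e6, chrB = 6e6),
        split_fraction = 0, change_fraction = 0, flip_fraction = 0,
        n_loops = 30L, n_genes = 800L, n_peaks = 800L, hic_depth = 6e5))
}

small_loops_hic <- function() {
    memo("small_loops_hic", analyse_hic(small_loops_scenario()))
}

small_counts <- function() {
    memo("small_counts", simulateScenarioCounts(small_scenario()))
}

# full-scale activation scenario shared by the acceptance criteria
act_scenario <- function() memo("act_scn", buildActivationScenario(seed = 101))
act_hic <- function() memo("act_hic", analyse_hic(act_scenario()))
act_counts <- function() memo("act_counts", simulateScenarioCounts(act_scenario()))

act_tads <- function() {
    memo("act_tads", {
        h <- act_hic()
        scn <- act_scenario()
        rest <- scn$hic_design$sample[scn$hic_design$condition == "resting"]
        act <- scn$hic_design$sample[scn$hic_design$condition == "activated"]
        tadR <- callTads(insulationProfiles(h$bp50, 10, rest), h$bins50,
                         condition = "resting")
        tadA <- callTads(insulationProfiles(h$bp50, 10, act), h$bins50,
                         condition = "activated")
        list(rest = tadR, act = tadA, rest_samples = rest, act_samples = act)
    })
}

act_da_de <- function() {
    memo("act_da_de", {
        scn <- act_scenario()
        cnts <- act_counts()
        X <- design_matrix(scn$omics$genes$design)
        da <- testDifferentialAccessibility(cnts$peaks$counts, X, "act")
        nf <- tmmFactors(cnts$genes$counts)
        de <- voomModeratedTest(cnts$genes$counts, X, "act", norm.factors = nf)
        de$status <- ifelse(de$fdr < 0.05,
                            ifelse(de$logFC > 0, "up", "down"), "unchanged")
        de$gene_id <- rownames(de)
        list(da = da, de = de, X = X)
    })
}

# boundary universe and strength test for a scenario bundle
run_dtb <- function(scn, h, tads) {
    univ <- GenomicRanges::reduce(c(boundaries(tads$rest), boundaries(tads$act)))
    univ <- univ[BiocGenerics::width(univ) <= scn$bin_width]
    bct <- boundaryUpDownCounts(h$reads, univ)
    dtb <- testBoundaryStrength(bct, scn$hic_design$condition,
                                lib.size = h$lib)
    list(universe = univ, bct = bct, dtb = dtb)
}

# compartment tracks and flips for a scenario bundle
run_compartments <- function(scn, h) {
    rest <- scn$hic_design$sample[scn$hic_design$condition == "resting"]
    act <- scn$hic_design$sample[scn$hic_design$condition == "activated"]
    cR <- callCompartments(h$bp50, scn$tracks$accessibility, rest)
    cA <- callCompartments(h$bp50, scn$tracks$accessibility, act)
    flips <- NULL
    for (ch in names(scn$chrom_sizes)) {
        fl <- classifyFlips(cR[[ch]]$track, cA[[ch]]$track,
                            cR[[ch]]$oec, cA[[ch]]$oec)
        fl$chrom <- ch
        fl$bin <- seq_len(nrow(fl))
        flips <- rbind(flips, fl)
    }
    list(rest = cR, act = cA, flips = flips)
}

act_dtb <- function() {
    memo("act_dtb", run_dtb(act_scenario(), act_hic(), act_tads()))
}

# null scenario (no planted differences) at the calibration scale
null_scenario <- function() memo("null_scn", buildNullScenario(seed = 202))
null_hic <- function() memo("null_hic", analyse_hic(null_scenario()))
null_counts <- function() {
    memo("null_counts", simulateScenarioCounts(null_scenario()))
}
null_tads <- function() {
    memo("null_tads", {
        h <- null_hic()
        scn <- null_scenario()
        rest <- scn$hic_design$sample[scn$hic_design$condition == "resting"]
        act <- scn$hic_design$sample[scn$hic_design$condition == "activated"]
        list(rest = callTads(insulationProfiles(h$bp50, 10, rest), h$bins50,
                             condition = "resting"),
             act = callTads(insulationProfiles(h$bp50, 10, act), h$bins50,
                            condition = "activated"))
    })
}

act_network <- function() {
    memo("act_network", {
        scn <- act_scenario()
        h <- act_hic()
        dd <- act_da_de()
        keep <- cpmFilter(act_counts()$genes$counts, 1.5, 2)
        prom <- definePromoters(
            scn$annotation$genes[keep[scn$annotation$genes$gene_id], ],
            scn$chrom_sizes)
        buildRegulatoryNetwork(h$di, scn$annotation$peaks, dd$da, prom,
                               h$bins100)
    })
}
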