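# Activation scenarios: a resting architecture plus a derived activated one
# (TAD splits, boundary strengthening/weakening, compartment flips, gained
# and lost loops wired to planted DA peaks and DE genes), omics specs for the
# matching count data, and the truth tables that make every downstream call
# checkable. All scenario randomness is consumed at build time under one
# seed; data generation for a scenario sample uses seeds derived from it.

.deriveSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629)
}

# Sample TAD lengths (bins) until a chromosome is filled.
.sampleTads <- function(nbins, min_bins, max_bins) {
    lens <- integer(0)
    while (sum(lens) < nbins) {
        lens <- c(lens, sample(min_bins:max_bins, 1L))
    }
    lens[length(lens)] <- nbins - sum(head(lens, -1L))
    cumsum(head(lens, -1L)) + 1L  # first bin of each downstream TAD
}

.alternatingCompartments <- function(nbins, min_block = 20L, max_block = 60L) {
    lab <- character(0)
    cur <- "A"
    while (length(lab) < nbins) {
        lab <- c(lab, rep(cur, sample(min_block:max_block, 1L)))
        cur <- if (cur == "A") "B" else "A"
    }
    lab[seq_len(nbins)]
}

#' Build an activation scenario with planted multi-level remodelling
#'
#' Derives an "activated" chromatin architecture from a resting one by
#' splitting a fraction of TADs at a new internal boundary, strengthening and
#' weakening subsets of the pre-existing boundaries, flipping a small
#' fraction of compartment bins, and adding gained loops (and removing lost
#' ones) whose anchors carry a planted differentially accessible peak on one
#' side and the promoter of a planted differentially expressed gene on the
#' other. Returns the two architecture specs, the omics specs, annotation and
#' per-level truth tables.
#'
#' @param seed Integer seed; all scenario randomness derives from it.
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param bin_width Architecture grid (bp).
#' @param di_binwidth Bin width used for interaction testing; loop anchors
#'   are aligned to this grid.
#' @param split_fraction Fraction of resting TADs split in the activated
#'   state.
#' @param change_fraction Fraction of shared boundaries strengthened (and,
#'   independently, weakened) on activation.
#' @param strength_change Attenuation multiplier applied to strengthened
#'   boundaries (weakened ones are divided by it).
#' @param flip_fraction Fraction of compartment bins flipped.
#' @param n_loops Total planted loops (half gained, half lost).
#' @param loop_mult Differential loop multiplier: gained loops go from
#'   `loop_base` to `loop_base * loop_mult` on activation, lost loops the
#'   reverse (a condition ratio of `loop_mult`, resp. `1/loop_mult`).
#' @param loop_base Baseline enrichment of a loop anchor pair present in
#'   both conditions (loops change strength rather than appearing from
#'   nothing, and stay above the background-abundance filter).
#' @param subtad_boost Self-interaction boost of the sub-TADs created by a
#'   split (partitioning concentrates contacts into the smaller domains).
#'   `NULL` (default) calibrates the boost so the genome-wide expected
#'   contact mass is identical in both conditions: sequencing depth is fixed,
#'   so without this conservation every untouched bin pair would shift
#'   compositionally between conditions.
#' @param hic_depth Expected intra-chromosomal read pairs per Hi-C sample.
#' @param hic_dispersion NB dispersion of contact counts.
#' @param inter_fraction Inter-chromosomal (background ligation) pairs as a
#'   fraction of `hic_depth`.
#' @param n_genes,n_peaks Feature counts for the RNA and ATAC layers.
#' @param fraction_de,fraction_da Differential fractions (wired features
#'   included).
#' @param logfc_mag Planted |log2 FC| for DE genes and DA peaks.
#' @param donor_sd Donor batch-effect SD (log2).
#' @param rna_lib,atac_lib Mean library sizes.
#' @return A list of class `chromshift_scenario`; see Details in the package
#'   vignette. Key components: `arch$resting`/`arch$activated`, `hic_design`,
#'   `omics` (gene/peak/eRNA specs), `annotation` (genes, peaks, exons),
#'   `tracks` (per-bin accessibility and nucleosome occupancy), `truth`.
#' @export
buildActivationScenario <- function(seed = 1,
                                    chrom_sizes = c(chr1 = 4e7, chr2 = 3e7),
                                    bin_width = 5e4, di_binwidth = 1e5,
                                    split_fraction = 0.5,
                                    change_fraction = 0.25,
                                    strength_change = 3,
                                    flip_fraction = 0.015,
                                    n_loops = 200L, loop_mult = 4,
                                    loop_base = 2, subtad_boost = NULL,
                                    hic_depth = 3e6, hic_dispersion = 0.05,
                                    inter_fraction = 0.15,
                                    n_genes = 5000L, n_peaks = 5000L,
                                    genes_per_loop = 3L,
                                    fraction_de = 0.15, fraction_da = 0.1,
                                    logfc_mag = 2, donor_sd = 0.3,
                                    rna_lib = 2e7, atac_lib = 3e7) {
    if (split_fraction < 0 || split_fraction > 1 ||
        flip_fraction < 0 || flip_fraction > 1 ||
        change_fraction < 0 || change_fraction > 0.5) {
        stop("fractions must lie in [0, 1] (change_fraction in [0, 0.5])")
    }
    set.seed(as.integer(seed))
    chroms <- names(chrom_sizes)
    nbins <- ceiling(chrom_sizes / bin_width)
    ratio <- di_binwidth / bin_width

    ## resting TADs and boundary strengths
    tads_rest <- lapply(chroms, function(ch) .sampleTads(nbins[[ch]], 16L, 40L))
    names(tads_rest) <- chroms
    str_rest <- lapply(tads_rest, function(b) runif(length(b), 2, 3))

    ## activated: strengthen / weaken shared boundaries
    str_act <- str_rest
    bnd_truth <- NULL
    for (ch in chroms) {
        nb <- length(tads_rest[[ch]])
        cls <- rep("stable", nb)
        if (nb >= 2L) {
            nchg <- floor(change_fraction * nb)
            pick <- sample(nb, min(2L * nchg, nb))
            if (nchg > 0L) {
                cls[pick[seq_len(nchg)]] <- "strengthened"
                cls[pick[nchg + seq_len(min(nchg, length(pick) - nchg))]] <- "weakened"
            }
        }
        s <- str_rest[[ch]]
        s[cls == "strengthened"] <- s[cls == "strengthened"] * strength_change
        s[cls == "weakened"] <- pmax(s[cls == "weakened"] / strength_change, 1.05)
        str_act[[ch]] <- s
        bnd_truth <- rbind(bnd_truth, data.frame(
            chrom = ch, bin = tads_rest[[ch]], class = cls,
            stringsAsFactors = FALSE))
    }

    ## activated: split TADs
    tads_act <- tads_rest
    split_truth <- NULL
    for (ch in chroms) {
        edges <- c(1L, tads_rest[[ch]], nbins[[ch]] + 1L)
        sizes <- diff(edges)
        mids <- edges[-length(edges)] + sizes %/% 2L
        # split only TADs large enough to leave two real domains, with the
        # new boundary clear of the chromosome ends where the insulation
        # window is incomplete and no caller can score a boundary
        splittable <- which(sizes >= 12L & mids >= 15L & mids <= nbins[[ch]] - 14L)
        nsplit <- round(split_fraction * length(sizes))
        nsplit <- min(nsplit, length(splittable))
        if (nsplit > 0L) {
            for (t in splittable[sample.int(length(splittable), nsplit)]) {
                lo <- edges[t]; hi <- edges[t + 1L] - 1L
                newb <- lo + (hi - lo + 1L) %/% 2L + sample(-2:2, 1L)
                newb <- min(max(newb, lo + 3L), hi - 2L)
                tads_act[[ch]] <- c(tads_act[[ch]], newb)
                str_act[[ch]] <- c(str_act[[ch]], runif(1, 2.5, 3.5))
                split_truth <- rbind(split_truth, data.frame(
                    chrom = ch, bin = newb, tad_lo = lo, tad_hi = hi,
                    stringsAsFactors = FALSE))
            }
            ord <- order(tads_act[[ch]])
            tads_act[[ch]] <- tads_act[[ch]][ord]
            str_act[[ch]] <- str_act[[ch]][ord]
        }
    }

    # per-TAD enrichment in the activated state: sub-TADs born from a split
    # self-interact more intensely
    mkEnrAct <- function(boost) {
        out <- lapply(chroms, function(ch) {
            edges <- c(1L, tads_act[[ch]], nbins[[ch]] + 1L)
            e <- rep(3, length(edges) - 1L)
            spl <- NULL
            if (!is.null(split_truth)) {
                spl <- split_truth[split_truth$chrom == ch, , drop = FALSE]
            }
            if (!is.null(spl) && nrow(spl)) {
                for (t in seq_len(length(edges) - 1L)) {
                    if (any(edges[t] >= spl$tad_lo &
                            edges[t + 1L] - 1L <= spl$tad_hi)) {
                        e[t] <- 3 * boost
                    }
                }
            }
            e
        })
        names(out) <- chroms
        out
    }

    ## compartments and flips
    comp_rest <- lapply(chroms, function(ch) .alternatingCompartments(nbins[[ch]]))
    names(comp_rest) <- chroms
    comp_act <- comp_rest
    comp_truth <- NULL
    nflip_total <- round(flip_fraction * sum(nbins))
    flip_alloc <- table(factor(sample(chroms, nflip_total, replace = TRUE,
                                      prob = nbins), levels = chroms))
    for (ch in chroms) {
        nf <- flip_alloc[[ch]]
        flip_bins <- if (nf > 0L) sort(sample(nbins[[ch]], nf)) else integer(0)
        lab <- comp_rest[[ch]]
        lab_act <- lab
        lab_act[flip_bins] <- ifelse(lab[flip_bins] == "A", "B", "A")
        comp_act[[ch]] <- lab_act
        comp_truth <- rbind(comp_truth, data.frame(
            chrom = ch, bin = seq_len(nbins[[ch]]),
            label_rest = lab, label_act = lab_act,
            flip_class = paste0(lab, "->", lab_act),
            stringsAsFactors = FALSE))
    }

    ## loops: gained short-range, lost long-range, anchors on the DI grid
    n_gain <- n_loops %/% 2L
    n_lost <- n_loops - n_gain
    used <- character(0)
    mkloop <- function(kind) {
        for (try in seq_len(200L)) {
            ch <- sample(chroms, 1L, prob = nbins)
            gap_di <- if (kind == "gained") sample(2:8, 1L) else sample(8:14, 1L)
            max_block <- (nbins[[ch]] %/% ratio) - gap_di - 1L
            if (max_block < 1L) next
            k1 <- sample(max_block, 1L)
            a1_lo <- (k1 - 1L) * ratio + 1L
            a2_lo <- a1_lo + gap_di * ratio
            key <- paste(ch, a1_lo, a2_lo)
            if (key %in% used) next
            used <<- c(used, key)
            return(data.frame(chrom = ch, a1_lo = a1_lo, a1_hi = a1_lo + ratio - 1L,
                              a2_lo = a2_lo, a2_hi = a2_lo + ratio - 1L,
                              class = kind, stringsAsFactors = FALSE))
        }
        NULL
    }
    loops <- do.call(rbind, c(lapply(seq_len(n_gain), function(i) mkloop("gained")),
                              lapply(seq_len(n_lost), function(i) mkloop("lost"))))
    loops_rest <- data.frame(loops[c("chrom", "a1_lo", "a1_hi", "a2_lo", "a2_hi")],
                             mult = loop_base * ifelse(loops$class == "gained",
                                                       1, loop_mult))
    loops_act <- data.frame(loops[c("chrom", "a1_lo", "a1_hi", "a2_lo", "a2_hi")],
                            mult = loop_base * ifelse(loops$class == "gained",
                                                      loop_mult, 1))

    background_rate <- inter_fraction * hic_depth /
        ((sum(nbins)^2 - sum(nbins^2)) / 2)
    arch_rest <- architectureSpec(chrom_sizes, bin_width, tads_rest, str_rest,
                                  comp_rest, loops_rest,
                                  nb_dispersion = hic_dispersion,
                                  background_rate = background_rate)
    mkAct <- function(boost) {
        architectureSpec(chrom_sizes, bin_width, tads_act, str_act,
                         comp_act, loops_act,
                         tad_enrichment = if (!is.null(split_truth))
                             mkEnrAct(boost) else 3,
                         nb_dispersion = hic_dispersion,
                         background_rate = background_rate)
    }
    totalRel <- function(spec) {
        sum(vapply(chroms, function(ch) {
            M <- .contactMeans(spec, ch)
            sum(M[upper.tri(M, diag = TRUE)])
        }, numeric(1)))
    }
    if (is.null(subtad_boost)) {
        if (!is.null(split_truth)) {
            # expected contact mass is linear in the boost: solve for the
            # value conserving the resting total, so untouched bin pairs do
            # not shift compositionally under fixed sequencing depth
            t_rest <- totalRel(arch_rest)
            t1 <- totalRel(mkAct(1)); t2 <- totalRel(mkAct(2))
            subtad_boost <- 1 + (t_rest - t1) / (t2 - t1)
            subtad_boost <- min(max(subtad_boost, 1), 4)
        } else subtad_boost <- 1
    }
    arch_act <- mkAct(subtad_boost)

    ## gene / peak annotation with wired placements
    gene_lfc <- numeric(n_genes)
    peak_lfc <- numeric(n_peaks)
    gene_chrom <- sample(chroms, n_genes, replace = TRUE, prob = chrom_sizes)
    gene_tss <- floor(runif(n_genes, 6000, chrom_sizes[gene_chrom] - 12000))
    gene_strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    peak_chrom <- sample(chroms, n_peaks, replace = TRUE, prob = chrom_sizes)
    peak_start <- floor(runif(n_peaks, 1000, chrom_sizes[peak_chrom] - 2000))

    # wired loop couplings: a DA peak in anchor1 and a cluster of
    # co-regulated DE genes (promoters) in anchor2, signed by loop class
    loops$peak_id <- NA_character_
    loops$gene_id <- NA_character_
    for (k in seq_len(nrow(loops))) {
        p <- k
        gs <- (k - 1L) * genes_per_loop + seq_len(genes_per_loop)
        ch <- loops$chrom[k]
        a1 <- c((loops$a1_lo[k] - 1L) * bin_width, loops$a1_hi[k] * bin_width)
        a2 <- c((loops$a2_lo[k] - 1L) * bin_width, loops$a2_hi[k] * bin_width)
        peak_chrom[p] <- ch
        peak_start[p] <- floor(runif(1, a1[1] + 100, a1[2] - 700))
        gene_chrom[gs] <- ch
        gene_tss[gs] <- floor(runif(length(gs), a2[1] + 2000, a2[2] - 7000))
        sgn <- if (loops$class[k] == "gained") 1 else -1
        gene_lfc[gs] <- sgn * logfc_mag
        peak_lfc[p] <- sgn * logfc_mag
        loops$peak_id[k] <- sprintf("p%04d", p)
        loops$gene_id[k] <- sprintf("g%04d", gs[1L])
    }

    # flip couplings: one peak and one gene per flipped bin, signed by flip
    flips <- comp_truth[comp_truth$label_rest != comp_truth$label_act, ]
    off_p <- nrow(loops)
    off_g <- nrow(loops) * genes_per_loop
    for (k in seq_len(nrow(flips))) {
        p <- off_p + k; g <- off_g + k
        ch <- flips$chrom[k]
        lo <- (flips$bin[k] - 1L) * bin_width
        hi <- min(flips$bin[k] * bin_width, chrom_sizes[[ch]])
        sgn <- if (flips$flip_class[k] == "B->A") 1 else -1
        peak_chrom[p] <- ch
        peak_start[p] <- floor(runif(1, lo + 100, hi - 700))
        gene_chrom[g] <- ch
        gene_tss[g] <- floor(runif(1, lo + 2000, max(lo + 2001, hi - 7000)))
        gene_lfc[g] <- sgn * logfc_mag
        peak_lfc[p] <- sgn * logfc_mag
    }

    # fill the remaining DE quota at random
    want_de <- round(fraction_de * n_genes) - sum(gene_lfc != 0)
    if (want_de > 0) {
        pick <- sample(which(gene_lfc == 0), want_de)
        gene_lfc[pick] <- sample(c(-1, 1), want_de, TRUE) * logfc_mag
    }

    # accessibility changes co-locate with contact changes: a per-bin contact
    # trend (+1 near weakened boundaries, where cross-boundary interactions
    # gain; -1 near strengthened or newly created boundaries, where they are
    # lost) steers the random DA quota, mirroring the genome-wide coupling
    # between accessibility and 3D remodelling in activated T cells
    trend_w <- 10L
    trend <- lapply(chroms, function(ch) integer(nbins[[ch]]))
    names(trend) <- chroms
    mark <- function(ch, b, v) {
        lo <- max(1L, b - trend_w); hi <- min(nbins[[ch]], b + trend_w)
        trend[[ch]][lo:hi] <<- v
    }
    for (i in seq_len(nrow(bnd_truth))) {
        if (bnd_truth$class[i] == "weakened") {
            mark(bnd_truth$chrom[i], bnd_truth$bin[i], 1L)
        }
    }
    for (i in seq_len(nrow(bnd_truth))) {
        if (bnd_truth$class[i] == "strengthened") {
            mark(bnd_truth$chrom[i], bnd_truth$bin[i], -1L)
        }
    }
    peak_bin <- peak_start %/% bin_width + 1L
    peak_trend <- vapply(seq_len(n_peaks), function(p) {
        trend[[peak_chrom[p]]][min(peak_bin[p], nbins[[peak_chrom[p]]])]
    }, integer(1))
    # neutral bins: no contact remodelling touches their interactions
    # (outside split TADs, clear of changed boundaries and flipped bins)
    neutral <- lapply(chroms, function(ch) rep(TRUE, nbins[[ch]]))
    names(neutral) <- chroms
    markN <- function(ch, lo, hi) {
        lo <- max(1L, lo); hi <- min(nbins[[ch]], hi)
        neutral[[ch]][lo:hi] <<- FALSE
    }
    for (i in seq_len(nrow(bnd_truth))) {
        if (bnd_truth$class[i] != "stable") {
            markN(bnd_truth$chrom[i], bnd_truth$bin[i] - 2L * trend_w,
                  bnd_truth$bin[i] + 2L * trend_w)
        }
    }
    if (!is.null(split_truth)) {
        for (i in seq_len(nrow(split_truth))) {
            markN(split_truth$chrom[i], split_truth$tad_lo[i] - trend_w,
                  split_truth$tad_hi[i] + trend_w)
        }
    }
    for (i in which(comp_truth$label_rest != comp_truth$label_act)) {
        markN(comp_truth$chrom[i], comp_truth$bin[i] - 1L,
              comp_truth$bin[i] + 1L)
    }
    peak_neutral <- vapply(seq_len(n_peaks), function(p) {
        neutral[[peak_chrom[p]]][min(peak_bin[p], nbins[[peak_chrom[p]]])]
    }, logical(1))

    want_da <- round(fraction_da * n_peaks) - sum(peak_lfc != 0)
    if (want_da > 0) {
        # 60% of the quota follows the contact trend; the rest sits in
        # neutral regions with balanced signs, so peaks without any contact
        # change carry a symmetric population of accessibility changes
        matched <- round(0.6 * want_da)
        free <- which(peak_lfc == 0)
        n_up <- matched %/% 2L; n_dn <- matched - n_up
        up_pool <- free[peak_trend[free] > 0L]
        dn_pool <- free[peak_trend[free] < 0L]
        pick_up <- up_pool[sample.int(length(up_pool), min(n_up, length(up_pool)))]
        pick_dn <- dn_pool[sample.int(length(dn_pool), min(n_dn, length(dn_pool)))]
        peak_lfc[pick_up] <- logfc_mag
        peak_lfc[pick_dn] <- -logfc_mag
        rest <- want_da - length(pick_up) - length(pick_dn)
        if (rest > 0) {
            free2 <- which(peak_lfc == 0 & peak_neutral)
            if (length(free2) < rest) {
                free2 <- c(free2, setdiff(which(peak_lfc == 0), free2))
            }
            pick <- free2[seq_len(rest)]
            peak_lfc[pick] <- rep_len(c(1, -1), rest) * logfc_mag
        }
    }

    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    peak_ids <- sprintf("p%04d", seq_len(n_peaks))
    exon_len <- 5000L
    genes <- data.frame(gene_id = gene_ids, chrom = gene_chrom, tss = gene_tss,
                        strand = gene_strand,
                        exon_start = ifelse(gene_strand == "+", gene_tss,
                                            gene_tss - exon_len),
                        exon_end = ifelse(gene_strand == "+",
                                          gene_tss + exon_len, gene_tss),
                        stringsAsFactors = FALSE)
    peaks <- GenomicRanges::GRanges(peak_chrom,
                                    IRanges::IRanges(peak_start + 1,
                                                     peak_start + 500))
    peaks$peak_id <- peak_ids
    GenomeInfoDb::seqlengths(peaks) <- chrom_sizes[GenomeInfoDb::seqlevels(peaks)]

    ## per-bin tracks on the architecture grid
    bins50 <- makeBins(chrom_sizes, bin_width)
    lab_all <- unlist(comp_rest, use.names = FALSE)
    atac <- bins50
    atac$score <- 1 + 0.8 * (lab_all == "A") + rnorm(length(bins50), 0, 0.1)
    occ <- bins50
    occ$score <- rnorm(length(bins50), 1, 0.1)
    chrom_off <- c(0, cumsum(nbins))[seq_along(chroms)]
    names(chrom_off) <- chroms
    # occupancy is elevated wherever insulation strengthens: both boundaries
    # whose attenuation increases and the newly created split boundaries
    strengthened <- bnd_truth[bnd_truth$class == "strengthened", ]
    occ_bins <- c(chrom_off[strengthened$chrom] + strengthened$bin,
                  if (!is.null(split_truth)) {
                      chrom_off[split_truth$chrom] + split_truth$bin
                  })
    occ$score[occ_bins] <- occ$score[occ_bins] + 0.5

    ## omics design and specs (2 donors x 2 conditions)
    design <- data.frame(
        sample = c("rest_d1", "rest_d2", "act_d1", "act_d2"),
        condition = factor(c("resting", "resting", "activated", "activated"),
                           levels = c("resting", "activated")),
        donor = c("d1", "d2", "d1", "d2"), stringsAsFactors = FALSE)
    gene_spec <- omicsSpec(
        n_genes, design, lib_sizes = rna_lib * exp(rnorm(4, 0, 0.1)),
        fraction_de = sum(gene_lfc != 0) / n_genes, logfc_mag = logfc_mag,
        dispersion = 0.05, donor_sd = donor_sd,
        coupled = data.frame(feature = which(gene_lfc != 0),
                             logfc = gene_lfc[gene_lfc != 0]),
        feature_ids = gene_ids)
    peak_spec <- omicsSpec(
        n_peaks, design, lib_sizes = atac_lib * exp(rnorm(4, 0, 0.1)),
        logfc_mag = logfc_mag,
        dispersion = 0.05, donor_sd = donor_sd,
        fraction_de = sum(peak_lfc != 0) / n_peaks,
        coupled = data.frame(feature = which(peak_lfc != 0),
                             logfc = peak_lfc[peak_lfc != 0]),
        feature_ids = peak_ids)

    ## eRNA: expressed over non-exonic peaks, coupled to the DA effect
    exons <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$exon_start + 1,
                                                     genes$exon_end))
    nonexonic <- peak_ids[!IRanges::overlapsAny(peaks, exons)]
    ne_idx <- match(nonexonic, peak_ids)
    erna_lfc <- 0.8 * peak_lfc[ne_idx]
    erna_spec <- omicsSpec(
        length(nonexonic), design,
        lib_sizes = rna_lib * exp(rnorm(4, 0, 0.1)),
        fraction_de = sum(erna_lfc != 0) / length(nonexonic),
        logfc_mag = 0.8 * logfc_mag, dispersion = 0.1, donor_sd = donor_sd,
        baseline_log_mean = log(15),
        coupled = data.frame(feature = which(erna_lfc != 0),
                             logfc = erna_lfc[erna_lfc != 0]),
        feature_ids = nonexonic)

    hic_design <- data.frame(
        sample = design$sample, condition = design$condition,
        donor = design$donor,
        size_factor = exp(rnorm(4, 0, 0.05)), stringsAsFactors = FALSE)

    structure(list(
        seed = as.integer(seed), chrom_sizes = chrom_sizes,
        bin_width = bin_width, di_binwidth = di_binwidth,
        hic_depth = hic_depth,
        arch = list(resting = arch_rest, activated = arch_act),
        hic_design = hic_design,
        omics = list(genes = gene_spec, peaks = peak_spec, erna = erna_spec),
        annotation = list(genes = genes, peaks = peaks, exons = exons),
        tracks = list(accessibility = atac, occupancy = occ),
        truth = list(
            loops = loops, boundaries = bnd_truth, tad_splits = split_truth,
            compartments = comp_truth,
            genes = data.frame(gene_id = gene_ids, logfc = gene_lfc,
                               status = ifelse(gene_lfc > 0, "up",
                                               ifelse(gene_lfc < 0, "down", "null")),
                               stringsAsFactors = FALSE),
            peaks = data.frame(peak_id = peak_ids, logfc = peak_lfc,
                               status = ifelse(peak_lfc > 0, "up",
                                               ifelse(peak_lfc < 0, "down", "null")),
                               stringsAsFactors = FALSE)),
        params = list(split_fraction = split_fraction,
                      change_fraction = change_fraction,
                      strength_change = strength_change,
                      flip_fraction = flip_fraction, n_loops = n_loops,
                      loop_mult = loop_mult, loop_base = loop_base,
                      subtad_boost = subtad_boost,
                      hic_dispersion = hic_dispersion,
                      inter_fraction = inter_fraction, logfc_mag = logfc_mag,
                      donor_sd = donor_sd)),
        class = "chromshift_scenario")
}

#' Build a null scenario (no planted differences)
#'
#' Both conditions share one architecture (including static loops), all
#' differential fractions are zero, while the donor batch effect and
#' per-sample depth variation are retained as nuisances. Drives the type-I
#' error checks of every downstream test.
#'
#' @inheritParams buildActivationScenario
#' @return A `chromshift_scenario` whose truth tables contain no planted
#'   differences.
#' @export
buildNullScenario <- function(seed = 1, chrom_sizes = c(chr1 = 4e7, chr2 = 3e7),
                              hic_depth = 5e6, n_genes = 5000L,
                              n_peaks = 5000L, donor_sd = 0.3, ...) {
    scn <- buildActivationScenario(
        seed = seed, chrom_sizes = chrom_sizes, split_fraction = 0,
        change_fraction = 0, flip_fraction = 0, hic_depth = hic_depth,
        n_genes = n_genes, n_peaks = n_peaks,
        fraction_de = 0, fraction_da = 0, donor_sd = donor_sd, ...)
    # static loops: identical multiplier in both conditions
    scn$arch$activated$loops$mult <- scn$arch$resting$loops$mult
    scn$arch$activated$tads <- scn$arch$resting$tads
    scn$arch$activated$boundary_strengths <- scn$arch$resting$boundary_strengths
    scn$arch$activated$compartments <- scn$arch$resting$compartments
    scn$truth$loops$class <- "static"
    scn$truth$boundaries$class <- "stable"
    # remove the wired loop couplings: a null scenario plants no effects
    for (layer in names(scn$omics)) {
        scn$omics[[layer]]$coupled <- NULL
        scn$omics[[layer]]$fraction_de <- 0
    }
    scn$truth$genes$logfc <- 0; scn$truth$genes$status <- "null"
    scn$truth$peaks$logfc <- 0; scn$truth$peaks$status <- "null"
    scn
}

#' Simulate the Hi-C read pairs of a scenario
#'
#' One read-pair table per sample of `scn$hic_design`, each generated from
#' the architecture of the sample's condition under a seed derived from the
#' scenario seed (deterministic, reproducible per sample).
#'
#' @param scn A scenario from [buildActivationScenario()] /
#'   [buildNullScenario()].
#' @param depth Override the scenario's per-sample depth.
#' @return Named list of `data.table`s (`chrom1, pos1, chrom2, pos2`).
#' @export
simulateScenarioHiC <- function(scn, depth = scn$hic_depth) {
    des <- scn$hic_design
    out <- lapply(seq_len(nrow(des)), function(s) {
        spec <- scn$arch[[as.character(des$condition[s])]]
        simulateContactReads(spec, depth = depth,
                             seed = .deriveSeed(scn$seed, s),
                             size_factors = des$size_factor[s])[[1L]]
    })
    names(out) <- des$sample
    out
}

#' Simulate the count matrices of a scenario
#'
#' @param scn A scenario.
#' @return List with `genes`, `peaks`, `erna`, each a
#'   [simulateFeatureCounts()] result.
#' @export
simulateScenarioCounts <- function(scn) {
    list(genes = simulateFeatureCounts(scn$omics$genes,
                                       seed = .deriveSeed(scn$seed, 101L)),
         peaks = simulateFeatureCounts(scn$omics$peaks,
                                       seed = .deriveSeed(scn$seed, 102L)),
         erna = simulateFeatureCounts(scn$omics$erna,
                                      seed = .deriveSeed(scn$seed, 103L)))
}

#' Write a scenario's fixture tree to disk
#'
#' Emits per-sample Hi-C read-pair TSVs, gene/peak/eRNA count matrices, peak
#' BED, gene annotation TSV, per-bin accessibility and nucleosome-occupancy
#' bedGraph tracks, the truth tables and a JSON manifest carrying the seed
#' and all generative parameters. Regenerating with the manifest seed gives
#' an identical tree.
#'
#' @param scn A scenario.
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
writeFixtureSet <- function(scn, out_dir, force = FALSE) {
    if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force) {
        stop("output directory is not empty (use force = TRUE)")
    }
    dir.create(file.path(out_dir, "readpairs"), recursive = TRUE,
               showWarnings = FALSE)
    reads <- simulateScenarioHiC(scn)
    for (s in names(reads)) {
        data.table::fwrite(reads[[s]],
                           file.path(out_dir, "readpairs", paste0(s, ".tsv")),
                           sep = "\t")
    }
    cnts <- simulateScenarioCounts(scn)
    for (layer in names(cnts)) {
        dt <- data.table::data.table(feature = rownames(cnts[[layer]]$counts),
                                     cnts[[layer]]$counts)
        data.table::fwrite(dt, file.path(out_dir, paste0("counts_", layer, ".tsv")),
                           sep = "\t")
    }
    writeBed(scn$annotation$peaks, file.path(out_dir, "peaks.bed"))
    writeGeneTable(scn$annotation$genes, file.path(out_dir, "genes.tsv"))
    writeBedGraph(scn$tracks$accessibility,
                  file.path(out_dir, "accessibility.bedGraph"))
    writeBedGraph(scn$tracks$occupancy, file.path(out_dir, "occupancy.bedGraph"))
    data.table::fwrite(
        data.table::data.table(chrom = names(scn$chrom_sizes),
                               length = scn$chrom_sizes),
        file.path(out_dir, "chrom_sizes.tsv"), sep = "\t", col.names = FALSE)
    dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
    for (nm in names(scn$truth)) {
        tr <- scn$truth[[nm]]
        if (is.null(tr)) next
        data.table::fwrite(data.table::as.data.table(tr),
                           file.path(out_dir, "truth", paste0(nm, ".tsv")),
                           sep = "\t")
    }
    manifest <- c(list(seed = scn$seed,
                       chrom_sizes = as.list(scn$chrom_sizes),
                       bin_width = scn$bin_width,
                       di_binwidth = scn$di_binwidth,
                       hic_depth = scn$hic_depth,
                       hic_design = scn$hic_design),
                  scn$params)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(out_dir)
}
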