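# Cross-assay integration: differential accessibility, promoter definitions,
# the gene-regulatory interaction network linking DA peaks to promoters of
# expressed genes through tested bin pairs, coupling statistics, and eRNA
# analysis over non-exonic peaks.

#' Strand-aware promoter regions
#'
#' The promoter of a gene spans from 1 kb upstream to 100 bp downstream of
#' the TSS (mirrored on the minus strand), clipped at chromosome ends.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss` (0-based position),
#'   `strand` ("+"/"-").
#' @param chrom_sizes Optional named lengths for end clipping.
#' @param upstream,downstream Extents in bp.
#' @return GRanges with a `gene_id` column.
#' @export
definePromoters <- function(genes, chrom_sizes = NULL, upstream = 1000,
                            downstream = 100) {
    if (any(!genes$strand %in% c("+", "-"))) {
        bad <- genes$gene_id[!genes$strand %in% c("+", "-")][1L]
        stop("missing or invalid strand for gene ", bad)
    }
    plus <- genes$strand == "+"
    start0 <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
    end0 <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
    start0 <- pmax(start0, 0)
    if (!is.null(chrom_sizes)) {
        end0 <- pmin(end0, chrom_sizes[genes$chrom])
    }
    gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(start0 + 1, end0),
                                 strand = genes$strand)
    gr$gene_id <- genes$gene_id
    gr
}

#' Differential accessibility test
#'
#' TMM-normalizes the peak counts and tests the contrast with the
#' quasi-likelihood framework; peaks with FDR < `fdr_cut` are the DA peaks,
#' signed by log fold change.
#'
#' @param counts Peak x sample count matrix.
#' @param design Model matrix (should include the donor coefficient when the
#'   samples are donor-paired).
#' @param contrast Coefficient name or numeric contrast.
#' @param lib.size Per-sample library sizes.
#' @param fdr_cut FDR threshold for the `status` classes.
#' @param ... Passed to [qlTest()].
#' @return [qlTest()] table plus a `status` column (up/down/unchanged).
#' @export
testDifferentialAccessibility <- function(counts, design, contrast,
                                          lib.size = colSums(counts),
                                          fdr_cut = 0.05, ...) {
    nf <- tmmFactors(counts, lib.size = lib.size)
    dtr <- estimateDispersionTrend(counts, design, lib.size = lib.size,
                                   norm.factors = nf)
    tt <- qlTest(counts, design, contrast, dispersion = dtr$dispersion,
                 lib.size = lib.size, norm.factors = nf, ...)
    tt$status <- ifelse(tt$fdr < fdr_cut,
                        ifelse(tt$logFC > 0, "up", "down"), "unchanged")
    tt
}

#' Build the gene-regulatory interaction network
#'
#' For every tested bin pair, attaches the (DA-eligible) peaks overlapping
#' one anchor and the promoters of expressed genes overlapping the other
#' anchor, in both orientations; a link requires a peak and a promoter on
#' distinct anchors. The interaction class comes from the DI result: gained
#' (FDR < 0.05, logFC > 0), lost (FDR < 0.05, logFC < 0), else unchanged.
#'
#' @param di DI table from [testDifferentialInteractions()].
#' @param peaks GRanges of peaks with `peak_id`.
#' @param da DA table (rows parallel to `peaks`) with `status`; used to
#'   restrict to DA peaks when `da_only = TRUE` and to annotate links.
#' @param promoters GRanges from [definePromoters()] (already restricted to
#'   expressed genes by the caller).
#' @param bins Genome-wide bins underlying the DI table's anchor indices.
#' @param da_only Keep only DA peaks (the default network definition).
#' @param fdr_cut DI significance threshold.
#' @return data.frame, one row per (bin pair, peak, gene) link: anchor
#'   indices, `peak_id`, `gene_id`, `class`, `peak_status`, `peak_logfc`.
#' @export
buildRegulatoryNetwork <- function(di, peaks, da, promoters, bins,
                                   da_only = TRUE, fdr_cut = 0.05) {
    bw <- max(BiocGenerics::width(bins))
    if (!is.null(attr(di, "bin_width")) && attr(di, "bin_width") != bw) {
        stop("bin width of the DI table does not match 'bins'")
    }
    pk <- peaks
    pst <- da$status
    plf <- da$logFC
    if (da_only) {
        keep <- pst != "unchanged"
        pk <- pk[keep]; pst <- pst[keep]; plf <- plf[keep]
    }
    ovp <- GenomicRanges::findOverlaps(pk, bins)
    peak_map <- data.table::data.table(
        bin = S4Vectors::subjectHits(ovp),
        peak_id = pk$peak_id[S4Vectors::queryHits(ovp)],
        peak_status = pst[S4Vectors::queryHits(ovp)],
        peak_logfc = plf[S4Vectors::queryHits(ovp)])
    ovg <- GenomicRanges::findOverlaps(promoters, bins)
    gene_map <- data.table::data.table(
        bin = S4Vectors::subjectHits(ovg),
        gene_id = promoters$gene_id[S4Vectors::queryHits(ovg)])
    dt <- data.table::data.table(row = seq_len(nrow(di)),
                                 anchor1 = di$anchor1, anchor2 = di$anchor2,
                                 p = di$p,
                                 class = ifelse(di$fdr < fdr_cut,
                                                ifelse(di$logFC > 0, "gained",
                                                       "lost"), "unchanged"))
    dt <- dt[anchor1 != anchor2]
    link1 <- merge(merge(dt, peak_map, by.x = "anchor1", by.y = "bin",
                         allow.cartesian = TRUE),
                   gene_map, by.x = "anchor2", by.y = "bin",
                   allow.cartesian = TRUE)
    link2 <- merge(merge(dt, peak_map, by.x = "anchor2", by.y = "bin",
                         allow.cartesian = TRUE),
                   gene_map, by.x = "anchor1", by.y = "bin",
                   allow.cartesian = TRUE)
    net <- unique(data.table::rbindlist(list(link1, link2), use.names = TRUE))
    data.table::setorderv(net, c("row", "peak_id", "gene_id"))
    as.data.frame(net[, c("row", "anchor1", "anchor2", "class", "p", "peak_id",
                          "peak_status", "peak_logfc", "gene_id")])
}

#' Coupling between interaction classes and expression classes
#'
#' At the interaction-gene link level, tests whether gained interactions are
#' enriched for up-regulated genes (gained-vs-rest x up-vs-rest) and lost
#' interactions for down-regulated genes, with Fisher's exact test; also
#' returns the expression-class composition of each interaction class.
#'
#' @param net Network from [buildRegulatoryNetwork()].
#' @param de DE table with `status` and rownames (or `gene_id`) identifying
#'   genes.
#' @param collapse_genes Count each (interaction class, gene) once instead
#'   of once per link.
#' @return List with `gained_up` and `lost_down` (`table` + [fisherExact2x2()]
#'   results) and `composition` (class x status fractions).
#' @export
couplingTests <- function(net, de, collapse_genes = FALSE) {
    gstat <- de$status
    names(gstat) <- if (!is.null(de$gene_id)) de$gene_id else rownames(de)
    links <- net
    if (collapse_genes) {
        links <- unique(links[c("class", "gene_id")])
    }
    st <- gstat[links$gene_id]
    mk <- function(cls, dir) {
        tab <- matrix(c(sum(links$class == cls & st == dir),
                        sum(links$class == cls & st != dir),
                        sum(links$class != cls & st == dir),
                        sum(links$class != cls & st != dir)), 2L, 2L,
                      dimnames = list(c(dir, paste0("not_", dir)),
                                      c(cls, paste0("not_", cls))))
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
            return(list(table = tab, odds_ratio = NA_real_, p = NA_real_,
                        degenerate = TRUE))
        }
        c(list(table = tab, degenerate = FALSE), fisherExact2x2(t(tab)))
    }
    comp <- prop.table(table(links$class, factor(st, levels = c("up", "down",
                                                                "unchanged"))),
                       margin = 1L)
    list(gained_up = mk("gained", "up"), lost_down = mk("lost", "down"),
         composition = comp)
}

#' Accessibility change by interaction class
#'
#' Distribution of peak accessibility logFC per interaction class, compared
#' pairwise (gained vs lost, gained vs unchanged) with the rank-sum test.
#' The default unit is the network link (one observation per
#' interaction-peak-gene link); `unit = "peak"` collapses to one observation
#' per peak, classified by its most significant interaction.
#'
#' @param net Network from [buildRegulatoryNetwork()].
#' @param unit `"link"` (default) or `"peak"`.
#' @return List with `values` (per-class numeric vectors) and `tests`.
#' @export
accessibilityByInteractionClass <- function(net, unit = c("link", "peak")) {
    unit <- match.arg(unit)
    classes <- c("gained", "lost", "unchanged")
    if (unit == "peak") {
        o <- order(net$peak_id, net$p)
        first <- !duplicated(net$peak_id[o])
        cls <- net$class[o][first]
        lfc <- net$peak_logfc[o][first]
        vals <- lapply(classes, function(k) lfc[cls == k])
    } else {
        vals <- lapply(classes, function(cl) net$peak_logfc[net$class == cl])
    }
    names(vals) <- classes
    cmp <- list(c("gained", "lost"), c("gained", "unchanged"))
    tests <- do.call(rbind, lapply(cmp, function(pr) {
        x <- vals[[pr[1L]]]; y <- vals[[pr[2L]]]
        if (!length(x) || !length(y)) {
            return(data.frame(class1 = pr[1L], class2 = pr[2L], p = NA_real_))
        }
        data.frame(class1 = pr[1L], class2 = pr[2L],
                   p = wilcoxonRankSum(x, y)$p)
    }))
    list(values = vals, tests = tests)
}

#' eRNA analysis over non-exonic peaks
#'
#' RNA read counts summarised over non-exonic ATAC peaks are filtered at
#' CPM > 0.5 in at least 2 samples against fixed library sizes (the total
#' genome-aligned reads per sample), TMM-normalized and tested with the
#' precision-weighted moderated-t linear model; eRNA logFC is then compared
#' between peaks that gained vs lost accessibility.
#'
#' @param counts RNA counts over peaks (peak x sample).
#' @param peaks GRanges of the same peaks (with `peak_id`).
#' @param exons GRanges of annotated exons; any overlap is an error (the
#'   peaks must be pre-filtered to non-exonic).
#' @param aligned_totals Per-sample total genome-aligned reads (the fixed
#'   library sizes).
#' @param design,contrast Model matrix and tested contrast.
#' @param da DA table (rows parallel to `peaks`) with `status`.
#' @param cpm_threshold,min_samples Expression filter.
#' @return List with `table` (moderated-t results for expressed eRNAs,
#'   including the peak's DA `status`) and `comparison` (gained vs lost
#'   rank-sum test on eRNA logFC).
#' @export
ernaAnalysis <- function(counts, peaks, exons, aligned_totals, design,
                         contrast, da, cpm_threshold = 0.5, min_samples = 2L) {
    if (any(IRanges::overlapsAny(peaks, exons))) {
        stop("exon-overlapping peak passed to the eRNA analysis")
    }
    keep <- cpmFilter(counts, threshold = cpm_threshold,
                      min_samples = min_samples, fixed_lib = aligned_totals)
    cnt <- counts[keep, , drop = FALSE]
    nf <- tmmFactors(cnt, lib.size = aligned_totals)
    tt <- voomModeratedTest(cnt, design, contrast, lib.size = aligned_totals,
                            norm.factors = nf)
    tt$status <- da$status[keep]
    g <- tt$logFC[tt$status == "up"]
    l <- tt$logFC[tt$status == "down"]
    comparison <- if (length(g) && length(l)) {
        c(list(n_gained = length(g), n_lost = length(l),
               median_gained = median(g), median_lost = median(l)),
          wilcoxonRankSum(g, l))
    } else list(n_gained = length(g), n_lost = length(l), W = NA, p = NA)
    list(table = tt, comparison = comparison)
}
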