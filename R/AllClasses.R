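#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats approx approxfun ave cor dnbinom dnorm dpois ecdf lowess
#'   mad median model.matrix p.adjust pchisq pf pnorm prop.table pt qf qnorm
#'   quantile rlnorm rnbinom rnorm rpois runif sd setNames t.test var
#'   fisher.test wilcox.test
#' @importFrom utils head tail
NULL

# data.table syntax (.N, :=) is used through data.table:: calls
.datatable.aware <- TRUE

#' BinPairs: intra-chromosomal bin-pair counts across samples
#'
#' An S4 container extending [SummarizedExperiment::SummarizedExperiment] for
#' Hi-C read-pair counts aggregated into pairs of fixed-width genomic bins.
#' Rows are bin pairs (anchor1 <= anchor2, both on the same chromosome, bin
#' indices referring to the genome-wide bin table in `binGrid()`), columns are
#' samples. The `counts` assay holds non-negative integers; `colData` carries
#' `lib.size` (total input read pairs per sample, intra- plus
#' inter-chromosomal) and any sample covariates; `metadata(x)$inter` records
#' the per-sample count of inter-chromosomal read pairs routed to the
#' background-ligation pool rather than to the table.
#'
#' @slot bins A [GenomicRanges::GRanges] of genome-wide bins (the coordinate
#'   system for the `anchor1`/`anchor2` indices in `rowData`).
#' @aliases BinPairs-class
#' @export
setClass("BinPairs",
    contains = "SummarizedExperiment",
    slots = c(bins = "GRanges"))

setValidity("BinPairs", function(object) {
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("anchor1", "anchor2") %in% colnames(rd))) {
        return("rowData must contain 'anchor1' and 'anchor2' bin indices")
    }
    a1 <- rd$anchor1; a2 <- rd$anchor2
    nb <- length(object@bins)
    if (length(a1) && (min(a1) < 1L || max(a2) > nb)) {
        return("anchor indices outside the bin table")
    }
    if (any(a1 > a2)) return("anchor1 must be <= anchor2")
    ch <- as.character(GenomeInfoDb::seqnames(object@bins))
    if (length(a1) && any(ch[a1] != ch[a2])) {
        return("bin pairs must be intra-chromosomal")
    }
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) return("counts must be non-negative")
    if (!"lib.size" %in% colnames(SummarizedExperiment::colData(object))) {
        return("colData must contain 'lib.size'")
    }
    TRUE
})

#' Construct a BinPairs object
#'
#' @param counts Integer matrix, bin pairs x samples.
#' @param anchor1,anchor2 Integer bin indices (`anchor1 <= anchor2`) into
#'   `bins`.
#' @param bins Genome-wide bin [GenomicRanges::GRanges] from [makeBins()].
#' @param lib.size Per-sample total read-pair counts. Defaults to column sums.
#' @param inter Per-sample inter-chromosomal read-pair counts (default 0).
#' @param colData Optional data.frame of sample covariates.
#' @return A [BinPairs-class] object with a `gap` rowData column holding the
#'   anchor mid-point distance in bp.
#' @export
BinPairs <- function(counts, anchor1, anchor2, bins, lib.size = NULL,
                     inter = NULL, colData = NULL) {
    counts <- as.matrix(counts)
    if (is.null(colnames(counts))) {
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    }
    if (is.null(lib.size)) lib.size <- colSums(counts)
    if (is.null(inter)) inter <- rep(0, ncol(counts))
    mid <- (BiocGenerics::start(bins) + BiocGenerics::end(bins)) / 2
    cd <- S4Vectors::DataFrame(lib.size = as.numeric(lib.size),
                               row.names = colnames(counts))
    if (!is.null(colData)) {
        cd <- cbind(cd, S4Vectors::DataFrame(colData))
    }
    rd <- S4Vectors::DataFrame(anchor1 = as.integer(anchor1),
                               anchor2 = as.integer(anchor2),
                               gap = abs(mid[anchor2] - mid[anchor1]))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowData = rd, colData = cd,
        metadata = list(inter = setNames(as.numeric(inter), colnames(counts))))
    new("BinPairs", se, bins = bins)
}

#' @describeIn BinPairs The genome-wide bin table underlying the anchors.
#' @param x A `BinPairs` object.
#' @export
binGrid <- function(x) x@bins

#' @describeIn BinPairs Anchor regions as GRanges (`which` = 1 or 2).
#' @param which Anchor to extract (1 or 2).
#' @export
anchors <- function(x, which = 1) {
    idx <- SummarizedExperiment::rowData(x)[[paste0("anchor", which)]]
    x@bins[idx]
}

#' @describeIn BinPairs Per-sample inter-chromosomal read-pair totals.
#' @export
interCounts <- function(x) S4Vectors::metadata(x)$inter

#' @describeIn BinPairs Anchor mid-point distances (bp).
#' @export
pairGaps <- function(x) SummarizedExperiment::rowData(x)$gap

setMethod("show", "BinPairs", function(object) {
    ch <- unique(as.character(GenomeInfoDb::seqnames(object@bins)))
    cat("BinPairs with", nrow(object), "bin pairs x", ncol(object),
        "samples\n")
    cat("  bins:", length(object@bins), "bins on",
        length(ch), "chromosomes (width ~",
        round(median(BiocGenerics::width(object@bins))), "bp)\n")
    cat("  lib.size:", paste(format(SummarizedExperiment::colData(object)$lib.size,
                                    big.mark = ","), collapse = ", "), "\n")
    inter <- interCounts(object)
    if (!is.null(inter)) {
        cat("  inter-chromosomal pool:",
            paste(format(inter, big.mark = ","), collapse = ", "), "\n")
    }
})

#' TADSet: a per-condition domain segmentation
#'
#' Holds the called TADs (non-overlapping, sorted GRanges covering each
#' chromosome) and the boundary regions between consecutive TADs (one
#' bin-width region, by convention the first bin of the downstream TAD).
#'
#' @slot tads GRanges of domains.
#' @slot boundaries GRanges of boundary regions.
#' @slot condition Character label.
#' @aliases TADSet-class
#' @export
setClass("TADSet", slots = c(tads = "GRanges", boundaries = "GRanges",
                             condition = "character"))

setValidity("TADSet", function(object) {
    t <- object@tads
    if (length(t) > 1L) {
        sp <- split(t, GenomeInfoDb::seqnames(t))
        for (g in sp) {
            if (length(g) < 2L) next
            if (is.unsorted(BiocGenerics::start(g))) return("TADs must be sorted")
            if (any(BiocGenerics::start(g)[-1L] <=
                    BiocGenerics::end(g)[-length(g)] - 0L &
                    BiocGenerics::start(g)[-1L] <= BiocGenerics::end(g)[-length(g)])) {
                return("TADs must not overlap")
            }
        }
    }
    TRUE
})

#' Construct a TADSet
#' @param tads,boundaries GRanges.
#' @param condition Character label for the condition the segmentation
#'   belongs to.
#' @export
TADSet <- function(tads, boundaries, condition = "unspecified") {
    new("TADSet", tads = tads, boundaries = boundaries, condition = condition)
}

#' @describeIn TADSet Domains.
#' @param x A `TADSet`.
#' @export
tads <- function(x) x@tads

#' @describeIn TADSet Boundary regions.
#' @export
boundaries <- function(x) x@boundaries

setMethod("show", "TADSet", function(object) {
    cat("TADSet (", object@condition, "): ", length(object@tads), " TADs, ",
        length(object@boundaries), " boundaries; mean size ",
        round(mean(BiocGenerics::width(object@tads)) / 1e6, 2), " Mb\n",
        sep = "")
})
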