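#' Partition a genome into fixed-width bins
#'
#' Tiles every chromosome with contiguous, non-overlapping bins of `width`
#' base pairs; the terminal bin of each chromosome is truncated at the
#' chromosome end. Bin order (and therefore the integer bin index used by all
#' bin-pair machinery) follows the order of `chrom_sizes`, with no karyotype
#' re-sorting, so results are deterministic for any genome naming scheme.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param width Bin width in bp.
#' @return A [GenomicRanges::GRanges] with one range per bin, `seqlengths`
#'   set, in genome order. The bin index of a bin is its position in this
#'   object.
#' @examples
#' makeBins(c(chr1 = 100000), width = 25000)
#' @export
makeBins <- function(chrom_sizes, width) {
    if (length(chrom_sizes) == 0L) stop("no chromosomes")
    if (is.null(names(chrom_sizes)) || anyNA(names(chrom_sizes)) ||
        any(names(chrom_sizes) == "")) {
        stop("'chrom_sizes' must be a named vector of chromosome lengths")
    }
    if (!(width > 0)) stop("'width' must be a positive number of base pairs")
    if (any(chrom_sizes <= 0)) stop("all chromosome lengths must be > 0")
    sl <- setNames(as.integer(chrom_sizes), names(chrom_sizes))
    bins <- GenomicRanges::tileGenome(sl, tilewidth = as.integer(width),
                                      cut.last.tile.in.chrom = TRUE)
    bins
}

#' Reciprocal overlap between two regions
#'
#' Computes `min(|a intersect b| / |a|, |a intersect b| / |b|)`, the symmetric
#' overlap fraction used to decide whether two TADs "intersect" (the analysis
#' calls two domains intersecting when this exceeds 0.75). Vectorised over
#' parallel ranges.
#'
#' @param a,b [GenomicRanges::GRanges] of equal length (or length 1, recycled).
#' @return Numeric vector of fractions in `[0, 1]`; 0 for regions on different
#'   chromosomes or with empty intersection.
#' @export
reciprocalOverlap <- function(a, b) {
    if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
    if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
    if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
    wa <- BiocGenerics::width(a)
    wb <- BiocGenerics::width(b)
    if (any(wa < 1L) || any(wb < 1L)) stop("zero-length region")
    same <- as.character(GenomeInfoDb::seqnames(a)) ==
        as.character(GenomeInfoDb::seqnames(b))
    inter <- pmin(BiocGenerics::end(a), BiocGenerics::end(b)) -
        pmax(BiocGenerics::start(a), BiocGenerics::start(b)) + 1L
    inter <- pmax(inter, 0L)
    inter[!same] <- 0L
    pmin(inter / wa, inter / wb)
}

#' Overlap query between two region sets
#'
#' Returns, for every query region, the indices of subject regions it overlaps
#' (non-empty intersection under half-open disk coordinates, i.e. shared
#' bases). A thin wrapper around [GenomicRanges::findOverlaps()] that preserves
#' query order and returns a plain list, convenient for brute-force
#' cross-checking.
#'
#' @param query,subject [GenomicRanges::GRanges].
#' @return List (length = `length(query)`) of integer vectors of subject
#'   indices, each sorted increasingly; empty integer vector where there is no
#'   overlap.
#' @export
overlapQuery <- function(query, subject) {
    if (length(query) == 0L) return(list())
    ov <- GenomicRanges::findOverlaps(query, subject)
    hits <- split(S4Vectors::subjectHits(ov),
                  factor(S4Vectors::queryHits(ov), levels = seq_along(query)))
    lapply(hits, function(x) sort(as.integer(x)))
}

.stop_line <- function(path, i, msg) {
    stop(sprintf("%s: line %d: %s", path, i, msg), call. = FALSE)
}

#' Read and write BED regions
#'
#' BED files are 0-based half-open on disk; in memory regions are GRanges
#' (1-based closed), converted at this boundary. Columns beyond chrom, start,
#' end are interpreted as name, score, strand when present.
#'
#' @param path File path.
#' @param regions A [GenomicRanges::GRanges], optionally with `name` and
#'   `score` metadata columns.
#' @return `readBed` returns a GRanges with any `name`/`score` columns.
#' @export
readBed <- function(path) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = list(character = 1))
    if (ncol(dt) < 3L) stop(sprintf("%s: expected at least 3 BED columns", path))
    start0 <- suppressWarnings(as.numeric(dt[[2L]]))
    end0 <- suppressWarnings(as.numeric(dt[[3L]]))
    bad <- which(is.na(start0) | is.na(end0))
    if (length(bad)) .stop_line(path, bad[1L], "non-numeric start/end")
    bad <- which(start0 >= end0)
    if (length(bad)) .stop_line(path, bad[1L], "start >= end")
    strand <- if (ncol(dt) >= 6L) dt[[6L]] else "*"
    gr <- GenomicRanges::GRanges(dt[[1L]],
                                 IRanges::IRanges(start0 + 1, end0),
                                 strand = strand)
    if (ncol(dt) >= 4L) gr$name <- as.character(dt[[4L]])
    if (ncol(dt) >= 5L) gr$score <- suppressWarnings(as.numeric(dt[[5L]]))
    gr
}

#' @rdname readBed
#' @export
writeBed <- function(regions, path) {
    dt <- data.table::data.table(
        chrom = as.character(GenomeInfoDb::seqnames(regions)),
        start = BiocGenerics::start(regions) - 1L,
        end = BiocGenerics::end(regions))
    has_strand <- any(as.character(BiocGenerics::strand(regions)) != "*")
    if (!is.null(regions$name) || !is.null(regions$score) || has_strand) {
        dt$name <- if (is.null(regions$name)) "." else regions$name
    }
    if (!is.null(regions$score) || has_strand) {
        dt$score <- if (is.null(regions$score)) 0 else regions$score
    }
    if (has_strand) {
        st <- as.character(BiocGenerics::strand(regions))
        st[st == "*"] <- "."
        dt$strand <- st
    }
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Read and write BEDPE anchor pairs
#'
#' BEDPE carries two genomic anchors per record plus optional name/score and
#' any number of extra columns (a header line is written and expected for the
#' extra columns to survive a round trip). On-disk coordinates are 0-based
#' half-open; the returned table holds 1-based closed coordinates.
#'
#' @param path File path.
#' @param pairs A data.frame with columns `chrom1,start1,end1,chrom2,start2,
#'   end2` (1-based closed) plus any extra columns.
#' @return `readBedpe` returns a data.frame.
#' @export
readBedpe <- function(path) {
    first <- readLines(path, n = 1L)
    header <- grepl("^#?chrom1\t", first)
    dt <- data.table::fread(path, header = header, sep = "\t")
    if (ncol(dt) < 6L) stop(sprintf("%s: expected at least 6 BEDPE columns", path))
    if (!header) {
        base <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
        extra <- c("name", "score")
        nm <- c(base, extra, paste0("V", seq_len(max(0L, ncol(dt) - 8L))))
        data.table::setnames(dt, nm[seq_len(ncol(dt))])
    } else {
        data.table::setnames(dt, 1L, sub("^#", "", names(dt)[1L]))
    }
    for (j in c(2L, 3L, 5L, 6L)) {
        bad <- which(is.na(suppressWarnings(as.numeric(dt[[j]]))))
        if (length(bad)) .stop_line(path, bad[1L] + as.integer(header),
                                    "non-numeric coordinate")
    }
    bad <- which(dt$start1 >= dt$end1 | dt$start2 >= dt$end2)
    if (length(bad)) .stop_line(path, bad[1L] + as.integer(header), "start >= end")
    dt$start1 <- dt$start1 + 1L
    dt$start2 <- dt$start2 + 1L
    as.data.frame(dt)
}

#' @rdname readBedpe
#' @export
writeBedpe <- function(pairs, path) {
    need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
    if (!all(need %in% names(pairs))) {
        stop("'pairs' must have columns ", paste(need, collapse = ", "))
    }
    out <- data.table::as.data.table(pairs)
    out$start1 <- out$start1 - 1L
    out$start2 <- out$start2 - 1L
    data.table::setcolorder(out, c(need, setdiff(names(out), need)))
    data.table::setnames(out, 1L, "#chrom1")
    data.table::fwrite(out, path, sep = "\t", col.names = TRUE)
    invisible(path)
}

#' Read and write gene annotation tables
#'
#' Tab-separated with header columns `gene_id`, `chrom`, `tss`, `strand`
#' (TSS is a 0-based position, matching the BED dialect on disk) and optional
#' extra columns such as `exon_start`/`exon_end`.
#'
#' @param path File path.
#' @param genes A data.frame with at least the four required columns.
#' @export
readGeneTable <- function(path) {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% names(dt))) {
        stop(sprintf("%s: gene table needs columns %s", path,
                     paste(need, collapse = ", ")))
    }
    if (anyDuplicated(dt$gene_id)) stop(sprintf("%s: duplicated gene_id", path))
    as.data.frame(dt)
}

#' @rdname readGeneTable
#' @export
writeGeneTable <- function(genes, path) {
    data.table::fwrite(data.table::as.data.table(genes), path, sep = "\t")
    invisible(path)
}

#' Read chromosome sizes from a two-column TSV
#' @param path File path (chrom, length; no header).
#' @return Named numeric vector in file order.
#' @export
readChromSizes <- function(path) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    setNames(as.numeric(dt[[2L]]), as.character(dt[[1L]]))
}

#' Write a bedGraph track
#'
#' @param regions GRanges with a `score` metadata column.
#' @param path File path.
#' @export
writeBedGraph <- function(regions, path) {
    dt <- data.table::data.table(
        chrom = as.character(GenomeInfoDb::seqnames(regions)),
        start = BiocGenerics::start(regions) - 1L,
        end = BiocGenerics::end(regions),
        score = regions$score)
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' @rdname writeBedGraph
#' @export
readBedGraph <- function(path) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            col.names = c("chrom", "start", "end", "score"))
    gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start + 1, dt$end))
    gr$score <- dt$score
    gr
}
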