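# Independent brute-force oracles. These re-derive expected results by the
# most direct (often quadratic) method available so that the package's
# optimized implementations can be checked on random instances.

# all-pairs interval overlap under closed 1-based coordinates
brute_overlap <- function(query, subject) {
    qc <- as.character(GenomeInfoDb::seqnames(query))
    sc <- as.character(GenomeInfoDb::seqnames(subject))
    qs <- BiocGenerics::start(query); qe <- BiocGenerics::end(query)
    ss <- BiocGenerics::start(subject); se <- BiocGenerics::end(subject)
    lapply(seq_along(query), function(i) {
        which(sc == qc[i] & ss <= qe[i] & se >= qs[i])
    })
}

brute_reciprocal <- function(c1, s1, e1, c2, s2, e2) {
    # 0-based half-open arithmetic
    if (c1 != c2) return(0)
    inter <- max(0, min(e1, e2) - max(s1, s2))
    min(inter / (e1 - s1), inter / (e2 - s2))
}

brute_bh <- function(p) {
    m <- length(p)
    vapply(seq_len(m), function(i) {
        r <- rank(p, ties.method = "first")[i]
        min(1, min(m * sort(p)[r:m] / (r:m)))
    }, numeric(1))
}

brute_simes <- function(p) min(1, min(length(p) * sort(p) / seq_along(p)))

# dictionary accumulation of intra-chromosomal bin pairs
brute_bin_pairs <- function(rp, chrom_sizes, width) {
    chroms <- names(chrom_sizes)
    nb <- ceiling(chrom_sizes / width)
    off <- setNames(c(0, cumsum(nb))[seq_along(chroms)], chroms)
    env <- new.env()
    for (i in seq_len(nrow(rp))) {
        if (rp$chrom1[i] != rp$chrom2[i]) next
        b1 <- off[[rp$chrom1[i]]] + (rp$pos1[i] - 1) %/% width + 1
        b2 <- off[[rp$chrom2[i]]] + (rp$pos2[i] - 1) %/% width + 1
        k <- paste(min(b1, b2), max(b1, b2))
        env[[k]] <- (if (is.null(env[[k]])) 0 else env[[k]]) + 1
    }
    out <- sort(ls(env))
    data.frame(key = out, n = vapply(out, function(k) env[[k]], numeric(1)),
               row.names = NULL)
}

# per read pair, per region, up/down classification by definition
brute_updown <- function(rp, regions, flank) {
    nr <- length(regions)
    up <- integer(nr); down <- integer(nr)
    rch <- as.character(GenomeInfoDb::seqnames(regions))
    rs <- BiocGenerics::start(regions); re <- BiocGenerics::end(regions)
    for (i in seq_len(nrow(rp))) {
        if (rp$chrom1[i] != rp$chrom2[i]) next
        for (r in seq_len(nr)) {
            if (rp$chrom1[i] != rch[r]) next
            in1 <- rp$pos1[i] >= rs[r] && rp$pos1[i] <= re[r]
            in2 <- rp$pos2[i] >= rs[r] && rp$pos2[i] <= re[r]
            if (in1 == in2) next
            other <- if (in1) rp$pos2[i] else rp$pos1[i]
            if (other < rs[r] && other >= rs[r] - flank) up[r] <- up[r] + 1L
            if (other > re[r] && other <= re[r] + flank) down[r] <- down[r] + 1L
        }
    }
    list(up = up, down = down)
}

brute_diag_means <- function(mat) {
    n <- nrow(mat)
    vapply(0:(n - 1), function(d) {
        v <- numeric(0)
        for (i in seq_len(n - d)) v <- c(v, mat[i, i + d])
        mean(v)
    }, numeric(1))
}

# two-sided Fisher p by full hypergeometric enumeration
brute_fisher_p <- function(tab) {
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    support <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- vapply(support, function(x) {
        exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
    }, numeric(1))
    pobs <- probs[match(a, support)]
    sum(probs[probs <= pobs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumerating all group assignments
brute_wilcox_p <- function(x, y) {
    nx <- length(x); ny <- length(y)
    pooled <- c(x, y)
    r <- rank(pooled)
    wobs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    combs <- utils::combn(nx + ny, nx)
    ws <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
    mu <- nx * ny / 2
    mean(abs(ws - mu) >= abs(wobs - mu) - 1e-9)
}

# TMM by explicit sorting and trimming (independent of the package's rank
# based implementation)
brute_tmm <- function(counts, lib, ref, trimM = 0.3, trimA = 0.05) {
    f <- rep(1, ncol(counts))
    for (s in seq_len(ncol(counts))) {
        if (s == ref) next
        y <- counts[, s]; yr <- counts[, ref]
        ok <- y > 0 & yr > 0
        y <- y[ok]; yr2 <- yr[ok]
        M <- log2((y / lib[s]) / (yr2 / lib[ref]))
        A <- 0.5 * log2((y / lib[s]) * (yr2 / lib[ref]))
        w <- (lib[s] - y) / (lib[s] * y) + (lib[ref] - yr2) / (lib[ref] * yr2)
        n <- length(M)
        keepM <- order(M)[(floor(n * trimM) + 1):(n - floor(n * trimM))]
        keepA <- order(A)[(floor(n * trimA) + 1):(n - floor(n * trimA))]
        keep <- intersect(keepM, keepA)
        f[s] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
    }
    f / exp(mean(log(f)))
}

rand_regions <- function(n, chroms = c("chr1", "chr2"), maxpos = 1e6,
                         maxlen = 5e4) {
    st <- sample.int(maxpos, n, replace = TRUE)
    GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                           IRanges::IRanges(st, st + sample.int(maxlen, n,
                                                                replace = TRUE)))
}
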