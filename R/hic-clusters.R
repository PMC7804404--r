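# Aggregation of adjacent differential interactions into clusters with
# cluster-level FDR control. Significant bin pairs are connected when their
# anchor boxes touch in the two-dimensional interaction space; oversized
# connected components are split by tiling the space from the component
# corner so that no bounding box exceeds the size cap (mitigates chaining).
# The member significance threshold is chosen by a search so that the
# estimated cluster-level FDR (threshold x significant members / clusters,
# the worst case of every false-positive member forming its own cluster)
# stays at or below the target; Simes' method combines member p-values and
# BH across the combined p-values gives the reported cluster FDR.

.connectedComponents <- function(a1, a2, tol = 1L) {
    n <- length(a1)
    if (n == 0L) return(integer(0))
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    ord <- order(a1, a2)
    # neighbour search over the +-tol band in anchor1
    for (ii in seq_len(n - 1L)) {
        i <- ord[ii]
        for (jj in (ii + 1L):n) {
            j <- ord[jj]
            if (a1[j] - a1[i] > tol) break
            if (abs(a2[j] - a2[i]) <= tol) {
                ri <- find(i); rj <- find(j)
                if (ri != rj) parent[ri] <- rj
            }
        }
    }
    vapply(seq_len(n), find, integer(1))
}

#' Cluster differential interactions with cluster-level FDR control
#'
#' @param di DI table from [testDifferentialInteractions()] covering all
#'   tested bin pairs (not only significant ones).
#' @param max_size Maximum bounding-box side (bp) of a cluster.
#' @param target_fdr Cluster-level FDR target.
#' @param tol Adjacency tolerance in bins (1 = touching boxes).
#' @return List with `clusters` (data.frame: cluster id, bounding box,
#'   n_members, combined Simes p, cluster `fdr`, best member row index and
#'   p), `members` (per-member cluster assignment), and the chosen member
#'   `threshold`.
#' @export
clusterDifferentialInteractions <- function(di, max_size = 1e6,
                                            target_fdr = 0.05, tol = 1L) {
    bw <- attr(di, "bin_width")
    if (is.null(bw)) {
        bw <- max(di$end1 - di$start1 + 1)
    }
    ksplit <- max(1L, floor(max_size / bw))

    buildClusters <- function(thr) {
        sig <- which(di$fdr <= thr)
        if (!length(sig)) return(NULL)
        keys <- character(length(sig))
        for (ch in unique(di$chrom1[sig])) {
            sel <- which(di$chrom1[sig] == ch)
            a1 <- di$anchor1[sig][sel]
            a2 <- di$anchor2[sig][sel]
            comp <- .connectedComponents(a1, a2, tol = tol)
            # split oversized components by tiling from the component corner
            t1 <- (a1 - ave(a1, comp, FUN = min)) %/% ksplit
            t2 <- (a2 - ave(a2, comp, FUN = min)) %/% ksplit
            keys[sel] <- paste(ch, comp, t1, t2)
        }
        list(sig = sig, ids = as.integer(factor(keys)))
    }

    estClusterFDR <- function(thr) {
        cl <- buildClusters(thr)
        if (is.null(cl)) return(0)
        (thr * length(cl$sig)) / length(unique(cl$ids))
    }

    cand <- sort(unique(di$fdr[di$fdr <= target_fdr]))
    if (length(cand) > 50L) {
        cand <- unique(quantile(cand, probs = seq(0, 1, length.out = 50L),
                                type = 1L))
    }
    thr <- 0
    for (t in rev(cand)) {          # largest threshold meeting the target
        if (estClusterFDR(t) <= target_fdr) { thr <- t; break }
    }
    cl <- buildClusters(thr)
    if (is.null(cl)) {
        return(list(clusters = data.frame(), members = data.frame(),
                    threshold = thr))
    }
    sig <- cl$sig; ids <- cl$ids
    uid <- sort(unique(ids))
    rows <- lapply(uid, function(u) {
        m <- sig[ids == u]
        pm <- di$p[m]
        best <- m[which.min(pm)]
        data.frame(
            cluster = u, chrom = di$chrom1[m[1L]],
            start1 = min(di$start1[m]), end1 = max(di$end1[m]),
            start2 = min(di$start2[m]), end2 = max(di$end2[m]),
            n_members = length(m), p_simes = .simes(pm),
            best_row = best, best_p = min(pm),
            direction = ifelse(mean(sign(di$logFC[m])) >= 0, "gained", "lost"),
            stringsAsFactors = FALSE)
    })
    clusters <- do.call(rbind, rows)
    clusters$fdr <- bhAdjust(clusters$p_simes)
    members <- data.frame(row = sig, cluster = ids)
    list(clusters = clusters, members = members, threshold = thr)
}
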