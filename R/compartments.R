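# A/B compartments from the observed/expected contact correlation matrix:
# per-chromosome PCA (leading eigenvector), sign-oriented by an external
# open-chromatin covariate, and flip classification between conditions via
# the cross-condition correlation of each bin's O/E interaction profile.

#' Observed/expected correlation matrix of a contact map
#'
#' The expected count at distance d is the mean count over all bin pairs at
#' that distance; O/E is observed over expected (0/0 treated as missing) and
#' the result is the Pearson correlation matrix of the O/E columns over the
#' shared non-missing entries. Bins with zero coverage, or with fewer than
#' `min_pairs` informative O/E entries, are masked (NA rows/columns).
#'
#' @param mat Square symmetric contact matrix (one chromosome).
#' @param min_pairs Minimum informative O/E entries for a bin.
#' @param exclude_dist Exclude O/E entries closer than this many bins from
#'   the correlation (0 keeps everything). Masking the short range keeps the
#'   domain (TAD) signal, which lives below a few Mb, out of the
#'   compartment eigenvector.
#' @return List with `corr` (bins x bins, NA for masked), `oe` (the O/E
#'   matrix), `masked` (logical), and `degenerate` (TRUE when the O/E matrix
#'   carries no variance, e.g. the matrix equals its distance expectation).
#' @export
observedExpectedCorrelation <- function(mat, min_pairs = 10L,
                                        exclude_dist = 0L) {
    n <- nrow(mat)
    if (!is.matrix(mat) || n != ncol(mat)) stop("'mat' must be square")
    if (all(mat == 0)) stop("all-zero contact matrix")
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    expd <- vapply(0:(n - 1L), function(k) {
        mean(mat[cbind(seq_len(n - k), seq_len(n - k) + k)])
    }, numeric(1))
    E <- matrix(expd[d + 1L], n, n)
    OE <- ifelse(E > 0, mat / E, NA_real_)
    if (exclude_dist > 0L) OE[d < exclude_dist] <- NA_real_
    covered <- rowSums(mat) > 0
    OE[!covered, ] <- NA_real_
    OE[, !covered] <- NA_real_
    diag(OE) <- NA_real_
    masked <- !covered | rowSums(!is.na(OE)) < min_pairs
    OE[masked, ] <- NA_real_
    OE[, masked] <- NA_real_
    sds <- apply(OE, 2L, sd, na.rm = TRUE)
    degenerate <- all(is.na(sds) | sds < 1e-12)
    corr <- suppressWarnings(cor(OE, use = "pairwise.complete.obs"))
    corr[masked, ] <- NA_real_
    corr[, masked] <- NA_real_
    list(corr = corr, oe = OE, masked = masked, degenerate = degenerate)
}

#' Compartment scores from a contact correlation matrix
#'
#' PC1 (leading eigenvector of the correlation matrix over unmasked bins),
#' sign-oriented so that it correlates positively with the orientation
#' covariate (an open-chromatin proxy such as per-bin accessibility
#' coverage); bins with positive score are labelled A. Scores of different
#' chromosomes are not comparable.
#'
#' @param oec Result of [observedExpectedCorrelation()].
#' @param orientation Per-bin numeric covariate (same length as the matrix).
#' @return data.frame per bin: `score`, `label` ("A"/"B", NA for masked);
#'   attribute `dominance` = lambda1/lambda2 with a `weak_structure` flag
#'   when the two leading eigenvalues are close.
#' @export
compartmentScores <- function(oec, orientation) {
    corr <- oec$corr
    n <- nrow(corr)
    if (length(orientation) != n) stop("orientation must cover every bin")
    keep <- !oec$masked
    score <- rep(NA_real_, n)
    label <- rep(NA_character_, n)
    if (sum(keep) >= 3L) {
        C <- corr[keep, keep]
        C[is.na(C)] <- 0
        eig <- eigen(C, symmetric = TRUE)
        v <- eig$vectors[, 1L]
        orc <- cor(v, orientation[keep])
        if (!is.na(orc) && orc < 0) v <- -v
        score[keep] <- v
        label[keep] <- ifelse(v > 0, "A", "B")
        dominance <- eig$values[1L] / max(eig$values[2L], 1e-12)
    } else {
        dominance <- NA_real_
    }
    out <- data.frame(score = score, label = label, stringsAsFactors = FALSE)
    attr(out, "dominance") <- dominance
    attr(out, "weak_structure") <- is.na(dominance) || dominance < 1.2
    if (isTRUE(attr(out, "weak_structure"))) {
        warning("no dominant compartment structure (lambda1/lambda2 = ",
                round(dominance, 2), ")")
    }
    out
}

#' Per-chromosome compartment calling from a BinPairs object
#'
#' Inflates the (optionally sample-summed) contact matrix of every
#' chromosome, computes the O/E correlation (excluding entries closer than
#' `exclude_dist` bp, default 2 Mbp, so domain-scale structure does not
#' contaminate the eigenvector) and the oriented PC1 scores.
#'
#' @param bp A [BinPairs-class] object at compartment resolution.
#' @param orientation GRanges on the same bins with a `score` column (e.g.
#'   accessibility coverage), or a numeric vector over all bins.
#' @param samples Columns to sum (default all).
#' @param exclude_dist Distance (bp) below which O/E entries are masked.
#' @param min_pairs Passed to [observedExpectedCorrelation()].
#' @return Named list per chromosome with `oec` and `track` components.
#' @export
callCompartments <- function(bp, orientation, samples = NULL,
                             exclude_dist = 2e6, min_pairs = 10L) {
    bins <- binGrid(bp)
    bw <- max(BiocGenerics::width(bins))
    ori <- if (inherits(orientation, "GRanges")) orientation$score
           else orientation
    if (length(ori) != length(bins)) {
        stop("orientation must cover every bin")
    }
    ch_all <- as.character(GenomeInfoDb::seqnames(bins))
    out <- lapply(GenomeInfoDb::seqlevels(bins), function(ch) {
        mat <- inflateContacts(bp, ch, samples)
        oec <- observedExpectedCorrelation(mat, min_pairs = min_pairs,
                                           exclude_dist = ceiling(exclude_dist / bw))
        track <- suppressWarnings(compartmentScores(oec, ori[ch_all == ch]))
        list(oec = oec, track = track)
    })
    names(out) <- GenomeInfoDb::seqlevels(bins)
    out
}

#' Classify compartment flips between two conditions
#'
#' Per bin: the class is the label pair (A->A, B->B, A->B, B->A); the
#' correlation-profile score is the Pearson correlation between the bin's
#' O/E interaction profile in the two conditions (shared non-missing
#' entries); the flip flag requires both a label change and a negative
#' profile correlation (the conjunction; set `require_profile = FALSE` for
#' the label-only criterion).
#'
#' @param track_rest,track_act Results of [compartmentScores()] for the two
#'   conditions.
#' @param oec_rest,oec_act Matching [observedExpectedCorrelation()] results.
#' @param require_profile Require profile correlation < 0 for a flip.
#' @return data.frame per bin: `class`, `profile_cor`, `flip`.
#' @export
classifyFlips <- function(track_rest, track_act, oec_rest, oec_act,
                          require_profile = TRUE) {
    n <- nrow(track_rest)
    if (nrow(track_act) != n) stop("tracks must share the binning")
    pc <- vapply(seq_len(n), function(b) {
        x <- oec_rest$oe[b, ]
        y <- oec_act$oe[b, ]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 3L) return(NA_real_)
        suppressWarnings(cor(x[ok], y[ok]))
    }, numeric(1))
    cls <- ifelse(is.na(track_rest$label) | is.na(track_act$label),
                  NA_character_,
                  paste0(track_rest$label, "->", track_act$label))
    changed <- !is.na(cls) & track_rest$label != track_act$label
    flip <- changed & if (require_profile) !is.na(pc) & pc < 0 else TRUE
    data.frame(class = cls, profile_cor = pc, flip = flip,
               stringsAsFactors = FALSE)
}

#' Accessibility and expression across compartment-flip classes
#'
#' Splits per-bin accessibility logFC and per-gene expression logFC by the
#' flip class of the bin carrying the peak/TSS and compares classes
#' pairwise with the rank-sum test.
#'
#' @param flips data.frame from [classifyFlips()] (one row per bin of a
#'   chromosome set, in bin order).
#' @param acc_logfc Per-bin accessibility logFC (same length/order).
#' @param expr_logfc Per-gene expression logFC.
#' @param gene_bins Bin index (into `flips`) of each gene's TSS.
#' @return List with `accessibility` / `expression` per-class value lists
#'   and `tests` (pairwise Wilcoxon p per track, skipping empty classes).
#' @export
flipFeatureStats <- function(flips, acc_logfc, expr_logfc = NULL,
                             gene_bins = NULL) {
    classes <- c("A->A", "B->B", "A->B", "B->A")
    acc <- lapply(classes, function(cl) {
        acc_logfc[!is.na(flips$class) & flips$class == cl]
    })
    names(acc) <- classes
    expr <- NULL
    if (!is.null(expr_logfc)) {
        gcls <- flips$class[gene_bins]
        expr <- lapply(classes, function(cl) {
            expr_logfc[!is.na(gcls) & gcls == cl]
        })
        names(expr) <- classes
    }
    pairTest <- function(vals, track) {
        combs <- utils::combn(classes, 2L)
        do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
            x <- vals[[combs[1L, k]]]; y <- vals[[combs[2L, k]]]
            if (!length(x) || !length(y)) {
                return(data.frame(track = track, class1 = combs[1L, k],
                                  class2 = combs[2L, k], p = NA_real_,
                                  note = "empty class"))
            }
            data.frame(track = track, class1 = combs[1L, k],
                       class2 = combs[2L, k], p = wilcoxonRankSum(x, y)$p,
                       note = "")
        }))
    }
    tests <- pairTest(acc, "accessibility")
    if (!is.null(expr)) tests <- rbind(tests, pairTest(expr, "expression"))
    list(accessibility = acc, expression = expr, tests = tests)
}
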