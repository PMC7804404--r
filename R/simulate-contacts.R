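# Generative model for Hi-C read pairs. The expected intensity of an
# intra-chromosomal bin pair (i, j) factorises as
#   (|i-j|+1)^(-decay) * tad * compartment * loop,
# where tad is an enrichment (default x3) when both bins share a TAD and an
# attenuation 1/s when the pair crosses a boundary (s = the strongest crossed
# boundary; using the maximum keeps long-range counts alive so that the same
# maps carry a recoverable compartment checkerboard), compartment multiplies
# same-label pairs (default x1.5), and loops multiply rectangular anchor
# blocks. Counts are NB-distributed around depth-scaled means and expanded to
# uniformly placed read positions; inter-chromosomal background ligation
# pairs are added at a fixed expected rate per inter-chromosomal bin pair.

#' Describe a planted chromatin architecture
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param bin_width Architecture grid width (bp), default 50 kbp.
#' @param tads Named list (per chromosome) of internal boundary positions,
#'   each the 1-based bin index of the first bin of the downstream TAD.
#' @param boundary_strengths Named list parallel to `tads`; insulation
#'   attenuation factor per boundary (>= 1).
#' @param compartments Named list per chromosome of per-bin "A"/"B" labels.
#' @param loops Optional data.frame with columns `chrom`, `a1_lo`, `a1_hi`,
#'   `a2_lo`, `a2_hi` (inclusive bin-index anchor blocks, `a1_hi < a2_lo`)
#'   and `mult` (> 0).
#' @param decay_exponent Power-law contact decay exponent.
#' @param tad_enrichment Within-TAD multiplier (scalar), or a named list per
#'   chromosome of one multiplier per TAD (length = breakpoints + 1) for
#'   architectures where some domains self-interact more intensely.
#' @param tad_range Range (bp) of domain-scale structure: the TAD enrichment
#'   and boundary attenuation apply only to pairs closer than this; the
#'   compartment factor applies at every distance. Keeps insulation local,
#'   as in real contact maps, so long-range O/E carries the compartment
#'   checkerboard only.
#' @param compartment_enrichment Same-label multiplier.
#' @param nb_dispersion NB dispersion of counts (0 = Poisson).
#' @param background_rate Expected inter-chromosomal read pairs per
#'   inter-chromosomal bin pair per sample.
#' @return A validated list of class `ArchitectureSpec`.
#' @export
architectureSpec <- function(chrom_sizes, bin_width = 50000, tads,
                             boundary_strengths, compartments, loops = NULL,
                             decay_exponent = 1, tad_enrichment = 3,
                             tad_range = 3e6, compartment_enrichment = 1.5,
                             nb_dispersion = 0.05, background_rate = 1) {
    nbins <- ceiling(chrom_sizes / bin_width)
    for (ch in names(chrom_sizes)) {
        b <- tads[[ch]]
        if (is.unsorted(b, strictly = TRUE)) stop("breakpoints must be sorted")
        if (length(b) && (min(b) < 2L || max(b) > nbins[[ch]])) {
            stop("breakpoints outside chromosome: ", ch)
        }
        if (length(boundary_strengths[[ch]]) != length(b)) {
            stop("boundary_strengths must parallel tads")
        }
        if (any(boundary_strengths[[ch]] < 1)) stop("boundary strengths must be >= 1")
        if (length(compartments[[ch]]) != nbins[[ch]]) {
            stop("compartment labels must cover every bin of ", ch)
        }
        if (is.list(tad_enrichment) &&
            length(tad_enrichment[[ch]]) != length(b) + 1L) {
            stop("per-TAD enrichment must have one value per TAD on ", ch)
        }
    }
    if (!is.null(loops)) {
        if (any(loops$mult <= 0)) stop("loop multipliers must be > 0")
        if (any(loops$a1_hi >= loops$a2_lo)) stop("loop anchors must be distinct")
        if (!all(loops$chrom %in% names(chrom_sizes))) {
            stop("loop anchors must be intra-chromosomal on known chromosomes")
        }
    }
    structure(list(chrom_sizes = chrom_sizes, bin_width = bin_width,
                   nbins = nbins, tads = tads,
                   boundary_strengths = boundary_strengths,
                   compartments = compartments, loops = loops,
                   decay_exponent = decay_exponent,
                   tad_enrichment = tad_enrichment, tad_range = tad_range,
                   compartment_enrichment = compartment_enrichment,
                   nb_dispersion = nb_dispersion,
                   background_rate = background_rate),
              class = "ArchitectureSpec")
}

# Relative mean contact matrix (dense, symmetric) for one chromosome.
.contactMeans <- function(spec, chrom) {
    n <- spec$nbins[[chrom]]
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    M <- (d + 1)^(-spec$decay_exponent)
    # TAD membership and boundary attenuation
    br <- spec$tads[[chrom]]
    tad_id <- findInterval(seq_len(n) - 1L, c(0L, br - 1L))
    same_tad <- outer(tad_id, tad_id, "==")
    S <- matrix(1, n, n)
    st <- spec$boundary_strengths[[chrom]]
    for (k in seq_along(br)) {
        b <- br[k]
        S[seq_len(b - 1L), b:n] <- pmax(S[seq_len(b - 1L), b:n], st[k])
        S[b:n, seq_len(b - 1L)] <- pmax(S[b:n, seq_len(b - 1L)], st[k])
    }
    local <- d <= (spec$tad_range / spec$bin_width)
    enr <- if (is.list(spec$tad_enrichment)) {
        spec$tad_enrichment[[chrom]][tad_id]
    } else rep(spec$tad_enrichment, length(tad_id))
    ENR <- matrix(enr, n, n)  # ENR[i, j] = enrichment of bin i's TAD
    tad_factor <- ifelse(same_tad, ENR, 1) / ifelse(same_tad, 1, S)
    tad_factor[!local] <- 1
    M <- M * tad_factor
    lab <- spec$compartments[[chrom]]
    M <- M * ifelse(outer(lab, lab, "=="), spec$compartment_enrichment, 1)
    loops <- spec$loops
    if (!is.null(loops)) {
        loops <- loops[loops$chrom == chrom, , drop = FALSE]
        for (k in seq_len(nrow(loops))) {
            r1 <- loops$a1_lo[k]:loops$a1_hi[k]
            r2 <- loops$a2_lo[k]:loops$a2_hi[k]
            M[r1, r2] <- M[r1, r2] * loops$mult[k]
            M[r2, r1] <- M[r2, r1] * loops$mult[k]
        }
    }
    M
}

# Bin starts (1-based) and widths for one chromosome of a spec.
.specBins <- function(spec, chrom) {
    n <- spec$nbins[[chrom]]
    start <- (seq_len(n) - 1L) * spec$bin_width + 1L
    end <- pmin(seq_len(n) * spec$bin_width, spec$chrom_sizes[[chrom]])
    list(start = start, width = end - start + 1L)
}

#' Simulate Hi-C read pairs from a planted architecture
#'
#' Draws per-sample intra-chromosomal bin-pair counts from the architecture's
#' expected contact map (NB noise, library scaled so that the expected
#' intra-chromosomal total equals `depth * size_factor`), expands them to
#' read positions uniform within bins, and appends inter-chromosomal
#' background ligation pairs at `background_rate` expected pairs per
#' inter-chromosomal bin pair. Identical `(spec, depth, seed)` give identical
#' output.
#'
#' @param spec An [architectureSpec()].
#' @param depth Expected intra-chromosomal read pairs per sample.
#' @param seed Integer seed.
#' @param n_samples Number of samples to draw.
#' @param size_factors Per-sample depth multipliers.
#' @return A list of `data.table`s (`chrom1, pos1, chrom2, pos2`, 1-based
#'   positions), one per sample.
#' @export
simulateContactReads <- function(spec, depth, seed, n_samples = 1L,
                                 size_factors = rep(1, n_samples)) {
    if (!(depth > 0)) stop("'depth' must be > 0")
    set.seed(as.integer(seed))
    chroms <- names(spec$chrom_sizes)
    means <- lapply(chroms, function(ch) {
        M <- .contactMeans(spec, ch)
        idx <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
        list(i = idx[, 1L], j = idx[, 2L], mu = M[idx])
    })
    names(means) <- chroms
    total_rel <- sum(vapply(means, function(m) sum(m$mu), numeric(1)))
    nb <- spec$nbins
    n_inter_pairs <- (sum(nb)^2 - sum(nb^2)) / 2
    disp <- spec$nb_dispersion

    lapply(seq_len(n_samples), function(s) {
        sf <- size_factors[s]
        parts <- lapply(chroms, function(ch) {
            m <- means[[ch]]
            mu <- m$mu * (depth * sf / total_rel)
            cnt <- if (disp > 0) rnbinom(length(mu), mu = mu, size = 1 / disp)
                   else rpois(length(mu), mu)
            keep <- cnt > 0L
            if (!any(keep)) return(NULL)
            idx <- rep.int(which(keep), cnt[keep])
            bi <- .specBins(spec, ch)
            i <- m$i[idx]; j <- m$j[idx]
            data.table::data.table(
                chrom1 = ch,
                pos1 = bi$start[i] + floor(runif(length(i)) * bi$width[i]),
                chrom2 = ch,
                pos2 = bi$start[j] + floor(runif(length(j)) * bi$width[j]))
        })
        intra <- data.table::rbindlist(parts)
        if (nrow(intra) == 0L) {
            warning("depth too small: no intra-chromosomal bin pair populated")
        }
        n_inter <- rpois(1L, spec$background_rate * n_inter_pairs * sf)
        inter <- NULL
        if (n_inter > 0L && length(chroms) > 1L) {
            w <- outer(nb, nb)
            diag(w) <- 0
            pick <- sample.int(length(w), n_inter, replace = TRUE,
                               prob = as.vector(w))
            c1 <- chroms[(pick - 1L) %% length(chroms) + 1L]
            c2 <- chroms[(pick - 1L) %/% length(chroms) + 1L]
            inter <- data.table::data.table(
                chrom1 = c1,
                pos1 = 1L + floor(runif(n_inter) * spec$chrom_sizes[c1]),
                chrom2 = c2,
                pos2 = 1L + floor(runif(n_inter) * spec$chrom_sizes[c2]))
        }
        out <- data.table::rbindlist(list(intra, inter))
        # randomize end order so downstream counting cannot rely on sortedness
        swap <- runif(nrow(out)) < 0.5
        if (any(swap)) {
            tmp <- out$chrom1[swap]
            out[swap, "chrom1"] <- out$chrom2[swap]
            out[swap, "chrom2"] <- tmp
            tmp <- out$pos1[swap]
            out[swap, "pos1"] <- out$pos2[swap]
            out[swap, "pos2"] <- tmp
        }
        out[]
    })
}
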