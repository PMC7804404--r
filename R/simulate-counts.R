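# NB feature-count generator for genes, ATAC peaks and eRNA regions, with a
# condition effect on a planted subset, a donor random intercept (the batch
# effect the linear models must remove) and per-sample library sizes.

#' Describe a feature-count simulation
#'
#' @param n_features Number of features.
#' @param design data.frame with one row per sample and columns `sample`,
#'   `condition` (two levels; the second is the "activated" one), `donor`,
#'   optionally `lineage`.
#' @param lib_sizes Per-sample library sizes.
#' @param fraction_de Fraction of features with a planted condition effect.
#' @param logfc_mag Magnitude of the planted log2 fold change.
#' @param dispersion NB dispersion (> 0, or 0 for Poisson).
#' @param donor_sd SD (log2 scale) of the per-feature, per-donor random
#'   intercept; 0 disables the batch effect.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   feature baseline intensities.
#' @param coupled Optional data.frame (`feature`, `logfc`) fixing the planted
#'   effect of specific features (wired couplings); these count toward
#'   `fraction_de`.
#' @param feature_ids Optional character vector of feature identifiers.
#' @return A validated list of class `OmicsSpec`.
#' @export
omicsSpec <- function(n_features, design, lib_sizes,
                      fraction_de = 0.1, logfc_mag = 2, dispersion = 0.05,
                      donor_sd = 0.3, baseline_log_mean = log(50),
                      baseline_log_sd = 1.2, coupled = NULL,
                      feature_ids = NULL) {
    if (fraction_de < 0 || fraction_de > 1) stop("fraction_de must be in [0, 1]")
    if (dispersion < 0) stop("dispersion must be >= 0")
    if (!is.factor(design$condition)) {
        # first-appearance order, so the later-listed condition is the
        # "activated" one regardless of alphabetical order
        design$condition <- factor(design$condition,
                                   levels = unique(design$condition))
    }
    if (nlevels(design$condition) != 2L) stop("design needs exactly 2 conditions")
    if (min(table(design$condition)) < 2L) {
        stop("need at least 2 samples per condition")
    }
    if (length(lib_sizes) != nrow(design)) {
        stop("lib_sizes must match design rows")
    }
    structure(list(n_features = n_features, design = design,
                   lib_sizes = lib_sizes, fraction_de = fraction_de,
                   logfc_mag = logfc_mag, dispersion = dispersion,
                   donor_sd = donor_sd, baseline_log_mean = baseline_log_mean,
                   baseline_log_sd = baseline_log_sd, coupled = coupled,
                   feature_ids = feature_ids),
              class = "OmicsSpec")
}

#' Simulate NB feature counts with planted differential features
#'
#' Counts are drawn `NB(mean = lib * q * 2^(x_act * logFC + donor), disp)`
#' where `q` is a normalized log-normal baseline, `x_act` indicates the
#' activated condition, and `donor` is a per-feature N(0, donor_sd) intercept
#' shared by all samples of a donor. A `fraction_de` subset of features gets
#' `logFC = +-logfc_mag` (random sign, unless fixed through `coupled`).
#'
#' @param spec An [omicsSpec()].
#' @param seed Integer seed.
#' @return List with `counts` (feature x sample integer matrix), `truth`
#'   (data.frame: `feature`, `status` in up/down/null, `logfc`), and the
#'   `design`.
#' @export
simulateFeatureCounts <- function(spec, seed) {
    set.seed(as.integer(seed))
    n <- spec$n_features
    des <- spec$design
    ns <- nrow(des)
    q <- rlnorm(n, spec$baseline_log_mean, spec$baseline_log_sd)
    q <- q / sum(q)

    lfc <- numeric(n)
    if (!is.null(spec$coupled) && nrow(spec$coupled)) {
        lfc[spec$coupled$feature] <- spec$coupled$logfc
    }
    n_de <- round(spec$fraction_de * n)
    extra <- n_de - sum(lfc != 0)
    if (extra > 0) {
        free <- which(lfc == 0)
        pick <- sample(free, extra)
        lfc[pick] <- sample(c(-1, 1), extra, replace = TRUE) * spec$logfc_mag
    }
    donors <- unique(as.character(des$donor))
    dEff <- matrix(rnorm(n * length(donors), 0, spec$donor_sd), n,
                   dimnames = list(NULL, donors))
    act <- as.integer(des$condition == levels(des$condition)[2L])
    ids <- if (is.null(spec$feature_ids)) paste0("f", seq_len(n))
           else spec$feature_ids
    counts <- matrix(0L, n, ns, dimnames = list(ids, as.character(des$sample)))
    for (s in seq_len(ns)) {
        mu <- spec$lib_sizes[s] * q *
            2^(act[s] * lfc + dEff[, as.character(des$donor[s])])
        counts[, s] <- if (spec$dispersion > 0) {
            rnbinom(n, mu = mu, size = 1 / spec$dispersion)
        } else rpois(n, mu)
    }
    status <- ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "null"))
    list(counts = counts,
         truth = data.frame(feature = rownames(counts), status = status,
                            logfc = lfc, stringsAsFactors = FALSE),
         design = des)
}
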