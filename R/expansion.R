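#' @include AllClasses.R patterns.R
NULL

#' Normalize a dosage matrix for expansion testing
#'
#' Divides each species column by its per-species divisor (default 1), and,
#' when the WGD re-normalization is enabled, additionally divides the
#' configured species set by the WGD divisor. Performed before every
#' expansion test; the WGD divisor models a presumed ancestral genome that
#' has not undergone whole-genome duplication.
#'
#' @param content an [ArchitectureContent-class] or a dosage matrix.
#' @param spec a [NormalizationSpec-class].
#' @return Real-valued matrix of normalized dosages.
#' @examples
#' m <- matrix(c(6, 3), 2, 1, dimnames = list(c("a(1)", "b(1)"), "Zm"))
#' normalizeDosage(m, normalizationSpec(c(Zm = 3)))
#' @export
normalizeDosage <- function(content, spec = normalizationSpec()) {
    m <- if (is(content, "ArchitectureContent")) dosage(content) else content
    m <- m * 1.0
    div <- rep(1, ncol(m))
    names(div) <- colnames(m)
    pd <- spec@perSpeciesDivisor
    known <- names(pd) %in% colnames(m)
    div[names(pd)[known]] <- pd[known]
    if (!is.na(spec@wgdDivisor)) {
        if (!all(spec@wgdSpecies %in% colnames(m)))
            stop("wgdSpecies not present in content: ",
                 paste(setdiff(spec@wgdSpecies, colnames(m)), collapse = ", "))
        div[spec@wgdSpecies] <- div[spec@wgdSpecies] * spec@wgdDivisor
    }
    sweep(m, 2L, div, "/")
}

#' Ordered lineage pairs of a scheme
#'
#' @param scheme a [LineageScheme-class].
#' @return data.frame with columns `earlier`, `later`: all ordered pairs in
#'   scheme order (six pairs for four lineages).
#' @export
lineagePairs <- function(scheme) {
    lab <- lineageLabels(scheme)
    idx <- utils::combn(seq_along(lab), 2L)
    data.frame(earlier = lab[idx[1L, ]], later = lab[idx[2L, ]])
}

## log-dosage matrix used by all expansion statistics; zero dosage is
## excluded (NA) unless a pseudo-count is supplied
.logDosage <- function(content, normalization, pseudoCount) {
    m <- normalizeDosage(content, normalization)
    if (pseudoCount > 0) return(log(m + pseudoCount))
    m[m == 0] <- NA_real_
    log(m)
}

## Welch t from per-group counts, means and variances; positive t means
## later-lineage mean log-dosage is larger. se == 0 collapses to t = 0
## (identical means) or +-Inf (separated constant groups).
.welch <- function(n1, m1, v1, n2, m2, v2) {
    se2 <- v1 / n1 + v2 / n2
    diff <- m2 - m1
    t <- diff / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    zero <- which(is.finite(diff) & !is.na(se2) & se2 == 0)
    zeq <- zero[diff[zero] == 0]
    zne <- zero[diff[zero] != 0]
    t[zeq] <- 0
    t[zne] <- sign(diff[zne]) * Inf
    p <- 2 * stats::pt(-abs(t), df)
    p[zeq] <- 1
    p[zne] <- 0
    list(t = t, df = df, p = p)
}

## per-group moment rows for a column subset of the log matrix
.groupMoments <- function(L, cols) {
    X <- L[, cols, drop = FALSE]
    n <- rowSums(!is.na(X))
    m <- rowMeans(X, na.rm = TRUE)
    ss <- rowSums(X^2, na.rm = TRUE)
    v <- (ss - n * m^2) / (n - 1)
    v[n < 2] <- NA_real_
    v <- pmax(v, 0)                 # guard tiny negative from rounding
    list(n = n, m = m, v = v)
}

#' Lineage-pair expansion tests on log genomic dosage
#'
#' For every architecture and every ordered lineage pair, performs a Welch
#' (unequal-variance) two-sample t-test on the natural-log-transformed,
#' normalized genomic dosages, treating species within a lineage as
#' replicates. Species with zero dosage are excluded from their lineage's
#' sample (set `pseudoCount` for the log(x + c) alternative). An
#' architecture with fewer than two non-zero species in either lineage of a
#' pair is flagged untestable for that pair, never dropped. Positive `t`
#' means the later lineage has the larger mean log dosage.
#'
#' @param content an [ArchitectureContent-class].
#' @param scheme a [LineageScheme-class].
#' @param pairs data.frame of `earlier` / `later` lineage labels; defaults
#'   to all ordered pairs from [lineagePairs()].
#' @param normalization a [NormalizationSpec-class] applied before testing.
#' @param pseudoCount non-negative; when positive, log(x + pseudoCount) is
#'   used and zero-dosage species are kept in the samples.
#' @param architectures optional subset of architectures to test.
#' @return data.frame with one row per architecture x pair: `architecture`,
#'   `earlier`, `later`, `pair`, `n_earlier`, `n_later`, `t`, `df`,
#'   `p_raw`, `p_adj` (`NA` until [bootstrapAdjust()]), `direction`
#'   (`expansion` / `contraction` / `none`), `untestable`.
#' @seealso [bootstrapAdjust()], [classifyExpansion()]
#' @export
testExpansion <- function(content, scheme, pairs = lineagePairs(scheme),
                          normalization = normalizationSpec(),
                          pseudoCount = 0, architectures = NULL) {
    L <- .logDosage(content, normalization, pseudoCount)
    if (!is.null(architectures)) L <- L[architectures, , drop = FALSE]
    mem <- lineageMembers(scheme)
    out <- vector("list", nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
        e <- pairs$earlier[k]; l <- pairs$later[k]
        g1 <- .groupMoments(L, intersect(mem[[e]], colnames(L)))
        g2 <- .groupMoments(L, intersect(mem[[l]], colnames(L)))
        unt <- g1$n < 2L | g2$n < 2L
        w <- .welch(g1$n, g1$m, g1$v, g2$n, g2$m, g2$v)
        t <- w$t; df <- w$df; p <- w$p
        t[unt] <- NA_real_; df[unt] <- NA_real_; p[unt] <- NA_real_
        dir <- rep(NA_character_, nrow(L))
        dir[!unt] <- ifelse(t[!unt] > 0, "expansion",
                            ifelse(t[!unt] < 0, "contraction", "none"))
        out[[k]] <- data.frame(
            architecture = rownames(L), earlier = e, later = l,
            pair = paste0(e, "->", l),
            n_earlier = as.integer(g1$n), n_later = as.integer(g2$n),
            t = t, df = df, p_raw = p, p_adj = NA_real_,
            direction = dir, untestable = unt)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Max-T step-down bootstrap adjustment of expansion p-values
#'
#' Adjusts the per-architecture Welch p-values of [testExpansion()] for the
#' multiplicity of architectures tested simultaneously, separately within
#' each lineage pair. Under the pooled null, species labels of the two
#' lineages are resampled with replacement `B` times; the free step-down
#' max-|t| distribution (Westfall-Young) gives, for each architecture, the
#' fraction of resamples whose successive maximal |t| over the family
#' reaches the observed |t|. Monotonicity over the observed ordering is
#' enforced, and `p_adj >= p_raw` always holds.
#'
#' Two numerical safeguards make the resampled null usable at lineage
#' sample sizes of 2-5: each architecture's values are centered by their
#' own lineage mean before resampling, so genuinely expanded architectures
#' do not contaminate the null (the bootstrap-null form of Westfall-Young),
#' and both the observed and resampled statistics are moderated with a
#' variance-stabilizing offset `s0` (the family median standard error) so
#' that near-constant resampled groups cannot dominate the maximum.
#' Degenerate resamples (fewer than two usable species in a group)
#' contribute |t| = 0.
#'
#' @param results data.frame from [testExpansion()].
#' @param content the [ArchitectureContent-class] the results came from.
#' @param scheme the [LineageScheme-class] used.
#' @param B number of bootstrap resamples, at least 100.
#' @param seed integer seed; fixed for reproducibility.
#' @param normalization,pseudoCount must match the [testExpansion()] call.
#' @return `results` with the `p_adj` column filled (NA for untestable rows).
#' @export
bootstrapAdjust <- function(results, content, scheme, B = 1000L, seed = 1L,
                            normalization = normalizationSpec(),
                            pseudoCount = 0) {
    if (!is.numeric(B) || length(B) != 1L || B < 100)
        stop("B must be at least 100")
    B <- as.integer(B)
    set.seed(as.integer(seed))
    L <- .logDosage(content, normalization, pseudoCount)
    mem <- lineageMembers(scheme)
    for (pr in unique(results$pair)) {
        rows <- which(results$pair == pr & !results$untestable)
        if (!length(rows)) next
        e <- results$earlier[rows[1L]]; l <- results$later[rows[1L]]
        fam <- results$architecture[rows]
        spE <- intersect(mem[[e]], colnames(L))
        spL <- intersect(mem[[l]], colnames(L))
        n1 <- length(spE); n2 <- length(spL)
        pool <- c(spE, spL)
        X <- L[fam, pool, drop = FALSE]
        ## moderated statistic used on both sides of the comparison: a
        ## variance-stabilizing offset s0 (the family median standard error)
        ## keeps near-zero denominators of tiny resampled groups from
        ## dominating the max-|t| distribution
        g1 <- .groupMoments(X, seq_len(n1))
        g2 <- .groupMoments(X, n1 + seq_len(n2))
        seObs <- sqrt(g1$v / g1$n + g2$v / g2$n)
        s0 <- max(stats::median(seObs, na.rm = TRUE), 1e-8)
        Tobs <- abs(g2$m - g1$m) / sqrt(seObs^2 + s0^2)
        ## enforce the pooled null: center each architecture's values by its
        ## own lineage mean so that true mean differences do not contaminate
        ## the resampled max-|t| distribution (bootstrap null of
        ## Westfall-Young); within-lineage variability is preserved
        iE <- seq_len(n1); iL <- n1 + seq_len(n2)
        X[, iE] <- X[, iE, drop = FALSE] -
            rowMeans(X[, iE, drop = FALSE], na.rm = TRUE)
        X[, iL] <- X[, iL, drop = FALSE] -
            rowMeans(X[, iL, drop = FALSE], na.rm = TRUE)
        W <- !is.na(X); storage.mode(W) <- "double"
        X0 <- X; X0[is.na(X0)] <- 0
        X0sq <- X0^2
        P <- length(pool)
        draws <- matrix(sample.int(P, (n1 + n2) * B, replace = TRUE),
                        n1 + n2, B)
        Z1 <- vapply(seq_len(B),
                     function(b) tabulate(draws[seq_len(n1), b], P),
                     numeric(P))
        Z2 <- vapply(seq_len(B),
                     function(b) tabulate(draws[n1 + seq_len(n2), b], P),
                     numeric(P))
        tstar <- .resampledAbsT(W, X0, X0sq, Z1, Z2, s0)
        ## free step-down: successive maxima over the family ordered by
        ## decreasing observed |t|
        ord <- order(Tobs, decreasing = TRUE)
        nT <- length(ord)
        U <- tstar[ord[nT:1L], , drop = FALSE]
        U <- apply(U, 2L, cummax)
        if (is.null(dim(U))) U <- matrix(U, nrow = 1L)
        U <- U[nT:1L, , drop = FALSE]
        padj <- rowMeans(U >= rep(Tobs[ord], B))
        padj <- cummax(padj)                       # monotone in the ordering
        padj_full <- numeric(nT)
        padj_full[ord] <- padj
        padj_full <- pmin(1, pmax(padj_full, results$p_raw[rows]))
        results$p_adj[rows] <- padj_full
    }
    results
}

## abs moderated Welch t for all resamples at once via moment matrix products
.resampledAbsT <- function(W, X0, X0sq, Z1, Z2, s0) {
    C1 <- W %*% Z1; C2 <- W %*% Z2
    S1 <- X0 %*% Z1; S2 <- X0 %*% Z2
    Q1 <- X0sq %*% Z1; Q2 <- X0sq %*% Z2
    m1 <- S1 / C1; m2 <- S2 / C2
    v1 <- pmax((Q1 - C1 * m1^2) / (C1 - 1), 0)
    v2 <- pmax((Q2 - C2 * m2^2) / (C2 - 1), 0)
    t <- abs(m2 - m1) / sqrt(v1 / C1 + v2 / C2 + s0^2)
    t[C1 < 2 | C2 < 2] <- 0       # degenerate resample: uninformative
    t
}

#' Classify per-architecture expansion over all lineage pairs
#'
#' Reduces adjusted pairwise test results to one row per architecture: a
#' logical flag per lineage pair (significant expansion: `p_adj <= alpha`
#' and later mean above earlier) and a human-readable class label that is a
#' pure function of the flag combination. An architecture with at least one
#' significant pair counts as showing a trend of expansion.
#'
#' @param results data.frame from [bootstrapAdjust()] (a filled `p_adj`
#'   column is required; raw p-values are not used for flags).
#' @param alpha significance level, canonically 0.01 or 0.05.
#' @return data.frame with one row per architecture: `architecture`, one
#'   logical column per pair, `n_significant` and `label`. The `alpha` used
#'   is attached as an attribute.
#' @export
classifyExpansion <- function(results, alpha = 0.01) {
    stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
    if (all(is.na(results$p_adj)) && any(!results$untestable))
        stop("results carry no adjusted p-values; run bootstrapAdjust() first")
    pairsU <- unique(results$pair)
    archs <- unique(results$architecture)
    sig <- !results$untestable & !is.na(results$p_adj) &
        results$p_adj <= alpha & results$direction == "expansion"
    flags <- matrix(FALSE, length(archs), length(pairsU),
                    dimnames = list(archs, pairsU))
    flags[cbind(match(results$architecture, archs),
                match(results$pair, pairsU))] <- sig
    labels <- apply(flags, 1L, .expansionLabel)
    out <- data.frame(architecture = archs, flags,
                      n_significant = rowSums(flags),
                      label = labels, check.names = FALSE)
    rownames(out) <- NULL
    attr(out, "alpha") <- alpha
    out
}

## fixed lookup for the named flag combinations; generic fallback
.expansionLabel <- function(flags) {
    sig <- names(flags)[flags]
    if (!length(sig)) return("no expansion")
    key <- paste(sort(sig), collapse = "+")
    named <- c(
        "A->B+A->C+A->D" = "expanded from algal into all land lineages",
        "A->B" = "expanded from algal into early-diverging only",
        "B->C" = "expanded from early-diverging into monocot only",
        "B->D" = "expanded from early-diverging into dicot only",
        "B->C+B->D" = "expanded from early-diverging into monocot and dicot",
        "A->C+A->D" = "expanded in monocot and dicot",
        "A->C" = "expanded in monocot only",
        "A->D" = "expanded in dicot only")
    if (key %in% names(named)) unname(named[key])
    else paste("expanded:", paste(sig, collapse = ", "))
}

#' Dosage-constrained architecture sets
#'
#' Identifies architectures whose copy numbers stayed constrained despite
#' whole-genome duplications: `low_dosage` architectures have unnormalized
#' dosage of at most `maxDosage` (default 2) in every species, and
#' `single_copy_land` architectures are the subset that is additionally
#' present at exactly one copy in every land-plant species (all lineages
#' after the first by default).
#'
#' @param content an [ArchitectureContent-class] (raw integer dosages).
#' @param scheme a [LineageScheme-class].
#' @param maxDosage low-dosage ceiling (default 2).
#' @param landLineages lineage labels defining the land plants; defaults to
#'   every lineage except the first (algal).
#' @return List with character vectors `low_dosage` and `single_copy_land`
#'   (the latter is always a subset of the former).
#' @export
constrainedArchitectures <- function(content, scheme, maxDosage = 2L,
                                     landLineages = lineageLabels(scheme)[-1L]) {
    d <- dosage(content)
    low <- rowSums(d > maxDosage) == 0L
    landSp <- unlist(lineageMembers(scheme)[landLineages], use.names = FALSE)
    landSp <- intersect(landSp, colnames(d))
    single <- low & rowSums(d[, landSp, drop = FALSE] != 1L) == 0L
    list(low_dosage = rownames(d)[low],
         single_copy_land = rownames(d)[single])
}
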