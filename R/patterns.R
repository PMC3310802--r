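#' @include AllClasses.R
NULL

#' All non-empty lineage patterns in canonical order
#'
#' @param labels ordered lineage labels (single characters).
#' @return Character vector of all non-empty label subsets, concatenated in
#'   scheme order, ordered by subset size then position (for four lineages:
#'   A, B, C, D, AB, ..., ABCD; 15 patterns).
#' @examples
#' allPatterns(c("A", "B", "C", "D"))
#' @export
allPatterns <- function(labels) {
    unlist(lapply(seq_along(labels), function(k)
        apply(utils::combn(labels, k), 2L, paste, collapse = "")))
}

#' Concatenate majority-present lineages into a pattern label
#'
#' @param majority logical vector (or matrix, one row per architecture) of
#'   per-lineage majority presence, in scheme order.
#' @param labels ordered lineage labels.
#' @return Pattern label(s), e.g. `"BCD"`. An all-`FALSE` vector is a
#'   contract violation (only prevalent architectures have patterns) and
#'   raises an error.
#' @examples
#' classifyPattern(c(FALSE, TRUE, TRUE, TRUE), c("A", "B", "C", "D"))
#' @export
classifyPattern <- function(majority, labels) {
    if (is.matrix(majority)) {
        if (any(rowSums(majority) == 0L))
            stop("pattern undefined: no lineage is majority-present")
        return(apply(majority, 1L, function(r) paste(labels[r], collapse = "")))
    }
    if (!any(majority)) stop("pattern undefined: no lineage is majority-present")
    paste(labels[majority], collapse = "")
}

#' Split architectures into species-specific and shared sets
#'
#' @param content an [ArchitectureContent-class].
#' @return List with character vectors `species_specific` (architectures
#'   with positive dosage in exactly one species) and `shared` (all others);
#'   the two sets partition the architectures.
#' @export
splitSpeciesSpecific <- function(content) {
    d <- dosage(content)
    ss <- rowSums(d > 0) == 1L
    list(species_specific = rownames(d)[ss], shared = rownames(d)[!ss])
}

#' Assign every architecture to a lineage presence/absence pattern
#'
#' For each architecture the per-lineage species presence counts and
#' majority flags are computed under the scheme's thresholds, and the
#' architecture is classified as `species_specific` (present in exactly one
#' species), `prevalent`, or `removed_less_common`. Under the default
#' `"strict"` prevalence rule a shared architecture is prevalent only if the
#' majority threshold is met in *every* lineage where it occurs at all, so
#' an architecture carried by a single outlier species of one lineage is
#' removed rather than re-patterned. The alternative `"majority"` rule keeps
#' any shared architecture that is majority-present somewhere and patterns
#' it on its majority lineages only.
#'
#' @param content an [ArchitectureContent-class].
#' @param scheme a [LineageScheme-class] covering all species of `content`.
#' @param prevalence `"strict"` (default) or `"majority"`; see Details.
#' @return A [S4Vectors::DataFrame] with one row per architecture:
#'   `architecture`, per-lineage presence counts (`presence_<L>`), majority
#'   flags (`majority_<L>`), `n_species`, `status` (factor with levels
#'   `species_specific`, `removed_less_common`, `prevalent`), `pattern`
#'   (majority pattern; `NA` unless prevalent) and `pattern_overall` (the
#'   raw presence pattern over lineages, defined for every architecture).
#' @seealso [summarizePatterns()], [subsetByDomain()]
#' @export
assignPatterns <- function(content, scheme,
                           prevalence = c("strict", "majority")) {
    prevalence <- match.arg(prevalence)
    d <- dosage(content)
    sp <- colnames(d)
    lab <- lineageLabels(scheme)
    mem <- lineageMembers(scheme)
    covered <- sp %in% unlist(mem, use.names = FALSE)
    if (!all(covered))
        stop("species missing from lineage scheme: ",
             paste(sp[!covered], collapse = ", "))
    P <- d > 0
    M <- vapply(lab, function(l) sp %in% mem[[l]],
                logical(length(sp)))        # species x lineage indicator
    C <- P %*% M                            # per-lineage presence counts
    storage.mode(C) <- "integer"
    thr <- lineageThresholds(scheme)[lab]
    maj <- t(t(C) >= thr)
    tot <- as.integer(rowSums(P))

    status <- rep("removed_less_common", nrow(d))
    ss <- tot == 1L
    status[ss] <- "species_specific"
    anyMaj <- rowSums(maj) > 0L
    prevOK <- if (prevalence == "strict")
        anyMaj & rowSums(C > 0L & !maj) == 0L
    else anyMaj
    status[!ss & prevOK] <- "prevalent"

    pattern <- rep(NA_character_, nrow(d))
    isPrev <- status == "prevalent"
    if (any(isPrev))
        pattern[isPrev] <- classifyPattern(maj[isPrev, , drop = FALSE], lab)
    patternOverall <- apply(C > 0L, 1L, function(r) paste(lab[r], collapse = ""))

    out <- S4Vectors::DataFrame(architecture = rownames(d))
    for (j in seq_along(lab))
        out[[paste0("presence_", lab[j])]] <- unname(C[, j])
    for (j in seq_along(lab))
        out[[paste0("majority_", lab[j])]] <- unname(maj[, j])
    out$n_species <- unname(tot)
    out$status <- factor(status, levels = c("species_specific",
                                            "removed_less_common", "prevalent"))
    out$pattern <- unname(pattern)
    out$pattern_overall <- unname(patternOverall)
    S4Vectors::metadata(out) <- list(labels = lab, prevalence = prevalence)
    out
}

#' Summarize a pattern assignment into per-pattern counts
#'
#' @param assignments output of [assignPatterns()] (or a row subset of it).
#' @return A [PatternSummary-class] with counts and shares per pattern over
#'   the prevalent architectures (shares use `n_prevalent` as denominator)
#'   and the species-specific / removed / prevalent partition totals.
#'   `n_lineage_specific` sums the single-lineage patterns.
#' @export
summarizePatterns <- function(assignments) {
    lab <- S4Vectors::metadata(assignments)$labels
    if (is.null(lab)) stop("assignments lack lineage labels metadata")
    pats <- allPatterns(lab)
    isPrev <- assignments$status == "prevalent"
    counts <- table(factor(assignments$pattern[isPrev], levels = pats))
    counts <- stats::setNames(as.integer(counts), pats)
    nPrev <- sum(counts)
    pct <- if (nPrev > 0) counts / nPrev else stats::setNames(
        numeric(length(pats)), pats)
    nss <- sum(assignments$status == "species_specific")
    nrem <- sum(assignments$status == "removed_less_common")
    totals <- c(n_total = nrow(assignments) , n_species_specific = nss,
                n_shared = nrow(assignments) - nss, n_removed = nrem,
                n_prevalent = nPrev,
                n_lineage_specific = sum(counts[lab]))
    new("PatternSummary", counts = counts, percentages = pct,
        totals = stats::setNames(as.integer(totals), names(totals)))
}

#' Pattern summary restricted to architectures containing a domain
#'
#' Recomputes the pattern summary over the subset of architectures whose
#' canonical string contains the given domain family (e.g. `"WD40"`), in
#' both the prevalent view and the overall (pre-filter, raw presence) view.
#'
#' @param assignments output of [assignPatterns()].
#' @param domainName a single domain family name.
#' @return List with `prevalent` (a [PatternSummary-class] over the subset)
#'   and `overall_counts` (named integer: raw presence-pattern counts of the
#'   subset, species-specific and removed architectures included).
#' @export
subsetByDomain <- function(assignments, domainName) {
    sel <- containsDomain(assignments$architecture, domainName)
    sub <- assignments[sel, , drop = FALSE]
    S4Vectors::metadata(sub) <- S4Vectors::metadata(assignments)
    lab <- S4Vectors::metadata(assignments)$labels
    pats <- allPatterns(lab)
    overall <- table(factor(sub$pattern_overall, levels = pats))
    list(prevalent = summarizePatterns(sub),
         overall_counts = stats::setNames(as.integer(overall), pats))
}
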