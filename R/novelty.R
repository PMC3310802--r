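#' @include patterns.R
NULL

#' Decompose an architecture set into its constituent domains
#'
#' @param architectures character vector of canonical architecture strings.
#' @param patterns optional character vector (same length) of the pattern
#'   each architecture belongs to; when given, each domain is mapped to the
#'   set of patterns in which any architecture containing it occurs.
#' @return A list of class `DomainInventory` with elements `domains`
#'   (distinct domain names across the set) and `patterns` (named list:
#'   domain -> sorted unique source patterns; empty when `patterns` is
#'   `NULL`).
#' @examples
#' domainInventory(c("A(1) B(2)", "B(1) C(1)"))$domains
#' @export
domainInventory <- function(architectures, patterns = NULL) {
    doms <- domainNames(architectures)
    all_doms <- sort(unique(unlist(doms)))
    pat <- list()
    if (!is.null(patterns)) {
        stopifnot(length(patterns) == length(architectures))
        long <- data.frame(domain = unlist(doms),
                           pattern = rep(patterns, lengths(doms)))
        pat <- lapply(split(long$pattern, long$domain),
                      function(p) sort(unique(p)))
        pat <- pat[all_doms]
    }
    structure(list(domains = all_doms, patterns = pat),
              class = "DomainInventory")
}

#' @export
print.DomainInventory <- function(x, ...) {
    cat(sprintf("DomainInventory: %d distinct domains\n", length(x$domains)))
    invisible(x)
}

#' Reference domain inventory of the early lineages
#'
#' Collects the domains of every architecture whose raw occurrence (any
#' species, prevalence filter not applied) includes at least one of the
#' reference lineages — by default the algal and early-diverging lineages.
#' A domain absent from this reference inventory is newly emerged.
#'
#' @param assignments output of [assignPatterns()].
#' @param lineages lineage labels defining the reference occurrence set
#'   (default the first two scheme lineages).
#' @param prevalentOnly restrict the reference to prevalent architectures
#'   (default `FALSE`: species-specific and less-common architectures also
#'   vouch for a domain's earlier existence).
#' @return Character vector of reference domain names.
#' @export
referenceInventory <- function(assignments,
                               lineages = S4Vectors::metadata(assignments)$labels[1:2],
                               prevalentOnly = FALSE) {
    occ <- assignments$pattern_overall
    sel <- grepl(paste0("[", paste(lineages, collapse = ""), "]"), occ)
    if (prevalentOnly) sel <- sel & assignments$status == "prevalent"
    domainInventory(assignments$architecture[sel])$domains
}

#' Classify domains as newly emerged or pre-existing
#'
#' A domain is newly emerged iff it occurs in no architecture of the
#' reference inventory (built from the lineages where earlier presence
#' counts, see [referenceInventory()]). Enlarging the reference inventory
#' can only convert newly-emerged calls to pre-existing, never the reverse.
#'
#' @param domains character vector of domain names to classify.
#' @param referenceDomains character vector of domains with earlier
#'   occurrence.
#' @return Named factor with levels `newly_emerged`, `pre_existing`.
#' @export
classifyNovelty <- function(domains, referenceDomains) {
    stats::setNames(factor(ifelse(domains %in% referenceDomains,
                                  "pre_existing", "newly_emerged"),
                           levels = c("newly_emerged", "pre_existing")),
                    domains)
}

#' Pearson chi-square goodness-of-fit test
#'
#' Tests observed category counts against expected proportions (default
#' uniform 50:50 for two categories), without continuity correction:
#' \eqn{X^2 = \sum_i (O_i - E_i)^2 / E_i} with `length(observed) - 1`
#' degrees of freedom.
#'
#' @param observed non-negative integer counts, summing to a positive total.
#' @param p expected proportions, positive and summing to 1.
#' @return An object of class `ChiSquareResult`: list with `observed`,
#'   `expected`, `statistic`, `df`, `p_value`.
#' @examples
#' gofTest(c(11, 40))   # X^2 = 16.49
#' @export
gofTest <- function(observed, p = rep(1 / length(observed), length(observed))) {
    observed <- as.numeric(observed)
    if (length(observed) < 2L) stop("need at least two categories")
    if (any(observed < 0)) stop("observed counts must be non-negative")
    if (sum(observed) <= 0) stop("observed counts must sum to a positive total")
    if (length(p) != length(observed)) stop("p must match observed in length")
    if (any(p <= 0)) stop("expected proportions must be positive")
    if (abs(sum(p) - 1) > 1e-8) stop("expected proportions must sum to 1")
    ht <- suppressWarnings(stats::chisq.test(observed, p = p))
    structure(list(observed = observed,
                   expected = sum(observed) * p,
                   statistic = unname(ht$statistic),
                   df = unname(ht$parameter),
                   p_value = unname(ht$p.value)),
              class = "ChiSquareResult")
}

#' @export
print.ChiSquareResult <- function(x, ...) {
    cat(sprintf("Chi-square GOF: X^2 = %.4g, df = %d, p = %.4g\n",
        x$statistic, x$df, x$p_value))
    cat("  observed:", paste(x$observed, collapse = ", "),
        " expected:", paste(signif(x$expected, 4), collapse = ", "), "\n")
    invisible(x)
}

#' Single- vs multi-domain novelty contingency for one lineage scope
#'
#' For the prevalent architectures of one lineage pattern (scope `"CD"`
#' angiosperm, `"C"` monocot-only or `"D"` dicot-only), splits the
#' architectures into single-domain (one domain instance) and multi-domain
#' (two or more), and tallies the distinct constituent domains of each split
#' by novelty against a reference inventory.
#'
#' @param assignments output of [assignPatterns()].
#' @param scope a pattern label (e.g. `"CD"`).
#' @param referenceDomains reference inventory, see [referenceInventory()].
#' @return A list of class `NoveltyContingency`: `scope`,
#'   `n_architectures` (named: `single`, `multi`), `counts` (named integer:
#'   `single_new`, `single_old`, `multi_new`, `multi_old`) and `domains`
#'   (list of the classified domain names per cell).
#' @export
buildContingency <- function(assignments, scope, referenceDomains) {
    sel <- !is.na(assignments$pattern) & assignments$pattern == scope &
        assignments$status == "prevalent"
    archs <- assignments$architecture[sel]
    ic <- if (length(archs)) domainInstanceCount(archs) else integer(0)
    singleDoms <- sort(unique(unlist(domainNames(archs[ic == 1L]))))
    multiDoms <- sort(unique(unlist(domainNames(archs[ic >= 2L]))))
    nv_s <- classifyNovelty(singleDoms, referenceDomains)
    nv_m <- classifyNovelty(multiDoms, referenceDomains)
    counts <- c(single_new = sum(nv_s == "newly_emerged"),
                single_old = sum(nv_s == "pre_existing"),
                multi_new = sum(nv_m == "newly_emerged"),
                multi_old = sum(nv_m == "pre_existing"))
    structure(list(scope = scope,
                   n_architectures = c(single = sum(ic == 1L),
                                       multi = sum(ic >= 2L)),
                   counts = stats::setNames(as.integer(counts), names(counts)),
                   domains = list(single = nv_s, multi = nv_m)),
              class = "NoveltyContingency")
}

#' @export
print.NoveltyContingency <- function(x, ...) {
    cat(sprintf("NoveltyContingency [%s]: %d single- / %d multi-domain architectures\n",
        x$scope, x$n_architectures[["single"]], x$n_architectures[["multi"]]))
    cat(sprintf("  single: %d newly emerged / %d pre-existing domains\n",
        x$counts[["single_new"]], x$counts[["single_old"]]))
    cat(sprintf("  multi:  %d newly emerged / %d pre-existing domains\n",
        x$counts[["multi_new"]], x$counts[["multi_old"]]))
    invisible(x)
}
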