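#' @include content.R
NULL

#' Profile the architecture content of one genome
#'
#' Computes the per-genome profile fractions: the fraction of the proteome
#' with a Pfam-predicted architecture (`frac_predicted`), the fraction of
#' the species' distinct architectures found in no other species
#' (`frac_unique`), and the fractions of the proteome whose architecture has
#' a total domain-instance count of 1, 2, 3 or >= 4 (`frac_single`,
#' `frac_double`, `frac_triple`, `frac_ge4`). Category fractions use the
#' proteome total as denominator, so they sum exactly to `frac_predicted`;
#' `frac_unique` uses the species' distinct-architecture count as
#' denominator.
#'
#' @param content an [ArchitectureContent-class].
#' @param speciesId one species present in `content`.
#' @return One-row data.frame with columns `species_id`, `frac_predicted`,
#'   `frac_unique`, `frac_single`, `frac_double`, `frac_triple`, `frac_ge4`.
#' @seealso [profileGenomes()], [summarizeAcrossGenomes()]
#' @export
profileGenome <- function(content, speciesId) {
    d <- dosage(content)
    if (!speciesId %in% colnames(d)) stop("unknown species: ", speciesId)
    nt <- nProteinsTotal(content)[[speciesId]]
    col <- d[, speciesId]
    ic <- domainInstanceCount(rownames(d))
    present <- col > 0
    uniq <- present & rowSums(d > 0) == 1L
    fracU <- if (any(present)) sum(uniq) / sum(present) else 0
    catfrac <- function(sel) sum(col[sel]) / nt
    data.frame(species_id = speciesId,
               frac_predicted = sum(col) / nt,
               frac_unique = fracU,
               frac_single = catfrac(ic == 1L),
               frac_double = catfrac(ic == 2L),
               frac_triple = catfrac(ic == 3L),
               frac_ge4 = catfrac(ic >= 4L))
}

#' Profile every genome of a multi-genome content
#'
#' @param content an [ArchitectureContent-class].
#' @return data.frame with one [profileGenome()] row per species, in column
#'   order of `content`.
#' @export
profileGenomes <- function(content) {
    out <- do.call(rbind, lapply(speciesIds(content), profileGenome,
                                 content = content))
    rownames(out) <- NULL
    out
}

#' Cross-genome summary statistics of one profile field
#'
#' @param profiles data.frame of genome profiles ([profileGenomes()] output
#'   or the bundled [referenceProfiles()]).
#' @param field name of a numeric profile column.
#' @return Named list with `min`, `max`, `median`, `mean`, `sd`, `se`, `n`.
#'   The median of an even-sized sample is the midpoint of the two central
#'   order statistics. Both the sample standard deviation and the standard
#'   error `sd/sqrt(n)` are reported, labelled as such.
#' @examples
#' summarizeAcrossGenomes(referenceProfiles(), "frac_predicted")$median
#' @export
summarizeAcrossGenomes <- function(profiles, field) {
    if (!field %in% names(profiles) || !is.numeric(profiles[[field]]))
        stop("unknown or non-numeric field: ", field)
    if (nrow(profiles) < 2L) stop("need at least two genome profiles")
    v <- profiles[[field]]
    list(min = min(v), max = max(v), median = stats::median(v),
         mean = mean(v), sd = stats::sd(v),
         se = stats::sd(v) / sqrt(length(v)), n = length(v))
}

#' Anderson-Darling composite test of normality
#'
#' Tests whether a sample is consistent with a normal distribution with
#' unknown mean and variance. The sample is standardized with its own mean
#' and standard deviation, the Anderson-Darling statistic
#' \deqn{A^2 = -n - \frac{1}{n}\sum_{i=1}^n (2i-1)\,[\ln\Phi(z_{(i)}) +
#'   \ln(1-\Phi(z_{(n+1-i)}))]}
#' is computed on the order statistics, adjusted for small samples as
#' \eqn{A^{2*} = A^2 (1 + 0.75/n + 2.25/n^2)}, and the p-value is obtained
#' from the piecewise exponential approximation of D'Agostino & Stephens
#' (1986) for the estimated-parameters case.
#'
#' @param values numeric sample, `n >= 5`, with positive variance.
#' @return An object of class `NormalityReport`: a list with elements `n`,
#'   `mean`, `sd`, `A2`, `A2_star`, `p_value` and `normal_at_05` (is the
#'   p-value above the 0.05 significance level?).
#' @details The test is invariant under affine transformations of the input,
#'   so it gives identical p-values on proportions and percentages.
#' @examples
#' andersonDarling(referenceProfiles()$frac_predicted)
#' @export
andersonDarling <- function(values) {
    x <- sort(as.numeric(values))
    n <- length(x)
    if (n < 5L) stop("need at least 5 values")
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) stop("degenerate input: zero variance")
    z <- (x - mean(x)) / s
    lp <- stats::pnorm(z, log.p = TRUE)
    lq <- stats::pnorm(-z, log.p = TRUE)     # log(1 - Phi(z))
    A2 <- -n - mean((2 * seq_len(n) - 1) * (lp + rev(lq)))
    AA <- A2 * (1 + 0.75 / n + 2.25 / n^2)
    p <- if (AA < 0.2) 1 - exp(-13.436 + 101.14 * AA - 223.73 * AA^2)
    else if (AA < 0.34) 1 - exp(-8.318 + 42.796 * AA - 59.938 * AA^2)
    else if (AA < 0.6) exp(0.9177 - 4.279 * AA - 1.38 * AA^2)
    else if (AA < 10) exp(1.2937 - 5.709 * AA + 0.0186 * AA^2)
    else 3.7e-24
    p <- min(max(p, .Machine$double.xmin), 1)
    structure(list(n = n, mean = mean(x), sd = s, A2 = A2, A2_star = AA,
                   p_value = p, normal_at_05 = p > 0.05),
              class = "NormalityReport")
}

#' @export
print.NormalityReport <- function(x, ...) {
    cat("Anderson-Darling composite normality test\n")
    cat(sprintf("  n = %d, mean = %.4g, sd = %.4g\n", x$n, x$mean, x$sd))
    cat(sprintf("  A2 = %.4f, A2* = %.4f, p = %.4g (%snormal at alpha = 0.05)\n",
        x$A2, x$A2_star, x$p_value, if (x$normal_at_05) "" else "not "))
    invisible(x)
}
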