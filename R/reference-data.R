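#' @include profile.R
NULL

#' Published reference profiles of 14 green plant proteomes
#'
#' Per-genome domain-architecture profile fractions reported for 14 green
#' plant genomes: five algae (Cr *Chlamydomonas reinhardtii*, Ol
#' *Ostreococcus lucimarinus*, Ot *O. tauri*, Cv *Chlorella vulgaris*, Vc
#' *Volvox carteri*), two early-diverging land plants (Pp *Physcomitrella
#' patens*, Sm *Selaginella moellendorffii*), three monocots (Os rice, Zm
#' maize, Sb sorghum) and four dicots (Vv grape, At *Arabidopsis thaliana*,
#' Pt poplar, Gm soybean). Fields follow [profileGenome()]: fraction of the
#' proteome with a Pfam-predicted architecture, fraction of species-unique
#' architectures, and proteome fractions in the single- / double- / triple-
#' / >=4-domain-instance categories.
#'
#' These values serve as a desk-scale reference input for the cross-genome
#' summary statistics and the normality assessment; they are not computed by
#' this package.
#'
#' @return data.frame with 14 rows and the [profileGenome()] columns.
#' @examples
#' andersonDarling(referenceProfiles()$frac_predicted)
#' @export
referenceProfiles <- function() {
    data.frame(
        species_id = c("Cr", "Ol", "Ot", "Cv", "Vc", "Pp", "Sm",
                       "Os", "Zm", "Sb", "Vv", "At", "Pt", "Gm"),
        frac_predicted = c(0.49, 0.64, 0.59, 0.59, 0.45, 0.42, 0.67,
                           0.60, 0.47, 0.64, 0.66, 0.75, 0.66, 0.66),
        frac_unique = c(0.09, 0.05, 0.06, 0.09, 0.12, 0.07, 0.09,
                        0.15, 0.15, 0.09, 0.12, 0.06, 0.12, 0.10),
        frac_single = c(0.36, 0.45, 0.41, 0.42, 0.32, 0.30, 0.46,
                        0.38, 0.35, 0.45, 0.45, 0.51, 0.48, 0.47),
        frac_double = c(0.09, 0.13, 0.12, 0.11, 0.09, 0.08, 0.12,
                        0.11, 0.08, 0.11, 0.12, 0.14, 0.12, 0.12),
        frac_triple = c(0.03, 0.05, 0.04, 0.04, 0.03, 0.03, 0.05,
                        0.06, 0.03, 0.04, 0.05, 0.05, 0.04, 0.04),
        frac_ge4 = c(0.03, 0.03, 0.03, 0.03, 0.03, 0.03, 0.06,
                     0.06, 0.02, 0.05, 0.06, 0.06, 0.04, 0.04))
}

#' Published reference counts for domain-novelty contingency tests
#'
#' Reported counts of newly-emerged versus pre-existing distinct domains
#' within the single-domain and multi-domain architectures specific to the
#' angiosperm (`CD`), monocot-only (`C`) and dicot-only (`D`) lineage
#' patterns, together with the architecture counts per split. These are the
#' inputs of the chi-square goodness-of-fit tests under a 50:50 expectation
#' (see [gofTest()]).
#'
#' @return data.frame with columns `scope`, `n_arch_single`, `n_arch_multi`,
#'   `single_new`, `single_old`, `multi_new`, `multi_old`.
#' @examples
#' rc <- noveltyReferenceCounts()
#' gofTest(c(rc$single_new[rc$scope == "C"], rc$single_old[rc$scope == "C"]))
#' @export
noveltyReferenceCounts <- function() {
    data.frame(
        scope = c("CD", "C", "D"),
        n_arch_single = c(65L, 51L, 15L),
        n_arch_multi = c(74L, 86L, 35L),
        single_new = c(33L, 11L, 12L),
        single_old = c(32L, 40L, 3L),
        multi_new = c(15L, 4L, 8L),
        multi_old = c(59L, 82L, 27L))
}
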