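test_that("dosage normalization divides per species and for WGD", {
    m <- matrix(c(6L, 3L, 4L, 2L), 2, 2,
                dimnames = list(c("a(1)", "b(1)"), c("Zm", "Pp")))
    ct <- contentFromMatrix(m)
    expect_equal(normalizeDosage(ct), m * 1.0)     # all divisors 1: unchanged
    nm <- normalizeDosage(ct, normalizationSpec(c(Zm = 3)))
    expect_equal(unname(nm[, "Zm"]), c(2, 1))
    expect_equal(unname(nm[, "Pp"]), c(4, 2))
    nw <- normalizeDosage(ct, normalizationSpec(wgdDivisor = 8, wgdSpecies = "Zm"))
    expect_equal(unname(nw[, "Zm"]), c(6, 3) / 8)
    expect_error(normalizationSpec(c(Zm = -1)), "positive")
    expect_error(normalizeDosage(ct, normalizationSpec(wgdDivisor = 8,
                                                       wgdSpecies = "nope")))
})

## content carrying one testable architecture with chosen lineage values
pairContent <- function(valuesA, valuesC) {
    m <- matrix(0L, 2, 14, dimnames = list(c("T(1)", "F(1)"), species14))
    m["T(1)", lineageMembers(scheme14)$A] <- as.integer(valuesA)
    m["T(1)", lineageMembers(scheme14)$C] <- as.integer(valuesC)
    m["F(1)", ] <- 1L
    contentFromMatrix(m)
}

test_that("Welch statistics match the frozen literal-formula oracle", {
    ct <- pairContent(c(1, 1, 2, 1, 2), c(8, 7, 9))
    res <- testExpansion(ct, scheme14)
    r <- res[res$architecture == "T(1)" & res$pair == "A->C", ]
    ## frozen from an independent hand computation of the Welch formula on
    ## the ln-transformed samples {1,1,2,1,2} vs {8,7,9}
    expect_equal(r$t, 9.7313220385, tolerance = 1e-9)
    expect_equal(r$df, 5.2455941009, tolerance = 1e-9)
    expect_equal(r$p_raw, 1.488725463e-4, tolerance = 1e-8)
    expect_equal(r$direction, "expansion")
    expect_equal(r$n_earlier, 5L)
    expect_equal(r$n_later, 3L)
})

test_that("identical lineage samples give t = 0 and p = 1", {
    ct <- pairContent(c(0, 0, 3, 3, 3), c(3, 3, 3))
    r <- testExpansion(ct, scheme14)
    r1 <- r[r$architecture == "T(1)" & r$pair == "A->C", ]
    expect_equal(r1$t, 0)
    expect_equal(r1$p_raw, 1)
    expect_equal(r1$direction, "none")
    ## zero-dosage species were excluded from the earlier sample
    expect_equal(r1$n_earlier, 3L)
})

test_that("architectures with too few carriers are flagged untestable", {
    ct <- pairContent(c(1, 0, 0, 0, 0), c(5, 5, 5))
    r <- testExpansion(ct, scheme14)
    r1 <- r[r$architecture == "T(1)" & r$pair == "A->C", ]
    expect_true(r1$untestable)
    expect_true(is.na(r1$t))
})

test_that("t statistics are invariant to a global dosage scale", {
    ct <- randomContent(41, nArch = 12L)
    r1 <- testExpansion(ct, scheme14)
    ct7 <- contentFromMatrix(dosage(ct) * 7L)
    r2 <- testExpansion(ct7, scheme14)
    expect_equal(r1$t, r2$t, tolerance = 1e-10)
    expect_equal(r1$p_raw, r2$p_raw, tolerance = 1e-10)
})

test_that("noiseless WGD duplication cancels exactly under the matching divisor", {
    set.seed(53)
    base <- sample(1:6, 30, replace = TRUE)
    m <- matrix(0L, 30, 14, dimnames = list(sprintf("W%02d(1)", 1:30), species14))
    land <- unlist(lineageMembers(scheme14)[c("B", "C", "D")])
    angio <- unlist(lineageMembers(scheme14)[c("C", "D")])
    for (sp in species14) m[, sp] <- base
    m[, angio] <- m[, angio] * 8L               # three WGD rounds, full retention
    ct <- contentFromMatrix(m)
    spec <- normalizationSpec(wgdDivisor = 8, wgdSpecies = angio)
    res <- testExpansion(ct, scheme14, normalization = spec)
    testable <- res[!res$untestable, ]
    expect_true(all(testable$t == 0))
    expect_true(all(testable$p_raw == 1))
    ## without the divisor the B->C and B->D pairs all show expansion
    res0 <- testExpansion(ct, scheme14)
    bc <- res0[res0$pair %in% c("B->C", "B->D") & !res0$untestable, ]
    expect_true(all(bc$direction == "expansion"))
})

test_that("bootstrap adjustment is monotone, reproducible and order invariant", {
    ct <- randomContent(61, nArch = 15L, zeroProb = 0.2)
    res <- testExpansion(ct, scheme14)
    expect_error(bootstrapAdjust(res, ct, scheme14, B = 50), "at least 100")
    a1 <- bootstrapAdjust(res, ct, scheme14, B = 200, seed = 9)
    a2 <- bootstrapAdjust(res, ct, scheme14, B = 200, seed = 9)
    expect_equal(a1$p_adj, a2$p_adj)           # seeded determinism
    ok <- !a1$untestable
    expect_true(all(a1$p_adj[ok] >= a1$p_raw[ok]))
    expect_true(all(a1$p_adj[ok] <= 1))
    ## row-permuted content gives the same per-architecture adjustment
    perm <- sample(nrow(dosage(ct)))
    ctp <- contentFromMatrix(dosage(ct)[perm, ])
    resp <- testExpansion(ctp, scheme14)
    ap <- bootstrapAdjust(resp, ctp, scheme14, B = 200, seed = 9)
    key <- paste(a1$architecture, a1$pair)
    keyp <- paste(ap$architecture, ap$pair)
    expect_equal(ap$p_adj[match(key, keyp)], a1$p_adj)
})

test_that("duplicated architecture rows get identical adjusted p-values", {
    m <- dosage(randomContent(71, nArch = 8L, zeroProb = 0.2))
    dup <- rbind(m, `DUP(1)` = m[1, ])
    ct <- contentFromMatrix(dup)
    res <- bootstrapAdjust(testExpansion(ct, scheme14), ct, scheme14,
                           B = 200, seed = 4)
    for (p in unique(res$pair)) {
        r1 <- res[res$architecture == rownames(m)[1] & res$pair == p, ]
        r2 <- res[res$architecture == "DUP(1)" & res$pair == p, ]
        expect_equal(r1$p_adj, r2$p_adj)
    }
})

test_that("with a single architecture the adjustment approaches the raw p", {
    ## two lineages with a real but moderate separation; large-ish groups
    sch <- LineageScheme(c("A", "B"),
                         list(A = paste0("a", 1:8), B = paste0("b", 1:8)),
                         c(A = 5, B = 5))
    set.seed(15)
    m <- matrix(c(sample(2:5, 8, TRUE), sample(4:9, 8, TRUE)), 1, 16,
                dimnames = list("X(1)", c(paste0("a", 1:8), paste0("b", 1:8))))
    ct <- contentFromMatrix(m)
    res <- testExpansion(ct, sch, pairs = lineagePairs(sch))
    B <- 2000
    adj <- bootstrapAdjust(res, ct, sch, B = B, seed = 2)
    expect_lt(abs(adj$p_adj - adj$p_raw), 2 / sqrt(B) + 0.05)
})

test_that("expansion classification maps flag combinations to labels", {
    mk <- function(pairs, sig) {
        data.frame(architecture = "X(1)",
                   earlier = sub("->.*", "", pairs),
                   later = sub(".*->", "", pairs), pair = pairs,
                   n_earlier = 3L, n_later = 3L, t = ifelse(sig, 5, 0),
                   df = 4, p_raw = ifelse(sig, 1e-4, 0.9),
                   p_adj = ifelse(sig, 1e-3, 0.95),
                   direction = ifelse(sig, "expansion", "none"),
                   untestable = FALSE)
    }
    pairs6 <- c("A->B", "A->C", "A->D", "B->C", "B->D", "C->D")
    none <- classifyExpansion(mk(pairs6, rep(FALSE, 6)), 0.01)
    expect_equal(none$label, "no expansion")
    expect_equal(none$n_significant, 0)
    allland <- classifyExpansion(mk(pairs6, c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                              FALSE)), 0.01)
    expect_equal(allland$label, "expanded from algal into all land lineages")
    mono <- classifyExpansion(mk(pairs6, c(FALSE, FALSE, FALSE, TRUE, FALSE,
                                           FALSE)), 0.01)
    expect_equal(mono$label, "expanded from early-diverging into monocot only")
    ## a contraction is never a significant expansion flag
    contr <- mk(pairs6, c(TRUE, rep(FALSE, 5)))
    contr$direction[1] <- "contraction"
    expect_equal(classifyExpansion(contr, 0.01)$label, "no expansion")
})

test_that("planted monocot-only expansion is classified as such", {
    set.seed(33)
    cfg <- simulationConfig(patternMix = c(ABCD = 25L),
        dosageModel = list(type = "jittered", value = 2, jitter = 1),
        expansionRules = list(list(fraction = 0.2, targets = "C", fold = 10)),
        seed = 35L)
    out <- simulateContent(cfg)
    res <- testExpansion(out$content, scheme14)
    res <- bootstrapAdjust(res, out$content, scheme14, B = 500, seed = 35)
    cls <- classifyExpansion(res, 0.05)
    planted <- out$truth$architecture[out$truth$expanded]
    lab <- cls$label[match(planted, cls$architecture)]
    expect_true(all(grepl("monocot|A->C|B->C", lab)))
    expect_false(any(grepl("dicot|->D", lab)))
})

test_that("constrained architecture sets follow the dosage rules", {
    land <- unlist(lineageMembers(scheme14)[c("B", "C", "D")])
    m <- matrix(0L, 3, 14, dimnames = list(
        c("SC(1)", "LOW(1)", "HI(1)"), species14))
    m["SC(1)", ] <- 1L                       # single copy everywhere
    m["LOW(1)", ] <- 2L                      # low dosage but not single copy
    m["HI(1)", ] <- 1L; m["HI(1)", "Os"] <- 3L
    cs <- constrainedArchitectures(contentFromMatrix(m), scheme14)
    expect_setequal(cs$low_dosage, c("SC(1)", "LOW(1)"))
    expect_equal(cs$single_copy_land, "SC(1)")
    expect_true(all(cs$single_copy_land %in% cs$low_dosage))
})

test_that("planted single-copy architectures are recovered exactly", {
    set.seed(88)
    n <- 60
    m <- matrix(sample(3:9, n * 14, replace = TRUE), n, 14,
                dimnames = list(sprintf("E%03d(1)", 1:n), species14))
    planted <- sort(sample(n, 20))
    m[planted, ] <- 1L
    cs <- constrainedArchitectures(contentFromMatrix(m), scheme14)
    expect_setequal(cs$single_copy_land, sprintf("E%03d(1)", planted))
})
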