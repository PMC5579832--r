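test_that("confusion counts follow the four definitions", {
    expect_equal(confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1)),
        c(TP = 1, FP = 1, TN = 1, FN = 1))
    expect_equal(confusionCounts(c(1, 0), c(1, 0)),
        c(TP = 1, FP = 0, TN = 1, FN = 0))
    expect_equal(confusionCounts(rep(1, 5), rep(0, 5)),
        c(TP = 0, FP = 0, TN = 0, FN = 5))
    expect_error(confusionCounts(numeric(), numeric()), "empty")
})

test_that("percent metrics handle perfect and undefined cases", {
    expect_equal(snSpAc(c(TP = 8, FP = 0, TN = 0, FN = 0)),
        c(sn = 100, sp = NA, ac = 100))
    expect_equal(snSpAc(c(TP = 3, FP = 1, TN = 4, FN = 2)),
        c(sn = 60, sp = 80, ac = 70))
})

test_that("accuracy is the prevalence-weighted mean of Sn and Sp", {
    set.seed(20)
    for (i in 1:25) {
        counts <- c(TP = sample(0:30, 1), FP = sample(0:30, 1),
            TN = sample(0:30, 1), FN = sample(0:30, 1))
        if (counts[["TP"]] + counts[["FN"]] == 0 ||
            counts[["FP"]] + counts[["TN"]] == 0) next
        s <- snSpAc(counts)
        wPos <- counts[["TP"]] + counts[["FN"]]
        wNeg <- counts[["FP"]] + counts[["TN"]]
        expect_equal(s[["ac"]],
            (wPos * s[["sn"]] + wNeg * s[["sp"]]) / (wPos + wNeg))
    }
})

test_that("DQ2 unit cases: perfect, mean-level, and out-of-range predictions", {
    expect_equal(dq2(c(0, 1, 1), yPred = c(0, 1, 1)), 1)
    y <- c(0, 0, 1, 1, 1)
    expect_equal(dq2(y, yPred = rep(mean(y), 5)), 0)
    expect_equal(dq2(c(0, 1), yPred = c(-0.4, 1.7)), 1)
    expect_error(dq2(c(1, 1), yPred = c(1, 1)), "one class")
})

test_that("DQ2 never penalizes more than conventional Q2 and never exceeds 1", {
    set.seed(21)
    for (i in 1:200) {
        n <- sample(4:40, 1)
        y <- c(0, 1, rbinom(n - 2, 1, 0.5))
        yhat <- rnorm(n, y, runif(1, 0.1, 2))
        d <- dq2(y, yPred = yhat)
        expect_gte(d, q2(y, yhat))
        expect_lte(d, 1)
    }
})

test_that("DQ2 equals 1 exactly when every prediction clears its bound", {
    y <- c(0, 0, 1, 1)
    expect_equal(dq2(y, yPred = c(-0.1, 0, 1, 1.5)), 1)
    expect_lt(dq2(y, yPred = c(0.01, 0, 1, 1.5)), 1)
})

test_that("LOO CV pools one prediction per row and separates clean clusters", {
    d <- makeSeparableData(nPerClass = 6, seed = 22)
    res <- looCV(d$X, d$y)
    expect_length(res$predictions@yPred, 12L)
    expect_equal(res$report@ac, 100)
    expect_identical(res$report@scheme, "loo_cv")
    # n = 4 toy set: four folds, four pooled predictions
    toy <- looCV(matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4), c(0, 0, 1, 1),
        nLV = 1)
    expect_length(toy$predictions@yPred, 4L)
})

test_that("permuted labels drive LOO accuracy to chance level", {
    acs <- sapply(1:6, function(sd) {
        set.seed(sd)
        d <- makeSeparableData(nPerClass = 30, seed = sd)
        looCV(d$X, sample(d$y))$report@ac
    })
    expect_gt(mean(acs), 35)
    expect_lt(mean(acs), 65)
})

test_that("segmented CV with singleton segments is bit-identical to LOO", {
    d <- makeSeparableData(nPerClass = 5, gap = 2, seed = 23)
    a <- looCV(d$X, d$y)
    b <- segmentedCV(d$X, d$y, segments = as.list(seq_len(10)))
    expect_identical(a$predictions@yPred, b$predictions@yPred)
    expect_identical(a$report@counts, b$report@counts)
})

test_that("grouped segments hold out whole groups without leakage", {
    # plant near-duplicate rows inside one segment; if any duplicate leaked
    # into training, its held-out twin would be predicted almost perfectly
    set.seed(24)
    base <- matrix(rnorm(8 * 3), 8, 3)
    X <- rbind(base, base[1, ] + 1e-6, base[1, ] + 2e-6)
    y <- c(rep(c(0, 1), each = 4), 0, 0)
    segs <- c(as.list(2:8), list(c(1L, 9L, 10L)))
    res <- segmentedCV(X, y, segs, nLV = 2)
    naive <- looCV(X, y, nLV = 2)
    held <- c(1L, 9L, 10L)
    # LOO leaks the planted duplicates; grouped CV must not be closer
    expect_gt(mean(abs(res$predictions@yPred[held] - y[held])),
        mean(abs(naive$predictions@yPred[held] - y[held])) - 1e-9)
    expect_identical(res$report@scheme, "segmented_cv")
})

test_that("segments built from IDs group by position, falling back to sample", {
    ids <- c("N144_Cn_1", "N144_Cn_2", "T144_B2_1", "T144_B2_2", "T191_1",
        "T191_2")
    pos <- positionSegments(ids)
    expect_length(pos, 3L)
    expect_equal(pos[["N144_Cn"]], 1:2)
    expect_equal(pos[["T191"]], 5:6)
    sam <- sampleSegments(ids)
    expect_length(sam, 3L)
    expect_equal(sam[["T144"]], 3:4)
})

test_that("six sample segments give six train/test cycles on series-A data", {
    set.seed(25)
    ids <- sprintf("%s19%d_%d", rep(c("T", "N", "T", "N", "T", "N"), each = 5),
        rep(c(1, 1, 4, 4, 8, 8), each = 5), rep(1:5, 6))
    segs <- sampleSegments(ids)
    expect_length(segs, 6L)
    X <- matrix(rnorm(30 * 4), 30) +
        outer(as.numeric(startsWith(ids, "T")), rep(4, 4))
    res <- segmentedCV(X, as.numeric(startsWith(ids, "T")), segs)
    expect_length(res$predictions@yPred, 30L)
})

test_that("cross-validation refuses single-class training folds by name", {
    X <- matrix(rnorm(12), 6, 2)
    y <- c(0, 0, 0, 0, 1, 1)
    expect_error(segmentedCV(X, y, list(1:2, 3:4, 5:6)), "single class")
})

test_that("RSV subset sizing, determinism and separable-data accuracy", {
    d <- makeSeparableData(nPerClass = 10, seed = 26)   # n = 20
    r1 <- randomSubsetValidation(d$X, d$y, fraction = 0.15,
        iterations = 200, seed = 5)
    # 15% of 20 rounds to 3 held out per iteration
    expect_equal(sum(r1@counts), 3L * 200L)
    expect_equal(r1@ac, 100)
    expect_equal(r1@nmc, 0)
    r2 <- randomSubsetValidation(d$X, d$y, fraction = 0.15,
        iterations = 200, seed = 5)
    expect_identical(as.data.frame(r1), as.data.frame(r2))
    expect_identical(r1@predictions@yPred, r2@predictions@yPred)
    expect_error(randomSubsetValidation(d$X, d$y, fraction = 0.7), "0.5")
})

test_that("RSV statistics converge: disjoint 500-iteration halves agree", {
    sen <- makeSyntheticSensor(seed = 5, classOffsetShift = 2,
        classContrastFactor = 1.1)
    a <- randomSubsetValidation(sen, iterations = 500, seed = 31)@ac
    b <- randomSubsetValidation(sen, iterations = 500, seed = 32)@ac
    expect_lt(abs(a - b), 2)
})

test_that("latent-variable selection recovers a two-factor structure", {
    picks <- sapply(1:10, function(sd) {
        set.seed(sd)
        n <- 60
        v1 <- c(1, 1, 0, 0, 0, 0) / sqrt(2)
        v2 <- c(0, 0, 1, 1, 0, 0) / sqrt(2)
        y <- rep(c(0, 1), each = n / 2)
        conf <- rnorm(n, 0, 1.5)
        X <- outer(y - 0.5, v1) * 2 + outer(conf, v2) +
            matrix(rnorm(n * 6, 0, 0.1), n)
        chooseNLV(X, y, candidates = 1:5,
            segments = as.list(seq_len(n)))$nLV
    })
    expect_gt(mean(picks == 2), 0.5)
})

test_that("latent-variable selection on pure-noise labels stays minimal", {
    picks <- sapply(1:10, function(sd) {
        set.seed(sd + 100)
        X <- matrix(rnorm(40 * 6), 40)
        y <- rep(c(0, 1), each = 20)
        chooseNLV(X, y, candidates = 1:4,
            segments = as.list(seq_len(40)))$nLV
    })
    expect_gt(mean(picks == 1), 0.5)
    # single candidate is returned as-is, with both DQ2 columns reported
    res <- chooseNLV(matrix(rnorm(40), 10), rep(c(0, 1), 5),
        candidates = 2, segments = as.list(1:10))
    expect_equal(res$nLV, 2L)
    expect_named(res$stats, c("nLV", "segmentedDQ2", "looDQ2"))
})

test_that("permutation test basics: pass on structure, re-drawn identity", {
    d <- makeSeparableData(nPerClass = 10, seed = 27)
    pt <- permutationTest(d$X, d$y, nPermutations = 20, iterations = 100,
        seed = 6)
    expect_true(pt$pass)
    expect_equal(pt$nmcOriginal, pt$reportOriginal@nmc)
    expect_length(pt$nmcPermuted, 20L)
    expect_false(is.unsorted(pt$nmcPermuted))
    # every permuted labeling differs from the original by construction,
    # so with strong structure every permuted NMC is strictly worse
    expect_true(all(pt$nmcPermuted > pt$nmcOriginal))
})
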