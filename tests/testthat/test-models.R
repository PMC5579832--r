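test_that("PCA matches an SVD oracle up to column sign", {
    set.seed(10)
    X <- matrix(rnorm(120), 20, 6)
    m <- fitPCA(X, 4)
    Xc <- scale(X, scale = FALSE)
    sv <- svd(Xc)
    for (j in 1:4) {
        lo <- loadings(m)[, j]
        vo <- sv$v[, j]
        expect_equal(abs(sum(lo * vo)), 1, tolerance = 1e-8)
        so <- sv$u[, j] * sv$d[j]
        expect_equal(abs(cor(scores(m)[, j], so)), 1, tolerance = 1e-8)
    }
    evOracle <- sv$d^2 / sum(sv$d^2)
    expect_equal(explainedVariance(m), evOracle[1:4], tolerance = 1e-8)
})

test_that("rank-1 data put essentially all variance on the first component", {
    u <- rnorm(15); v <- rnorm(5)
    m <- fitPCA(outer(u, v), 2)
    expect_gte(explainedVariance(m)[1], 1 - 1e-9)
})

test_that("all components reconstruct the centered matrix", {
    set.seed(11)
    X <- matrix(rnorm(48), 8, 6)
    m <- fitPCA(X, 6)
    recon <- scores(m) %*% t(loadings(m))
    expect_equal(recon, scale(X, scale = FALSE), tolerance = 1e-8,
        ignore_attr = TRUE)
    expect_error(fitPCA(X, 9), "nComponents")
})

test_that("univariate PLS1 with one LV is the OLS slope", {
    set.seed(12)
    x <- rnorm(30)
    y <- rep(c(0, 1), 15)
    m <- fitPLSDA(cbind(x), y, nLV = 1)
    ols <- unname(coef(lm(y ~ x))[2])
    expect_equal(unname(coef(m)), ols, tolerance = 1e-9)
})

test_that("full-rank PLS1 reproduces multiple-regression fitted values", {
    set.seed(13)
    for (rep in 1:5) {
        X <- matrix(rnorm(60), 15, 4)
        y <- rep(c(0, 1), c(7, 8))
        m <- fitPLSDA(X, y, nLV = 4)
        lmfit <- lm(y ~ X)
        expect_equal(fitted(m), unname(fitted(lmfit)), tolerance = 1e-6)
    }
})

test_that("well-separated clusters are fully discriminated in training", {
    d <- makeSeparableData(seed = 14)
    m <- fitPLSDA(d$X, d$y, nLV = 2)
    expect_identical(predictClass(fitted(m), 0.5), d$y)
})

test_that("duplicated predictor columns leave predictions unchanged", {
    set.seed(15)
    X <- matrix(rnorm(40), 10, 4)
    y <- rep(c(0, 1), each = 5)
    single <- fitPLSDA(X, y, nLV = 2)
    doubled <- fitPLSDA(cbind(X, X), y, nLV = 2)
    expect_equal(fitted(doubled), fitted(single), tolerance = 1e-8)
    expect_equal(predictResponse(doubled, cbind(X, X)),
        predictResponse(single, X), tolerance = 1e-8)
})

test_that("prediction identities: self-consistency, centering, linearity", {
    set.seed(16)
    X <- matrix(rnorm(40), 10, 4)
    y <- rep(c(0, 1), each = 5)
    m <- fitPLSDA(X, y, nLV = 2)
    expect_equal(predictResponse(m, X), fitted(m), tolerance = 1e-12)
    expect_equal(predictResponse(m, matrix(m@xMeans, 1)), mean(y))
    shift <- c(1, -2, 0.5, 3)
    expect_equal(predictResponse(m, X[3, ] + shift),
        fitted(m)[3] + sum(shift * coef(m)), tolerance = 1e-10)
    expect_error(predictResponse(m, matrix(0, 1, 3)), "3 columns")
})

test_that("model fitting rejects degenerate inputs", {
    X <- matrix(rnorm(20), 10, 2)
    expect_error(fitPLSDA(X, rep(1, 10)), "both classes")
    expect_error(fitPLSDA(matrix(3, 10, 2), rep(c(0, 1), 5)),
        "zero variance")
    expect_error(fitPLSDA(X, rep(c(0, 1), 5), nLV = 0), "at least 1")
})

test_that("class assignment thresholds with ties going to tumor", {
    expect_equal(predictClass(c(0.46, 0.48), 0.47), c(0, 1))
    expect_equal(predictClass(0.5, 0.5), 1)
    expect_equal(predictClass(c(-0.2, 1.3), 0.5), c(0, 1))
})

test_that("models are reproducible bit-identically across runs", {
    set.seed(17)
    X <- matrix(rnorm(60), 15, 4)
    y <- rep(c(0, 1), c(7, 8))
    expect_identical(coef(fitPLSDA(X, y)), coef(fitPLSDA(X, y)))
    expect_identical(scores(fitPCA(X, 3)), scores(fitPCA(X, 3)))
})
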