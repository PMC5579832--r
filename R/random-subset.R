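#' @include cross-validation.R
NULL

#' Random-subset validation (RSV)
#'
#' Repeatedly holds out a random subset of about `fraction` of the
#' measurements (subset size rounded to the nearest integer, at least 1),
#' fits the PLS-DA model on the remainder, and predicts the held-out rows.
#' Confusion counts are accumulated over all iterations and the reported
#' %Sn/%Sp/%Ac derive from the cumulative counts; DQ2 is computed on the
#' pooled out-of-subset predictions. The mean number of misclassified
#' measurements per iteration (NMC = (FP + FN) / iterations) is stored for
#' use as the permutation-test merit function. Subsets are drawn without
#' class stratification; a draw whose training remainder loses a class is
#' re-drawn (and the number of re-draws reported via a warning).
#'
#' @param X numeric matrix or [SpectraSet]/[SensorTable].
#' @param y numeric 0/1 response; taken from `X` when possible.
#' @param fraction held-out fraction, in (0, 0.5] (default 0.15).
#' @param iterations number of subset-selection/modeling/validation cycles
#'   (default 1000, which is enough for the cumulative statistics to
#'   converge).
#' @param nLV number of latent variables (default 2).
#' @param threshold decision threshold (default 0.5).
#' @param seed integer seed; the same seed always yields an identical
#'   report. `NULL` uses the current RNG stream.
#' @return a [ValidationReport-class] with scheme `"rsv"`, cumulative counts,
#'   pooled-prediction DQ2 and the per-iteration mean NMC.
#' @examples
#' X <- rbind(matrix(rnorm(40), 10), matrix(rnorm(40, 4), 10))
#' randomSubsetValidation(X, rep(c(0, 1), each = 10), iterations = 50,
#'                        seed = 1)
#' @export
randomSubsetValidation <- function(X, y = NULL, fraction = 0.15,
                                   iterations = 1000L, nLV = 2L,
                                   threshold = 0.5, seed = NULL) {
    xy <- .resolveXY(X, y)
    X <- xy$X; y <- xy$y
    if (fraction <= 0 || fraction > 0.5)
        stop("'fraction' must lie in (0, 0.5]")
    n <- nrow(X)
    k <- max(1L, as.integer(floor(fraction * n + 0.5)))
    if (n - k < 2L)
        stop("training remainder too small; reduce 'fraction'")
    withLocalSeed(seed, {
        yTrueAll <- vector("list", iterations)
        yPredAll <- vector("list", iterations)
        redraws <- 0L
        for (it in seq_len(iterations)) {
            repeat {
                hold <- sample.int(n, k)
                if (length(unique(y[-hold])) == 2L)
                    break
                redraws <- redraws + 1L
            }
            fit <- fitPLSDA(X[-hold, , drop = FALSE], y[-hold], nLV = nLV,
                threshold = threshold)
            yTrueAll[[it]] <- y[hold]
            yPredAll[[it]] <- predictResponse(fit, X[hold, , drop = FALSE])
        }
        if (redraws > 0L)
            warning(sprintf(
                "%d subset draw(s) left a single-class training set %s",
                redraws, "and were re-drawn"))
        pred <- PredictionSet(unlist(yTrueAll), unlist(yPredAll),
            threshold = threshold)
        report <- .makeReport("rsv", pred, nLV)
        report@nmc <- (report@counts[["FP"]] + report@counts[["FN"]]) /
            iterations
        report
    })
}
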