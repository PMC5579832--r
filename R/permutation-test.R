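#' @include random-subset.R
NULL

#' Label-permutation test of a PLS-DA discrimination
#'
#' Guards against chance correlation on small datasets: the response vector
#' is randomly permuted `nPermutations` times, the full random-subset
#' validation is re-run for each permutation, and the mean number of
#' misclassified measurements per RSV iteration (NMC = FP + FN) serves as
#' the merit function. The test passes if the original labeling yields a
#' strictly smaller NMC than every permutation. A permutation identical to
#' the original labeling is re-drawn. All randomness derives from the single
#' `seed` via documented stream splitting (one sub-seed per RSV run, drawn
#' up front), so results are reproducible.
#'
#' @param X numeric matrix or [SpectraSet]/[SensorTable].
#' @param y numeric 0/1 response; taken from `X` when possible.
#' @param nPermutations number of label permutations (default 100; 50--100
#'   is typically enough to reveal overfitting).
#' @param fraction,iterations,nLV,threshold passed to
#'   [randomSubsetValidation()] for the original and every permuted run.
#' @param seed integer seed for the whole test.
#' @return list with elements `pass` (logical), `nmcOriginal` (scalar),
#'   `nmcPermuted` (sorted numeric vector, ready for a permutation bar
#'   plot) and `reportOriginal` (the original-label
#'   [ValidationReport-class]).
#' @examples
#' X <- rbind(matrix(rnorm(40), 10), matrix(rnorm(40, 4), 10))
#' pt <- permutationTest(X, rep(c(0, 1), each = 10), nPermutations = 5,
#'                       iterations = 50, seed = 1)
#' pt$pass
#' @export
permutationTest <- function(X, y = NULL, nPermutations = 100L,
                            fraction = 0.15, iterations = 1000L, nLV = 2L,
                            threshold = 0.5, seed = NULL) {
    xy <- .resolveXY(X, y)
    X <- xy$X; y <- xy$y
    nPermutations <- as.integer(nPermutations)
    if (nPermutations < 1L)
        stop("'nPermutations' must be at least 1")
    withLocalSeed(seed, {
        subSeeds <- sample.int(.Machine$integer.max, nPermutations + 1L)
        perms <- vector("list", nPermutations)
        for (j in seq_len(nPermutations)) {
            repeat {
                yp <- sample(y)
                if (!identical(yp, y))
                    break
            }
            perms[[j]] <- yp
        }
        original <- randomSubsetValidation(X, y, fraction = fraction,
            iterations = iterations, nLV = nLV, threshold = threshold,
            seed = subSeeds[1L])
        nmcPerm <- vapply(seq_len(nPermutations), function(j)
            randomSubsetValidation(X, perms[[j]], fraction = fraction,
                iterations = iterations, nLV = nLV, threshold = threshold,
                seed = subSeeds[j + 1L])@nmc, numeric(1L))
        list(pass = original@nmc < min(nmcPerm),
            nmcOriginal = original@nmc,
            nmcPermuted = sort(nmcPerm),
            reportOriginal = original)
    })
}
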