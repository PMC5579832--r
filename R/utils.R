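#' Evaluate an expression under a temporary RNG seed
#'
#' Saves any existing `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous RNG state, so seeded package functions never
#' disturb the caller's random stream. `seed = NULL` evaluates `expr` under
#' the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @keywords internal
withLocalSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
    expr
}

#' Round half away from zero
#'
#' Conventional "half-up" rounding used when formatting percentages to one
#' decimal (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector; `NA` passes through.
#' @examples
#' roundHalfUp(90.45, 1)  # 90.5
#' @export
roundHalfUp <- function(x, digits = 0L) {
    scale <- 10^digits
    sign(x) * floor(abs(x) * scale + 0.5) / scale
}

## shared input checks
.checkMatrix <- function(X, what = "X") {
    X <- as.matrix(X)
    if (!is.numeric(X) || nrow(X) < 1L)
        stop(sprintf("'%s' must be a non-empty numeric matrix", what))
    storage.mode(X) <- "double"
    X
}

.checkBinary <- function(y) {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1)))
        stop("'y' must be coded 0 (normal) / 1 (tumor)")
    y
}
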