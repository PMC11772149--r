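## Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
## Every stochastic operation in the package routes its randomness through this,
## so identical (params, seed) pairs give bit-identical output.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single number", call. = FALSE)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

.checkScalar <- function(x, name, lower = -Inf, upper = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
        stop(sprintf("'%s' must be a single number", name), call. = FALSE)
    if (x < lower || x > upper)
        stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper),
             call. = FALSE)
    invisible(x)
}

## ITU-R BT.601 luminance of an RGB triplet matrix / array, 0-255 scale.
.luminance <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b

## Shift a matrix by (dy, dx), zero-filling the vacated band.
.shiftMat <- function(m, dy, dx) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(0, h, w)
    ys <- max(1, 1 + dy):min(h, h + dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    if (length(ys) && length(xs))
        out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
    out
}

.degrees <- function(rad) rad * 180 / pi
.radians <- function(deg) deg * pi / 180

## Interior angle (degrees) between vectors u and v, in [0, 180].
.vecAngle <- function(u, v) {
    cr <- u[1] * v[2] - u[2] * v[1]
    dt <- sum(u * v)
    .degrees(atan2(abs(cr), dt))
}

.rot2 <- function(v, deg) {
    a <- .radians(deg)
    c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}
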