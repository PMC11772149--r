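## Exhaustive per-pixel neighbourhood-sum oracle for the compactness map.
## Deliberately written as a scalar double loop over window offsets, with
## the same column-major accumulation order as plain matrix addition, so
## results are comparable bit for bit.
bruteCompactness <- function(intensity, mask, r) {
    h <- nrow(intensity); w <- ncol(intensity)
    vals <- intensity
    vals[!mask] <- 0
    out <- matrix(0, h, w)
    for (j in seq_len(w)) {
        for (i in seq_len(h)) {
            if (!mask[i, j]) next
            s <- 0
            for (dx in -r:r) {
                x <- j + dx
                if (x < 1 || x > w) next
                for (dy in -r:r) {
                    y <- i + dy
                    if (y < 1 || y > h) next
                    s <- s + vals[y, x]
                }
            }
            out[i, j] <- s
        }
    }
    out
}

## Block coverage of a mask at block size s (complete blocks only),
## computed directly from submatrix sums.
blockCoverageOracle <- function(m, s) {
    nby <- nrow(m) %/% s; nbx <- ncol(m) %/% s
    out <- matrix(0, nby, nbx)
    for (i in seq_len(nby))
        for (j in seq_len(nbx))
            out[i, j] <- mean(m[((i - 1) * s + 1):(i * s),
                                ((j - 1) * s + 1):(j * s)])
    out
}

## Straight axis-aligned structure mask helper.
straightMask <- function(h, w, rows, cols, pixelSize = 1,
                         axis = "columns") {
    m <- matrix(FALSE, h, w)
    m[rows, cols] <- TRUE
    new("StructureMask", mask = m, pixelSize = pixelSize, axis = axis)
}
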