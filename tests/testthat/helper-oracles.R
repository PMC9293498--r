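# Brute-force term-by-term moment evaluator: accumulates the defining
# sum of M_pq = E[x^(p-q) conj(x)^q] one element at a time. Kept
# deliberately independent of the package's vectorized path.
bruteMoment <- function(x, p, q) {
    acc <- 0
    for (xi in x) acc <- acc + xi^(p - q) * Conj(xi)^q
    Re(acc) / length(x)
}

# Cumulant set assembled directly from the defining moment formulas.
bruteCumulants <- function(x, mode = "paper", eightFeature = FALSE) {
    M20 <- bruteMoment(x, 2, 0)
    M21 <- sum(abs(x)^2) / length(x)
    M40 <- bruteMoment(x, 4, 0)
    M41 <- bruteMoment(x, 4, 1)
    M42 <- bruteMoment(x, 4, 2)
    psi40 <- M40 - 3 * M20^2
    if (mode == "paper") {
        psi41 <- M40 - 3 * M20 * M21
        psi42 <- M42 - M20^2 - 2 * M21
    } else {
        psi41 <- M41 - 3 * M21 * M20
        psi42 <- M42 - abs(M20)^2 - 2 * M21^2
    }
    out <- c(psi20 = M20, psi21 = M21, psi40 = psi40, psi41 = psi41,
             psi42 = psi42)
    if (eightFeature) out <- c(out, m20 = M20, m21 = M21, m42 = M42)
    out
}

# Small grid spec for desk-scale tests.
smallSpec <- function(...) {
    args <- list(...)
    if (is.null(args$gridShape)) args$gridShape <- c(8, 8, 6)
    do.call(syntheticSpec, args)
}

# Minimal hand-built design matrix (non-HRF) for algebraic GLM checks.
rawDesign <- function(X, kinds = NULL, tr = 2) {
    if (is.null(kinds))
        kinds <- c(rep("condition", ncol(X) - 1), "baseline")
    labels <- data.frame(name = paste0("c", seq_len(ncol(X))),
                         kind = kinds, stringsAsFactors = FALSE)
    colnames(X) <- labels$name
    new("DesignMatrix", X = X, labels = labels, tr = tr)
}

# Wrap a time-by-voxels matrix as a BoldRun on a V x 1 x 1 grid.
matrixBold <- function(Y, tr = 2) {
    new("BoldRun", data = array(t(Y), c(ncol(Y), 1, 1, nrow(Y))),
        tr = tr, mask = NULL)
}
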