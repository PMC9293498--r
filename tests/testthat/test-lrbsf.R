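cumTableOf <- function(values, labels) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
    new("CumulantFeatureTable", values = values,
        labels = as.integer(labels),
        trialIds = seq_len(nrow(values)), mode = "paper")
}

test_that("Silverman bandwidth matches the reference rule", {
    set.seed(1)
    s <- rnorm(200)
    k <- fitKde(s)
    expect_equal(k@bandwidth,
                 0.9 * min(sd(s), IQR(s) / 1.34) * 200^(-1/5))
    expect_equal(k@bandwidth, stats::bw.nrd0(s))
})

test_that("degenerate samples fall back and peak at the value", {
    expect_message(k <- fitKde(rep(2, 10)), "fallback bandwidth")
    expect_equal(k@bandwidth, 1e-3 * 3)
    y <- seq(1.9, 2.1, by = 0.01)
    d <- kdeDensityAt(k, y)
    expect_equal(y[which.max(d)], 2)
})

test_that("fitted densities integrate to one and stay floored", {
    set.seed(2)
    for (s in list(rnorm(50), rexp(80), runif(30, -5, 5))) {
        k <- fitKde(s)
        lo <- min(s) - 10 * k@bandwidth
        hi <- max(s) + 10 * k@bandwidth
        int <- stats::integrate(function(y) kdeDensityAt(k, y),
                                lo, hi)$value
        expect_gt(int, 0.99); expect_lt(int, 1.01)
        expect_gte(kdeDensityAt(k, 1e6), 1e-300)
    }
})

test_that("the KDE converges to the true density", {
    set.seed(3)
    k <- fitKde(rnorm(2000))
    grid <- seq(-4, 4, length.out = 400)
    expect_lt(max(abs(kdeDensityAt(k, grid) - dnorm(grid))), 0.05)
    # cross-check against the reference KDE at matched bandwidth
    ref <- stats::density(k@samples, bw = k@bandwidth, n = 512,
                          from = -4, to = 4)
    # stats::density bins onto a grid, so agreement is approximate
    expect_lt(max(abs(kdeDensityAt(k, ref$x) - ref$y)), 1e-3)
})

test_that("identical class densities give zero log likelihood ratio", {
    set.seed(4)
    V <- matrix(rnorm(40), 20, 2)
    tab <- cumTableOf(rbind(V, V), rep(1:2, each = 20))
    model <- fitDecoder(tab)
    for (y in list(c(0, 0), c(1, -1), c(2.5, 0.3)))
        expect_equal(likelihoodRatio(model, y, 1, 2), 0)
})

test_that("log LR is antisymmetric and orders by proximity", {
    set.seed(5)
    tab <- cumTableOf(matrix(c(rnorm(60, 0), rnorm(60, 5)), ncol = 2,
                             byrow = FALSE),
                      rep(1:2, each = 30))
    model <- fitDecoder(tab)
    y <- c(0.1, 0.2)
    expect_equal(likelihoodRatio(model, y, 1, 2),
                 -likelihoodRatio(model, y, 2, 1))
    expect_error(likelihoodRatio(model, y, 1, 9), "unknown class")
    expect_error(likelihoodRatio(model, c(1, 2, 3), 1, 2), "length")
})

test_that("the binary decision rule honors theta and the boundary", {
    expect_equal(decideBinary(0, 1), 1L)      # boundary goes to H0
    expect_equal(decideBinary(-0.1, 1), 2L)
    expect_equal(decideBinary(1, exp(2)), 2L) # log theta = 2 > 1
    expect_equal(decideBinary(2, exp(2)), 1L)
    expect_error(decideBinary(0, 0), "theta")
})

test_that("decoder training counts densities and is deterministic", {
    set.seed(6)
    tab2 <- cumTableOf(matrix(rnorm(100), 20, 5), rep(1:2, 10))
    m2 <- fitDecoder(tab2)
    expect_length(m2@densities, 2L)
    expect_equal(sum(lengths(m2@densities)), 10L)

    tab5 <- cumTableOf(matrix(rnorm(50 * 8), 50, 8), rep(1:5, 10))
    m5 <- fitDecoder(tab5)
    expect_equal(sum(lengths(m5@densities)), 40L)

    expect_identical(fitDecoder(tab5), m5)

    bad <- cumTableOf(matrix(rnorm(15), 3, 5), c(1, 1, 2))
    expect_error(fitDecoder(bad), "class 2 has fewer than 2")
    expect_error(fitDecoder(tab2, theta = -1), "theta")
})

test_that("multiclass prediction is argmax with low-index ties", {
    set.seed(7)
    tab <- cumTableOf(matrix(c(rnorm(40, 0), rnorm(40, 4),
                               rnorm(40, 8)), ncol = 1),
                      rep(1:3, each = 40))
    model <- fitDecoder(tab)
    expect_equal(predictMulticlass(model, 4), 2L)
    expect_equal(predictMulticlass(model, 8.2), 3L)
    # two classes trained on identical samples tie exactly; the test
    # point is deep in their shared support, so class 1 wins the tie
    V <- matrix(rnorm(30), 30, 1)
    tabTie <- cumTableOf(rbind(V, V, V + 50),
                         rep(1:3, each = 30))
    mTie <- fitDecoder(tabTie)
    expect_equal(predictMulticlass(mTie, 0), 1L)
})

test_that("with two classes argmax equals the LR rule at theta 1", {
    set.seed(8)
    tab <- cumTableOf(matrix(c(rnorm(80, 0), rnorm(80, 2)), ncol = 2),
                      rep(1:2, each = 40))
    model <- fitDecoder(tab)
    for (i in 1:50) {
        y <- rnorm(2, sample(0:2, 1))
        lr <- likelihoodRatio(model, y, 1, 2)
        expect_identical(predictMulticlass(model, y),
                         decideBinary(lr, 1, 1L, 2L))
    }
})

test_that("the decoder approaches the closed-form Bayes rule", {
    set.seed(9)
    nTrain <- 1000
    tab <- cumTableOf(matrix(c(rnorm(nTrain, 0), rnorm(nTrain, 3)),
                             ncol = 1),
                      rep(1:2, each = nTrain))
    model <- fitDecoder(tab)
    yTest <- seq(-2, 5, length.out = 500)
    pred <- vapply(yTest, function(y) predictMulticlass(model, y),
                   integer(1))
    bayes <- ifelse(yTest < 1.5, 1L, 2L)
    expect_gte(mean(pred == bayes), 0.98)
})

test_that("feature-name mismatches are rejected when scoring tables", {
    set.seed(10)
    tab <- cumTableOf(matrix(rnorm(80), 20, 4), rep(1:2, 10))
    model <- fitDecoder(tab)
    wrong <- cumTableOf(matrix(rnorm(40), 10, 4), rep(1:2, 5))
    colnames(wrong@values) <- paste0("g", 1:4)
    expect_error(decodeTable(model, wrong), "do not match")
    res <- decodeTable(model, tab)
    expect_length(res$predicted, 20L)
    expect_true(res$accuracy >= 0 && res$accuracy <= 100)
})
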