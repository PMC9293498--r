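test_that("design matrix column counts follow the layout", {
    ev5 <- data.frame(onset = seq(8, by = 12, length.out = 10),
                      duration = 1, condition = rep(1:5, 2),
                      trial_id = 1:10)
    nScans <- 80
    nuis <- matrix(rnorm(nScans * 6), nScans, 6)
    d <- buildDesignMatrix(ev5, nScans, 2, mode = "condition",
                           nuisance = nuis)
    expect_equal(ncol(designMatrix(d)), 12L)  # 5 + 6 + baseline
    expect_equal(sum(designLabels(d)$kind == "baseline"), 1L)

    ev1 <- data.frame(onset = c(8, 30), duration = 1, condition = 1,
                      trial_id = 1:2)
    d1 <- buildDesignMatrix(ev1, 40, 2, mode = "condition")
    expect_equal(ncol(designMatrix(d1)), 2L)  # condition + baseline
})

test_that("beta-series design over 260 trials has 267 columns", {
    spec <- syntheticSpec(seed = 4)  # 5 x 52 trials, defaults
    ev <- lrbsf:::withSeed(4L, lrbsf:::simulateEvents(spec))
    nScans <- ceiling((max(ev$onset) + 33) / 2)
    nuis <- matrix(rnorm(nScans * 6), nScans, 6)
    d <- buildDesignMatrix(ev, nScans, 2, mode = "beta_series",
                           nuisance = nuis)
    expect_equal(ncol(designMatrix(d)), 267L)  # 260 + 6 + 1
    expect_equal(sum(designLabels(d)$kind == "trial"), 260L)
})

test_that("collinear designs error with the offending column names", {
    ev <- data.frame(onset = c(8, 30), duration = 1,
                     condition = c(1, 2), trial_id = 1:2)
    nScans <- 40
    # nuisance column duplicating the baseline
    nuis <- matrix(1, nScans, 1, dimnames = list(NULL, "constant"))
    expect_error(buildDesignMatrix(ev, nScans, 2, mode = "condition",
                                   nuisance = nuis),
                 "rank deficient.*constant|baseline")
})

test_that("OLS recovers repeated-design means exactly", {
    X <- matrix(c(1, 0, 1, 0,
                  0, 1, 0, 1), 4, 2)
    d <- rawDesign(X, kinds = c("condition", "condition"))
    bold <- matrixBold(matrix(c(2, 3, 2, 3), 4, 1))
    fit <- fitGlm(bold, d)
    expect_equal(unname(fit@beta[, 1]), c(2, 3))
    expect_equal(fit@sigma2, 0)
})

test_that("noiseless synthetic runs are interpolated exactly", {
    spec <- smallSpec(nClasses = 2, trialsPerClass = 4, noiseSd = 0,
                      effectSize = c(1, 3), seed = 9)
    run <- makeBoldRun(spec)
    d <- buildDesignMatrix(run$events, dim(boldData(run$bold))[4], 2,
                           mode = "beta_series")
    fit <- fitGlm(run$bold, d)
    expect_lt(max(abs(trialBetas(fit) - run$truth)), 1e-8)
    expect_lt(max(fit@sigma2), 1e-16)
})

test_that("beta-hat sampling covariance matches sigma^2 (X'X)^-1", {
    nScans <- 400
    ev <- data.frame(onset = seq(8, by = 16, length.out = 40),
                     duration = 1, condition = rep(1:2, 20),
                     trial_id = 1:40)
    d <- buildDesignMatrix(ev, nScans, 2, mode = "condition")
    X <- designMatrix(d)
    betaTrue <- c(1, 2, 100)
    nSim <- 500
    set.seed(42)
    Y <- matrix(X %*% betaTrue, nScans, nSim) +
        matrix(rnorm(nScans * nSim), nScans, nSim)
    fit <- fitGlm(matrixBold(Y), d)
    empCov <- stats::cov(t(fit@beta))
    theoCov <- solve(crossprod(X))  # sigma^2 = 1
    relErr <- norm(empCov - theoCov, "F") / norm(theoCov, "F")
    expect_lt(relErr, 0.10)
    expect_lt(max(abs(rowMeans(fit@beta) - betaTrue)), 0.05)
})

test_that("residuals are orthogonal to every design column", {
    spec <- smallSpec(nClasses = 2, trialsPerClass = 4, noiseSd = 1,
                      seed = 13)
    run <- makeBoldRun(spec)
    d <- buildDesignMatrix(run$events, dim(boldData(run$bold))[4], 2,
                           mode = "beta_series")
    fit <- fitGlm(run$bold, d)
    X <- designMatrix(d)
    nvox <- prod(dim(boldData(run$bold))[1:3])
    Y <- t(matrix(boldData(run$bold), nvox,
                  dim(boldData(run$bold))[4]))
    res <- Y - X %*% fit@beta
    expect_lt(max(abs(crossprod(X, res))), 1e-6 * max(abs(Y)))
})

test_that("rescaling a regressor rescales its beta inversely", {
    X <- cbind(rnorm(30), 1)
    set.seed(8)
    Y <- matrix(X %*% c(2, 5) + rnorm(30), 30, 1)
    f1 <- fitGlm(matrixBold(Y), rawDesign(X,
                 kinds = c("condition", "baseline")))
    X2 <- X; X2[, 1] <- X2[, 1] * 10
    f2 <- fitGlm(matrixBold(Y), rawDesign(X2,
                 kinds = c("condition", "baseline")))
    expect_equal(f2@beta[1, 1] * 10, f1@beta[1, 1])
    # contrast rescaled inversely gives the identical t statistic
    t1 <- tContrast(f1, c(1, 0))@t
    t2 <- tContrast(f2, c(10, 0))@t
    expect_equal(t1, t2)
})

test_that("t contrasts behave at the edges", {
    set.seed(3)
    d <- rawDesign(cbind(rnorm(8), rnorm(8), 1),
                   kinds = c("condition", "condition", "baseline"))
    Y <- matrix(rnorm(8 * 4), 8, 4)
    fit <- fitGlm(matrixBold(Y), d)
    expect_error(tContrast(fit, c(0, 0, 0)), "nonzero")
    expect_error(tContrast(fit, c(1, 0)), "length")
    # c'beta = 0 by construction -> t = 0
    b <- fit@beta[, 1]
    cvec <- c(1, -b[1] / b[2], 0)
    tm <- tContrast(fit, cvec)
    expect_equal(tm@t[1], 0)
})

test_that("zero-variance voxels get signed infinite t and a flag", {
    spec <- smallSpec(nClasses = 1, trialsPerClass = 2, noiseSd = 0,
                      effectSize = 2, seed = 6,
                      gridShape = c(4, 4, 2),
                      activeClusters = list(c(0L, 1L)))
    run <- makeBoldRun(spec)
    d <- buildDesignMatrix(run$events, dim(boldData(run$bold))[4], 2,
                           mode = "condition")
    fit <- fitGlm(run$bold, d)
    tm <- tContrast(fit, c(1, 0))
    expect_true(all(tm@flagged))
    expect_equal(tm@t[1], Inf)   # active voxel, positive effect
    expect_equal(tm@t[10], 0)    # inactive voxel: zero effect, flagged
    # noiseless active vs inactive ordering
    expect_gt(abs(tm@t[1]), abs(tm@t[10]))
})
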