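mkSeries <- function(roi, total, bg, nPre = 1L)
    FrapSeries(timeS = seq_along(roi) - 1, roiMean = roi, totalMean = total,
               backgroundMean = bg, nPre = nPre)

test_that("background subtraction is frame-wise with clipping at zero", {
    s <- mkSeries(c(10, 10, 10), c(20, 20, 20), c(2, 2, 2))
    out <- subtractBackground(s)
    expect_equal(roiMean(out), c(8, 8, 8))
    expect_equal(totalMean(out), c(18, 18, 18))
    expect_equal(backgroundMean(out), c(0, 0, 0))

    # zero background: identity
    s0 <- mkSeries(c(10, 9, 8), c(20, 19, 18), c(0, 0, 0))
    expect_equal(roiMean(subtractBackground(s0)), c(10, 9, 8))

    # background exceeding the signal clips at 0 with a warning
    s2 <- mkSeries(c(1, 1, 1), c(5, 5, 5), c(2, 2, 2))
    expect_warning(out2 <- subtractBackground(s2), "clipped")
    expect_equal(roiMean(out2), c(0, 0, 0))
})

test_that("acquisition correction cancels decay shared by roi and total", {
    # constant total: identity
    s <- mkSeries(c(10, 4, 6, 8), c(20, 18, 18.5, 19), rep(0, 4))
    expect_equal(roiMean(acquisitionCorrection(s)),
                 roiMean(s) * mean(20) / totalMean(s))
    sConst <- mkSeries(c(10, 4, 6, 8), rep(20, 4), rep(0, 4))
    expect_equal(roiMean(acquisitionCorrection(sConst)), c(10, 4, 6, 8))

    # multiplying both traces by exp(-0.01 t) changes nothing after
    # correction (the single pre-bleach frame sits at t = 0, where the
    # decay factor is exactly 1)
    t <- 0:18
    roi0 <- c(100, 40 + 2 * (0:17))
    tot0 <- c(100, rep(99, 18))
    dec <- exp(-0.01 * t)
    plain <- acquisitionCorrection(mkSeries(roi0, tot0, rep(0, 19)))
    decayed <- acquisitionCorrection(mkSeries(roi0 * dec, tot0 * dec,
                                              rep(0, 19)))
    expect_equal(roiMean(decayed), roiMean(plain), tolerance = 1e-9)

    # with several pre-bleach frames the shared decay cancels up to the
    # constant pre-bleach decay average, which normalization removes
    t3 <- 0:20
    roi3 <- c(rep(100, 3), 40 + 2 * (0:17))
    tot3 <- c(rep(100, 3), rep(99, 18))
    dec3 <- exp(-0.01 * t3)
    c1 <- normalizeFrap(acquisitionCorrection(
        mkSeries(roi3, tot3, rep(0, 21), nPre = 3L)))
    c2 <- normalizeFrap(acquisitionCorrection(
        mkSeries(roi3 * dec3, tot3 * dec3, rep(0, 21), nPre = 3L)))
    expect_equal(curveValues(c2), curveValues(c1), tolerance = 1e-9)

    # non-positive total is a correction error naming the frame
    sBad <- mkSeries(c(10, 4, 6), c(20, 0, 18), rep(0, 3))
    expect_error(acquisitionCorrection(sBad), "frame")
})

test_that("normalization sets the pre-bleach mean to one and applies the plateau-window rule", {
    s <- mkSeries(c(100, 100, 100, 40, 50, 60, 70, 72, 74, 75),
                  rep(100, 10), rep(0, 10), nPre = 3L)
    curve <- normalizeFrap(s)
    expect_equal(mean(curveValues(curve)[1:3]), 1, tolerance = 1e-13)
    expect_equal(fPost(curve), 0.4)
    expect_equal(frapTimes(curve)[4], 0)  # re-zeroed at first post frame

    # window rule: 97 post-bleach frames -> last 20 scans
    c97 <- normalizeFrap(subtractBackground(
        generateFrapSeries(noiselessTruth())))
    expect_equal(endWindow(c97), 20L)
    # 10 post-bleach frames -> floor(10/4) = 2, raised to the minimum 3
    c10 <- normalizeFrap(mkSeries(c(rep(100, 3), seq(40, 76, 4)),
                                  rep(100, 13), rep(0, 13), nPre = 3L))
    expect_equal(endWindow(c10), 3L)

    # F_pre <= 0 is a normalization error
    sZero <- mkSeries(c(0, 0, 0, 10, 12), rep(100, 5), rep(0, 5), nPre = 3L)
    expect_error(normalizeFrap(sZero), "F_pre")
})

test_that("mobile fraction follows (F_end - F_post)/(F_pre - F_post)", {
    expect_equal(mobileFraction(curveWith(fPost = 0.4, fEnd = 0.85)), 0.75)
    expect_equal(mobileFraction(curveWith(fPost = 0.4, fEnd = 1.0)), 1.0)
    expect_equal(mobileFraction(curveWith(fPost = 0.4, fEnd = 0.4)), 0.0)
    # no bleach: undefined
    expect_error(mobileFraction(curveWith(fPost = 1.0, fEnd = 1.0)),
                 "F_pre <= F_post")
    # noise pushing M_f above 1.05 is reported but flagged
    expect_warning(mf <- mobileFraction(curveWith(fPost = 0.4, fEnd = 1.04)),
                   "1.05")
    expect_equal(mf, (1.04 - 0.4) / 0.6)
})

test_that("half-time estimators recover the generating half-time", {
    curve <- normalizeFrap(acquisitionCorrection(subtractBackground(
        generateFrapSeries(noiselessTruth(m = 0.89, h = 4.3)))))
    fit <- halfTime(curve, method = "exp_fit")
    expect_true(converged(fit))
    expect_lt(abs(halfTimeS(fit) - 4.3), 1e-6)
    expect_lt(fitRMSE(fit), 1e-9)

    interp <- halfTime(curve, method = "interpolation")
    expect_lt(abs(halfTimeS(interp) - 4.3), 1)  # within one frame interval
    expect_equal(fitRMSE(interp), 0)
})

test_that("noisy-curve exponential fit matches the independent optimizer", {
    # frozen oracle: scipy.optimize.curve_fit on the identical normalized
    # curve (seed 42, h = 3.0, noise SD 2% of the pre-bleach level)
    tr <- FrapGroundTruth(seed = 42L, mobileFraction = 0.89, halfTime = 3.0,
                          noiseSd = 20)
    curve <- normalizeFrap(acquisitionCorrection(subtractBackground(
        generateFrapSeries(tr))))
    fit <- halfTime(curve, method = "exp_fit")
    expect_true(converged(fit))
    expect_equal(halfTimeS(fit), 2.5880699238, tolerance = 1e-6)
    expect_equal(fitRMSE(fit), 0.0264800046, tolerance = 1e-6)
})

test_that("the full pipeline recovers ground truth over the (m, h) grid", {
    for (m in c(0, 0.25, 0.5, 0.75, 0.89, 1.0)) {
        for (h in c(1, 3, 4.3, 7.6, 10)) {
            est <- analyzeFrap(generateFrapSeries(noiselessTruth(m = m, h = h)))
            expect_lt(abs(mobileFraction(est) - m), 0.01)
            if (m > 0)  # half-time is unidentifiable without recovery
                expect_lt(abs(halfTimeS(est) - h) / h, 0.02)
        }
    }
})

test_that("estimates are invariant to monitor bleaching after correction", {
    ref <- analyzeFrap(generateFrapSeries(noiselessTruth(lambda = 0)))
    for (lambda in c(0.002, 0.005, 0.01)) {
        est <- analyzeFrap(generateFrapSeries(noiselessTruth(lambda = lambda)))
        expect_lt(abs(mobileFraction(est) - mobileFraction(ref)), 0.01)
        expect_lt(abs(halfTimeS(est) - halfTimeS(ref)), 0.01)
    }
    # the double-normalization route gives the same answer
    s <- generateFrapSeries(noiselessTruth(lambda = 0.005))
    estD <- analyzeFrap(s, doubleNormalization = TRUE)
    expect_lt(abs(mobileFraction(estD) - mobileFraction(ref)), 0.01)
})

test_that("estimates are invariant to the intensity scale", {
    s <- generateFrapSeries(FrapGroundTruth(seed = 8L, noiseSd = 10))
    scaled <- FrapSeries(timeS = frapTimes(s), roiMean = 7.3 * roiMean(s),
                         totalMean = 7.3 * totalMean(s),
                         backgroundMean = 7.3 * backgroundMean(s),
                         nPre = nPre(s))
    e1 <- analyzeFrap(s)
    e2 <- analyzeFrap(scaled)
    expect_equal(mobileFraction(e2), mobileFraction(e1), tolerance = 1e-9)
    expect_equal(halfTimeS(e2), halfTimeS(e1), tolerance = 1e-7)
})

test_that("replicate noisy curves average to the true mobile fraction", {
    # eight cells per condition at 2% noise, as in a typical FRAP study
    mfs <- vapply(1:8, function(seed) {
        tr <- FrapGroundTruth(seed = seed, mobileFraction = 0.89,
                              halfTime = 4.3, noiseSd = 20)
        mobileFraction(analyzeFrap(generateFrapSeries(tr)))
    }, numeric(1))
    expect_lt(abs(mean(mfs) - 0.89), 0.03)
})

test_that("exp_fit and interpolation agree within the frame interval", {
    for (h in c(2, 4.3, 8)) {
        curve <- normalizeFrap(acquisitionCorrection(subtractBackground(
            generateFrapSeries(noiselessTruth(m = 0.89, h = h)))))
        dFit <- abs(halfTimeS(halfTime(curve, "exp_fit")) -
                    halfTimeS(halfTime(curve, "interpolation")))
        expect_lt(dFit, 1)
    }
})

test_that("analyzeFrapSet emits one audited row per cell", {
    sl <- lapply(1:3, function(i)
        generateFrapSeries(FrapGroundTruth(seed = i, noiseSd = 5)))
    tab <- analyzeFrapSet(sl)
    expect_equal(nrow(tab), 3L)
    expect_true(all(c("cell_id", "mobile_fraction", "half_time_s", "method",
                      "f_pre", "f_post", "f_end", "end_window", "fit_rmse",
                      "converged") %in% names(tab)))
    expect_true(all(tab$converged))
})
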