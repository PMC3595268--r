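test_that("pooled t-test matches the textbook formula", {
    # identical samples: t = 0, p = 1
    eq <- studentsT(c(1, 2, 3), c(1, 2, 3))
    expect_equal(eq$t, 0)
    expect_equal(eq$p, 1)

    # well-separated samples with tiny jitter
    sep <- studentsT(c(0, 0, 0, 0) + c(0, 1e-6, -1e-6, 0),
                     c(1, 1, 1, 1) + c(1e-6, 0, 0, -1e-6))
    expect_lt(sep$p, 0.001)

    # frozen oracle: hand-computed pooled-variance t and scipy p
    tt <- studentsT(c(4.3, 4.1, 4.6, 4.2), c(3.0, 3.2, 2.9, 3.1))
    expect_equal(tt$t, 9.9339926780, tolerance = 1e-9)
    expect_equal(tt$p, 6.014823757523e-05, tolerance = 1e-9)
    expect_equal(tt$df, 6)

    expect_error(studentsT(c(1), c(1, 2)), "at least 2")
    expect_error(studentsT(c(2, 2, 2), c(2, 2, 2)), "degenerate")
})

test_that("t is antisymmetric and invariant to shift and scale", {
    set.seed(3)
    a <- rnorm(10, 5); b <- rnorm(12, 6)
    ab <- studentsT(a, b); ba <- studentsT(b, a)
    expect_equal(ab$t, -ba$t)
    expect_equal(ab$p, ba$p)
    shifted <- studentsT(a + 100, b + 100)
    expect_equal(shifted$t, ab$t, tolerance = 1e-9)
    scaled <- studentsT(3 * a, 3 * b)
    expect_equal(scaled$t, ab$t, tolerance = 1e-9)
    expect_equal(scaled$p, ab$p, tolerance = 1e-9)
})

test_that("significance stars use strict thresholds", {
    expect_equal(significanceStars(0.2), "")
    expect_equal(significanceStars(0.05), "")   # boundary: strict
    expect_equal(significanceStars(0.04), "*")
    expect_equal(significanceStars(0.01), "*")  # boundary: strict
    expect_equal(significanceStars(0.005), "**")
    expect_equal(significanceStars(0.001), "**")  # boundary: strict
    expect_equal(significanceStars(0.0005), "***")
    expect_equal(significanceStars(c(0.2, 0.04, 0.0005)), c("", "*", "***"))
    expect_error(significanceStars(1.2), "\\[0, 1\\]")
    expect_error(significanceStars(-0.1), "\\[0, 1\\]")
})

test_that("group summaries report mean, sample SD, N and starred comparisons", {
    set.seed(4)
    df <- data.frame(condition = rep(c("control", "treated"), each = 6),
                     ratio = c(rnorm(6, 2.0, 0.1), rnorm(6, 1.2, 0.1)))
    out <- summarizeGroups(df, "ratio")
    expect_equal(out$summary$n, c(6L, 6L))
    expect_equal(out$summary$sd[1],
                 sd(df$ratio[df$condition == "control"]))
    expect_equal(nrow(out$comparisons), 1L)
    expect_equal(out$comparisons$stars, "***")

    # identical groups: no stars
    df2 <- data.frame(condition = rep(c("a", "b"), each = 4),
                      v = rep(c(1, 2, 3, 4), 2))
    expect_equal(summarizeGroups(df2, "v")$comparisons$stars, "")

    # a single condition yields the summary only
    one <- summarizeGroups(df[df$condition == "control", ], "ratio")
    expect_equal(nrow(one$comparisons), 0L)

    # vs-control mode compares every group against the control
    df3 <- rbind(df, data.frame(condition = "late", ratio = rnorm(6, 1.5, 0.1)))
    vc <- summarizeGroups(df3, "ratio", mode = "vs-control",
                          control = "control")
    expect_equal(nrow(vc$comparisons), 2L)
    expect_true(all(vc$comparisons$group_a == "control"))
    expect_error(summarizeGroups(df3, "ratio", mode = "vs-control",
                                 control = "nope"), "control")
})

test_that("a strong ratio difference is detected at full study size", {
    # 140 cells/condition (14 fields of 10 cells), ratios 2.0 vs 1.2
    detected <- vapply(1:8, function(rep) {
        base <- 5000L + rep * 100L
        ratios <- lapply(c(control = 2.0, treated = 1.2), function(r) {
            unlist(lapply(1:14, function(f) {
                tr <- ImageGroundTruth(seed = base + f +
                                           ifelse(r == 1.2, 50L, 0L),
                                       nCells = 10L, nucleusRadius = 18,
                                       nucleolusRadius = 5,
                                       imageShape = c(256L, 256L),
                                       trueRatio = r)
                quantifyField(generateNucleiImage(tr)$channels)$measurements$ratio
            }))
        })
        studentsT(ratios$control, ratios$treated)$p < 0.001
    }, logical(1))
    expect_true(all(detected))
})
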