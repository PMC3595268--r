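# a hand-built two-cell field: labels from rasterized disks, no rendering
twoCellMasks <- function(shape = c(96L, 96L)) {
    disk <- nucleoFRAP:::rasterDisk
    lab <- matrix(0L, shape[1], shape[2])
    lab[disk(shape, c(25, 25), 15)] <- 1L
    lab[disk(shape, c(65, 65), 15)] <- 2L
    nuo <- disk(shape, c(25, 25), 5) | disk(shape, c(65, 65), 5)
    LabeledMasks(lab, nuo)
}

test_that("subset Otsu threshold maximizes the between-class variance", {
    # independent oracle: exhaustive search over every candidate split
    set.seed(1)
    x <- c(rnorm(3000, 40, 5), rnorm(1096, 160, 10))
    mine <- otsuThreshold(x)
    cand <- sort(unique(x))
    between <- vapply(cand[-length(cand)], function(th) {
        a <- x[x <= th]; b <- x[x > th]
        length(a) * length(b) / length(x)^2 * (mean(a) - mean(b))^2
    }, numeric(1))
    best <- cand[which.max(between)]
    binWidth <- diff(range(x)) / 256
    expect_lt(abs(mine - best), 2 * binWidth)
    expect_error(otsuThreshold(rep(3, 10)), "uniform")
})

test_that("nuclear segmentation recovers the rendered nuclei", {
    field <- generateNucleiImage(ImageGroundTruth(seed = 3L, nCells = 20L))
    lab <- nuclearMask(field$channels$dna)
    expect_equal(max(lab), 20L)
    # per-nucleus Jaccard vs ground-truth disks >= 0.9
    truthLab <- field$truthMasks$nuclearLabels
    for (k in 1:20) {
        truthK <- truthLab == k
        segLabel <- as.integer(names(which.max(table(lab[truthK]))))
        expect_gt(maskOverlap(lab == segLabel, truthK)["jaccard"], 0.9)
    }
    expect_error(nuclearMask(matrix(0, 64, 64)), "zero variance")
})

test_that("per-nucleus nucleolar segmentation recovers the marker disks", {
    # ratio marker:background 5:1 via a nonzero marker floor, noise-free
    field <- generateNucleiImage(smallFieldTruth(seed = 6L, noiseSd = 0))
    marker <- field$channels$marker + 100  # floor 100, nucleoli 600
    lab <- nuclearMask(field$channels$dna)
    masks <- nucleolarMask(marker, lab)
    expect_gt(maskOverlap(masks@nucleolarMask,
                          field$truthMasks$nucleolarMask)["jaccard"], 0.8)
    # every component assigned to the nucleus that contains it
    expect_true(all(masks@assignment$cell %in% seq_len(max(lab))))

    # a uniform-marker nucleus is flagged; the others are unaffected
    markerU <- marker
    markerU[lab == 1L] <- 100
    masksU <- nucleolarMask(markerU, lab)
    expect_true(1L %in% masksU@flaggedCells)
    expect_false(any(masksU@nucleolarMask & lab == 1L))
    others <- lab > 1L
    expect_identical(masksU@nucleolarMask[others], masks@nucleolarMask[others])

    # no nuclei: vacuous output
    empty <- nucleolarMask(marker, matrix(0L, nrow(marker), ncol(marker)))
    expect_equal(sum(empty@nucleolarMask), 0)
    expect_equal(nrow(empty@assignment), 0L)
})

test_that("mask overlap reports all three candidate metrics", {
    a <- matrix(FALSE, 10, 10); a[2:6, 2:6] <- TRUE
    expect_equal(unname(maskOverlap(a, a)), c(1, 1, 1))
    b <- matrix(FALSE, 10, 10); b[8:9, 8:9] <- TRUE
    expect_equal(unname(maskOverlap(a, b)), c(0, 0, 0))
    # A strictly inside B with |A| = 50, |B| = 100
    bigB <- matrix(FALSE, 20, 20); bigB[1:10, 1:10] <- TRUE
    inA <- matrix(FALSE, 20, 20); inA[1:5, 1:10] <- TRUE
    expect_equal(unname(maskOverlap(inA, bigB)), c(1.0, 0.5, 0.5))
    expect_error(maskOverlap(a, matrix(FALSE, 5, 5)), "dimensions")
})

test_that("compartment ratios are exact without blur and noise", {
    f <- generateNucleiImage(smallFieldTruth(seed = 5L, nCells = 1L,
                                             trueRatio = 3, blurSigma = 0,
                                             noiseSd = 0))
    q <- quantifyField(f$channels)
    expect_equal(q$measurements$ratio, 3, tolerance = 1e-12)

    # multiplicative rescaling of the target channel leaves ratios intact
    q7 <- compartmentRatio(7 * f$channels$target, q$masks)
    expect_equal(q7$ratio, q$measurements$ratio, tolerance = 1e-12)
})

test_that("compartment ratios recover ground truth under blur and noise", {
    f <- generateNucleiImage(ImageGroundTruth(seed = 21L, trueRatio = 2.5))
    q <- quantifyField(f$channels)
    expect_equal(nrow(q$measurements), 20L)
    expect_lt(abs(mean(q$measurements$ratio) - 2.5) / 2.5, 0.1)

    # ratio 1 is recovered as 1 regardless of segmentation quality
    f1 <- generateNucleiImage(ImageGroundTruth(seed = 22L, trueRatio = 1))
    q1 <- quantifyField(f1$channels)
    expect_true(all(abs(q1$measurements$ratio - 1) < 0.02))
})

test_that("nucleolar and nucleoplasmic pixels partition the nucleus", {
    f <- generateNucleiImage(smallFieldTruth(seed = 9L))
    q <- quantifyField(f$channels)
    m <- q$measurements
    lab <- q$masks@nuclearLabels
    for (k in m$cell_id) {
        nucleolar <- sum(lab == k & q$masks@nucleolarMask)
        nucleoplasm <- sum(lab == k & !q$masks@nucleolarMask)
        expect_equal(nucleolar + nucleoplasm, m$nuclear_area_px[m$cell_id == k])
        expect_equal(nucleolar, m$nucleolar_area_px[m$cell_id == k])
    }
})

test_that("nucleolar areas match an independent rasterization count", {
    # frozen oracle: numpy pixel count of a radius-5 disk at an integer
    # center is 81
    disk <- nucleoFRAP:::rasterDisk
    shape <- c(64L, 64L)
    lab <- matrix(0L, 64, 64)
    lab[disk(shape, c(30, 30), 15)] <- 1L
    masks <- LabeledMasks(lab, disk(shape, c(30, 30), 5))
    areas <- nucleolarArea(masks)
    expect_equal(areas$nucleolar_area_px, 81L)

    # no nucleoli: zero area
    areas0 <- nucleolarArea(LabeledMasks(lab, matrix(FALSE, 64, 64)))
    expect_equal(areas0$nucleolar_area_px, 0L)

    # two cells with identical geometry have identical areas
    m2 <- twoCellMasks()
    a2 <- nucleolarArea(m2)
    expect_equal(a2$nucleolar_area_px[1], a2$nucleolar_area_px[2])
    expect_equal(a2$nuclear_area_px[1], a2$nuclear_area_px[2])
})

test_that("nuclear mean intensities are exact and linear", {
    m2 <- twoCellMasks()
    uni <- matrix(5.5, 96, 96)
    expect_equal(nuclearMeanIntensity(uni, m2)$nuclear_mean, c(5.5, 5.5))
    set.seed(2)
    ch <- matrix(runif(96 * 96, 10, 60), 96, 96)
    expect_equal(nuclearMeanIntensity(2 * ch, m2)$nuclear_mean,
                 2 * nuclearMeanIntensity(ch, m2)$nuclear_mean)
})

test_that("cells with empty nucleolar sets get rows with missing ratios", {
    m2 <- twoCellMasks()
    # strip cell 2's nucleoli
    nuo <- m2@nucleolarMask & m2@nuclearLabels == 1L
    masks <- LabeledMasks(m2@nuclearLabels, nuo)
    target <- matrix(10, 96, 96)
    target[m2@nuclearLabels > 0] <- 50
    meas <- compartmentRatio(target, masks, subtractBackground = FALSE)
    expect_equal(nrow(meas), 2L)
    expect_false(is.na(meas$ratio[1]))
    expect_true(is.na(meas$ratio[2]))
})
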