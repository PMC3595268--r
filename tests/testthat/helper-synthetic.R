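# shared fixtures, built in code

# noiseless control-like FRAP truth; seed irrelevant without noise
noiselessTruth <- function(m = 0.89, h = 4.3, lambda = 0, nPost = 97L,
                           seed = 1L, ...) {
    FrapGroundTruth(seed = seed, mobileFraction = m, halfTime = h,
                    monitorBleachRate = lambda, noiseSd = 0,
                    nPost = nPost, ...)
}

# small field that segments quickly
smallFieldTruth <- function(seed, trueRatio = 2.5, nCells = 5L,
                            blurSigma = 1, noiseSd = 2, ...) {
    ImageGroundTruth(seed = seed, nCells = nCells, nucleusRadius = 18,
                     nucleolusRadius = 5, imageShape = c(160L, 160L),
                     trueRatio = trueRatio, blurSigma = blurSigma,
                     noiseSd = noiseSd, ...)
}

# build a minimal valid NormalizedCurve with given exact summary intensities
curveWith <- function(fPost, fEnd, nPostFrames = 10L) {
    value <- c(1, 1, 1, fPost, rep(fEnd, nPostFrames - 1L))
    new("NormalizedCurve", timeS = seq_along(value) - 4, value = value,
        nPre = 3L, fPre = 1, fPost = fPost, fEnd = fEnd,
        endWindow = 3L, preLevel = 100)
}
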