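## Shared noiseless calibration fixture: Hill fits of densely sampled
## truth curves (recovered essentially exactly; see the calibration test).
.calFixture <- local({
  truth <- ipeaqTruthCurves()
  ca <- 10^seq(log10(2.5), log10(25000), length.out = 12)
  function() fitCalibrations(ca, hillEval(truth$contrastCurve, ca),
                             hillEval(truth$fluorCurve, ca))
})

test_that("cycle detection measures the photochromism contrast", {
  ## square wave: 1.2 under violet relaxing instantly to 1.0
  t <- seq(0, 30, by = 0.1)
  violet <- (t %% 10) < 2.5
  f <- ifelse(violet, 1.2, 1.0)
  cyc <- detectCycles(PhotochromicTrace(t, f, violet))
  expect_equal(nrow(cyc), 3)
  expect_equal(cyc$contrast, rep(1 / 6, 3), tolerance = 1e-9)
  expect_true(all(cyc$complete))

  ## no photochromism (Ca-saturated limit): contrast 0
  cyc0 <- detectCycles(PhotochromicTrace(t, rep(1, length(t)), violet))
  expect_equal(cyc0$contrast, rep(0, 3))

  ## no violet epoch at all
  expect_error(detectCycles(PhotochromicTrace(t, f, rep(FALSE, length(t)))),
               "no violet epoch")
})

test_that("generated cycles reproduce the contrast ground truth", {
  ## [Ca2+] chosen so the truth contrast curve gives exactly 0.40;
  ## inter-cycle gaps are 15 relaxation time constants
  truth <- ipeaqTruthCurves()
  caAt <- as.numeric(hillInverse(truth$contrastCurve, 0.40))
  tr <- genPhotochromic(caTruth = caAt, nCycles = 5, tau = 0.5,
                        noiseCv = 0)
  cyc <- detectCycles(tr)
  expect_equal(nrow(cyc), 5)
  expect_equal(mean(cyc$contrast), 0.40, tolerance = 0.01)
})

test_that("dual calibration fits recover the generating curves", {
  cal <- .calFixture()
  truth <- ipeaqTruthCurves()
  for (nm in c("contrastCurve", "fluorCurve")) {
    got <- slot(cal, nm); want <- truth[[nm]]
    expect_equal(kd(got), kd(want), tolerance = 1e-4)
    expect_equal(hillCoef(got), hillCoef(want), tolerance = 1e-4)
    expect_equal(got@y0, want@y0, tolerance = 1e-4)
    expect_equal(got@yInf, want@yInf, tolerance = 1e-4)
  }

  ca <- 10^seq(0, 4, length.out = 8)
  ## contrast flat in [Ca2+]: unidentifiable
  expect_error(fitCalibrations(ca, rep(0.4, 8), hillValue(ca, 1, 30, 250, 1)),
               "nidentifiable")
  ## increasing contrast violates the stated monotonicity
  expect_error(fitCalibrations(ca, hillValue(ca, 0.05, 0.6, 250, 1),
                               hillValue(ca, 1, 30, 250, 1)),
               "orientation")
})

test_that("quantification has a fixed point at the basal state", {
  cal <- .calFixture()
  tr <- genPhotochromic(caTruth = 100, gain = 1, noiseCv = 0)
  q <- quantifyCalcium(tr, cal, settle = 2.5)
  expect_equal(q$basalCa, 100, tolerance = 1e-3)
  expect_equal(q$k, 1, tolerance = 1e-3)
  settled <- !is.na(q$ca)
  expect_true(any(settled))
  expect_equal(q$ca[settled], rep(100, sum(settled)), tolerance = 1e-3)
})

test_that("quantification is invariant to detector gain", {
  cal <- .calFixture()
  caF <- function(t) 100 + 900 * (t >= 55) * (1 - exp(-(t - 55) / 2))
  tr <- genPhotochromic(caTruth = caF, gain = 1, noiseCv = 0)
  q1 <- quantifyCalcium(tr, cal, stimStart = 50, settle = 2.5)
  for (g in c(0.01, 3.7, 1e4)) {
    trg <- tr; trg@f <- tr@f * g
    qg <- quantifyCalcium(trg, cal, stimStart = 50, settle = 2.5)
    ok <- !is.na(q1$ca)
    expect_equal(qg$ca[ok], q1$ca[ok], tolerance = 1e-9)
    expect_equal(qg$basalCa, q1$basalCa, tolerance = 1e-9)
  }
})

test_that("quantification round-trips the ground-truth [Ca2+](t)", {
  cal <- .calFixture()
  caF <- function(t) 100 + 900 * (t >= 55) * (1 - exp(-(t - 55) / 2))

  ## noiseless: within 1% pointwise after the cycles have settled
  tr <- genPhotochromic(caTruth = caF, gain = 2.5, noiseCv = 0)
  q <- quantifyCalcium(tr, cal, stimStart = 50, settle = 2.5)
  post <- which(tr@time > 50 & !is.na(q$ca))
  relErr <- abs(q$ca[post] - tr@truth$ca[post]) / tr@truth$ca[post]
  expect_lt(max(relErr), 0.01)

  ## CV = 0.02 noise, 50 seeds: basal and the release peak (the plateau
  ## of this saturating transient, averaged over its final 5 s to keep the
  ## peak estimate itself unbiased) recovered within 10%
  errs <- t(vapply(1:50, function(s) {
    trn <- genPhotochromic(caTruth = caF, gain = 2.5, noiseCv = 0.02,
                           seed = s)
    qn <- quantifyCalcium(trn, cal, stimStart = 50, settle = 2.5)
    plat <- which(trn@time > max(trn@time) - 5 & !is.na(qn$ca))
    peakHat <- mean(qn$ca[plat])
    peakTrue <- mean(trn@truth$ca[plat])
    c(abs(qn$basalCa - 100) / 100, abs(peakHat - peakTrue) / peakTrue)
  }, numeric(2)))
  expect_lt(stats::median(errs[, 1]), 0.10)
  expect_lt(stats::median(errs[, 2]), 0.10)
})

test_that("out-of-calibration basal contrast is refused", {
  cal <- .calFixture()
  ## zero-Ca limit: contrast sits on the upper plateau, not invertible
  tr <- genPhotochromic(caTruth = 0.001, noiseCv = 0)
  expect_error(quantifyCalcium(tr, cal), "out-of-calibration")
})

test_that("calibrations survive a JSON save/load round trip", {
  cal <- .calFixture()
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  saveCalibration(cal, tmp)
  cal2 <- loadCalibration(tmp)
  expect_equal(kd(cal2@contrastCurve), kd(cal@contrastCurve))
  expect_equal(cal2@fluorCurve@yInf, cal@fluorCurve@yInf)
})
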