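test_that("dF/F0 is the baseline-normalized fluorescence change", {
  t <- seq(0, 10, by = 0.1)

  ## constant trace: all zeros
  tr <- FluorescenceTrace(t, rep(100, length(t)), baselineWindow = c(0, 1),
                          stimOnsets = 2)
  expect_equal(as.numeric(deltaFOverF(tr)), rep(0, length(t)))

  ## F0 = 100, peak F = 300: peak dF/F0 = 2
  f <- rep(100, length(t)); f[t >= 2 & t < 3] <- 300
  tr2 <- FluorescenceTrace(t, f, baselineWindow = c(0, 1), stimOnsets = 2)
  expect_equal(max(deltaFOverF(tr2)), 2)

  ## generator ground truth: single AP peaks at kernelAmp / F0
  ap <- genAPTrain(nAp = 1, kernelAmp = 20, f0 = 100, noiseCv = 0)
  expect_equal(max(deltaFOverF(ap)), 20 / 100, tolerance = 1e-3)

  ## gain invariance; baseline shifts act only through F0
  tr3 <- FluorescenceTrace(t, 7 * f, baselineWindow = c(0, 1),
                           stimOnsets = 2)
  expect_equal(as.numeric(deltaFOverF(tr3)), as.numeric(deltaFOverF(tr2)))

  ## non-positive baseline is an error
  trBad <- FluorescenceTrace(t, f - 100, baselineWindow = c(0, 1),
                             stimOnsets = 2)
  expect_error(deltaFOverF(trBad), "baseline")
})

test_that("peak SNR decomposes exactly as peak SBR over baseline SD", {
  ap <- genAPTrain(nAp = 1, kernelAmp = 200, f0 = 100, noiseCv = 0.01,
                   seed = 11)
  s <- peakSNR(ap)
  expect_equal(s$peakSNR, s$peakSBR / s$sdBaseline)
  expect_gt(s$peakSNR, 10)

  ## noiseless trace: infinite SNR flagged, not thrown
  ap0 <- genAPTrain(nAp = 1, noiseCv = 0)
  expect_warning(s0 <- peakSNR(ap0), "zero baseline variance")
  expect_true(is.infinite(s0$peakSNR))
  expect_true(s0$zeroBaselineSD)
})

test_that("doubling the noise amplitude halves the expected peak SNR", {
  snrAt <- function(cv, seed)
    suppressWarnings(peakSNR(genAPTrain(nAp = 1, kernelAmp = 200,
                                        f0 = 100, noiseCv = cv,
                                        seed = seed))$peakSNR)
  s1 <- vapply(1:100, function(s) snrAt(0.005, s), numeric(1))
  s2 <- vapply(1:100, function(s) snrAt(0.010, s), numeric(1))
  expect_equal(mean(s1) / mean(s2), 2, tolerance = 0.1)
})

test_that("half-decay time is ln2 times the decay constant", {
  ## pure exponential with tau = 1 s from the peak
  t <- seq(0, 11, by = 0.02)
  f <- 100 * (1 + ifelse(t >= 1, 2 * exp(-(t - 1)), 0))
  tr <- FluorescenceTrace(t, f, baselineWindow = c(0, 1), stimOnsets = 1)
  hd <- halfDecayTime(tr, responseWindow = 8)
  expect_equal(as.numeric(hd), log(2), tolerance = 1e-3)

  ## generator with half-decay 409 ms (tau 0.59 s): recovered within 1%
  ap <- genAPTrain(nAp = 1, decayHalfMs = 409, noiseCv = 0)
  hd2 <- halfDecayTime(ap, responseWindow = 4)
  expect_equal(as.numeric(hd2), 0.409, tolerance = 0.01)

  ## invariance to amplitude and offset in the noiseless limit
  f3 <- 40 * (0.5 + ifelse(t >= 1, 5 * exp(-(t - 1)), 0))
  tr3 <- FluorescenceTrace(t, f3, baselineWindow = c(0, 1), stimOnsets = 1)
  expect_equal(as.numeric(halfDecayTime(tr3, responseWindow = 8)), log(2),
               tolerance = 1e-3)

  ## nonzero offset plus noise: unbiased tau recovery
  errs <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    fo <- 100 * (1 + ifelse(t >= 1, 2 * exp(-(t - 1)) + 0.3, 0)) *
      (1 + rnorm(length(t), 0, 0.01))
    tro <- FluorescenceTrace(t, fo, baselineWindow = c(0, 1),
                             stimOnsets = 1)
    abs(attr(halfDecayTime(tro, responseWindow = 8), "tau") - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.03)
})

test_that("ratiometric division cancels common multiplicative artifacts", {
  t <- seq(0, 20, by = 0.05)
  onset <- 5
  resp <- ifelse(t >= onset, 1.5 * exp(-(t - onset) / 2), 0)

  ## constant reference: ratio proportional to the signal
  sig <- FluorescenceTrace(t, 100 * (1 + resp), baselineWindow = c(3, 4),
                           stimOnsets = onset)
  ref <- FluorescenceTrace(t, rep(50, length(t)))
  rat <- ratiometric(sig, ref)
  expect_equal(rat@f, sig@f / 50)

  ## common motion artifact m(t) cancels exactly
  m <- 0.3 * sin(2 * pi * t / 3)
  sigM <- FluorescenceTrace(t, 100 * (1 + resp) * (1 + m),
                            baselineWindow = c(3, 4), stimOnsets = onset)
  refM <- FluorescenceTrace(t, 50 * (1 + m))
  ratM <- ratiometric(sigM, refM)
  expect_equal(ratM@f, 2 * (1 + resp), tolerance = 1e-9)

  ## anticorrelated channels amplify: signal x k, reference / j at the
  ## event makes the ratio change (k*j - 1) > (k - 1)
  k <- 2; j <- 1.7
  up <- ifelse(t >= onset & t < onset + 5, k, 1)
  dn <- ifelse(t >= onset & t < onset + 5, 1 / j, 1)
  sigA <- FluorescenceTrace(t, 100 * up, baselineWindow = c(3, 4),
                            stimOnsets = onset)
  refA <- FluorescenceTrace(t, 50 * dn)
  dR <- deltaFOverF(ratiometric(sigA, refA))
  expect_equal(max(dR), k * j - 1, tolerance = 1e-9)
  expect_gt(max(dR), max(deltaFOverF(sigA)))

  ## a reference crossing zero is an error
  refBad <- FluorescenceTrace(t, 50 - 10 * t)
  expect_error(ratiometric(sig, refBad), "channel")
})

test_that("responsive-cell test is a two-sample Student t-test at 0.01", {
  ## identical stimulus and baseline values: p = 1, not responsive
  r <- responsiveCellTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p, 1)
  expect_false(r$responsive)

  ## agrees with the reference implementation
  set.seed(42)
  a <- rnorm(6, 1); b <- rnorm(6)
  expect_equal(responsiveCellTest(a, b)$p,
               stats::t.test(a, b, var.equal = TRUE)$p.value)

  ## single trial: insufficient replication
  expect_error(responsiveCellTest(1, c(1, 2)), "replication")

  ## power: a 5-SD effect over 6 trials is detected in >= 99% of runs
  hits <- vapply(1:1000, function(s) {
    set.seed(s)
    responsiveCellTest(rnorm(6, 5, 1), rnorm(6, 0, 1))$responsive
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
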