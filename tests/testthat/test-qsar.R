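test_that("an exactly linear response is recovered perfectly", {
  tab <- syntheticDescriptorTable(seed = 11, noise_sd = 0)
  m <- fitQsar(tab, c("d", "S_vdW", "S_wat", "A_vdW", "mu_D"),
               mode = "new-compound")
  truth <- sigmaqsar:::syntheticDefaults()
  expect_equal(unname(m@coefficients[-1]),
               unname(truth$coefficients[m@descriptors]), tolerance = 1e-8)
  expect_equal(unname(m@coefficients[1]), truth$intercept, tolerance = 1e-8)
  expect_equal(m@R2, 1)
  expect_equal(m@RMSE, 0, tolerance = 1e-8)
  expect_true(is.infinite(m@F))
  expect_equal(max(abs(m@residuals)), 0, tolerance = 1e-8)
})

test_that("degenerate designs are rejected with informative errors", {
  tab <- syntheticDescriptorTable(seed = 2)
  tab$S_dup <- tab$S_vdW
  expect_error(fitQsar(tab, c("S_vdW", "S_dup", "d")), "collinear")
  expect_error(fitQsar(tab[1:4, ], c("S_vdW", "A_vdW", "S_wat")), "N > k")
  expect_error(fitQsar(tab, c("nope", "S_vdW")), "not in table")
})

test_that("model statistics match their defining formulas", {
  t4 <- fixtureTable4()
  m <- fitQsar(t4, c("S_vdW", "A_vdW", "S_wat"))
  y <- t4$dG_exp
  sse <- sum(m@residuals^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(m@R2, 1 - sse / sst, tolerance = 1e-12)
  expect_equal(m@RMSE, sqrt(sse / 14), tolerance = 1e-12)
  ## F from R2 agrees with the sums-of-squares form to relative 1e-10
  f_ss <- (sst - sse) / m@k / (sse / (m@N - m@k - 1))
  expect_equal(m@F, f_ss, tolerance = 1e-10)
  ## residual orthogonal to every design column
  X <- cbind(1, as.matrix(t4[, m@descriptors]))
  expect_lt(max(abs(crossprod(X, m@residuals))) / max(abs(X)), 1e-8)
  expect_equal(mean(m@residuals), 0, tolerance = 1e-10)
})

test_that("the RMSE convention divides by N, as the tabulated fit does", {
  ## hand-summed oracle over the 14 printed residuals: SSE = 3.697 (after
  ## correcting the one printed sign slip, whose square is unaffected)
  t4 <- fixtureTable4()
  sse_printed <- sum(t4$dG_res^2)
  expect_equal(sse_printed, 3.697, tolerance = 0.005)
  expect_equal(sqrt(sse_printed / 14), 0.514, tolerance = 0.002)
  ## and the printed residual column implies R2 = 0.77 with SST from the
  ## printed response column
  sst <- sum((t4$dG_exp - mean(t4$dG_exp))^2)
  expect_equal(round(1 - sse_printed / sst, 2), 0.77)
  ## F recomputed from the 2-dp R2: 11.16, printed as 11.2
  expect_equal(round(fStatistic(0.77, 3, 14), 1), 11.2)
})

test_that("prediction and residuals satisfy their identities", {
  t4 <- fixtureTable4()
  m <- fitQsar(t4, c("S_vdW", "A_vdW", "d"))
  expect_equal(predict(m, t4), unname(m@fitted))
  expect_equal(residualAffinity(t4$dG_exp, predict(m, t4)),
               unname(m@residuals))
  expect_equal(residualAffinity(1.5, 1.5), 0)
})

test_that("exhaustive subset search agrees with a brute-force oracle", {
  t4 <- fixtureTable4()
  search <- subsetSearch(t4, k = 3)
  expect_length(search, choose(5, 3))
  ## independent oracle: enumerate subsets with plain lm and rank by R2
  descr <- sort(c("d", "S_vdW", "S_wat", "A_vdW", "mu_D"))
  sets <- combn(descr, 3, simplify = FALSE)
  r2 <- vapply(sets, function(s)
    summary(lm(reformulate(s, "dG_exp"), t4))$r.squared, numeric(1))
  oracle <- sets[order(-r2, vapply(sets, paste, character(1),
                                   collapse = ","))]
  got <- lapply(search, function(m) m@descriptors)
  expect_equal(got, oracle)
  expect_equal(attr(search, "ranking")$R2, sort(r2, decreasing = TRUE),
               tolerance = 1e-12)
  ## k = 5 collapses to the single full model
  all5 <- subsetSearch(t4, k = 5)
  expect_length(all5, 1L)
  expect_equal(all5[[1]]@descriptors, descr)
})

test_that("leave-one-out cross-validation behaves canonically", {
  perfect <- syntheticDescriptorTable(seed = 5, noise_sd = 0)
  cv <- looCv(perfect, c("d", "S_vdW", "S_wat", "A_vdW", "mu_D"))
  expect_equal(cv$Q2, 1, tolerance = 1e-8)
  ## Q2 <= R2 on the reference table
  t4 <- fixtureTable4()
  m <- fitQsar(t4, c("S_vdW", "A_vdW", "S_wat"))
  cvf <- looCv(t4, c("S_vdW", "A_vdW", "S_wat"))
  expect_lte(cvf$Q2, m@R2)
  ## pure-noise response at large n has no held-out predictivity
  q2s <- vapply(1:20, function(s) {
    tab <- syntheticDescriptorTable(n = 60, seed = 100 + s, noise_sd = 1,
                                    coefficients = c(d = 0, S_vdW = 0,
                                                     S_wat = 0, A_vdW = 0,
                                                     mu_D = 0))
    looCv(tab, c("S_vdW", "A_vdW", "S_wat"))$Q2
  }, numeric(1))
  expect_lte(mean(q2s), 0)
})

test_that("equation strings mirror the reporting format", {
  t4 <- fixtureTable4()
  m <- fitQsar(t4, c("S_vdW", "A_vdW", "S_wat"))
  s <- equationString(m)
  expect_match(s, "^dG = -?[0-9.]+ [+-] [0-9.]+\\*S_vdW")
  rep_ <- qsarReport(m, observed = t4$dG_exp)
  expect_equal(rep_$N, 14L)
  expect_equal(nrow(rep_$per_compound), 14L)
})
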