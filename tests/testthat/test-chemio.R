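test_that("registry holds the fourteen compounds with consistent series", {
  reg <- compoundRegistry()
  expect_equal(nrow(reg), 14L)
  expect_false(anyDuplicated(reg$id) > 0)
  prefix <- substr(reg$id, 1, 1)
  expect_equal(unname(c("7" = "ketone", "8" = "alcohol",
                        "9" = "amine")[prefix]), reg$series)
  can <- canonicalSmiles(reg$smiles)
  expect_false(anyNA(can))
})

molecularFormula <- function(topo) {
  tab <- table(topo$elements)
  ord <- c("C", "H", setdiff(sort(names(tab)), c("C", "H")))
  paste0(ord, ifelse(tab[ord] > 1, tab[ord], ""), collapse = "")
}

test_that("registry structures match the reported molecular formulas", {
  reg <- compoundRegistry()
  formulas <- vapply(reg$smiles, function(s)
    molecularFormula(sigmaqsar:::smilesTopology(s)), character(1), USE.NAMES = FALSE)
  ## spot checks against the reported exact masses' formulas
  expect_equal(formulas[reg$id == "7a"], "C19H19F2NO")
  expect_equal(formulas[reg$id == "7e"], "C19H19BrFNO")
  expect_equal(formulas[reg$id == "8f"], "C20H24FNO")
  expect_equal(formulas[reg$id == "9e"], "C26H27Br2FN2")
})

test_that("every registry compound has exactly one ring amine nitrogen", {
  reg <- compoundRegistry()
  for (i in seq_len(nrow(reg))) {
    topo <- sigmaqsar:::smilesTopology(reg$smiles[i])
    info <- sigmaqsar:::analyzeTopology(topo)
    ringN <- 0L
    for (rg in info$rings[!info$aromatic]) {
      if (length(rg) == 6L) {
        ringN <- ringN + sum(topo$elements[rg] == "N")
      }
    }
    expect_equal(ringN, 1L, info = reg$id[i])
  }
})

test_that("binding table parses censoring and discards uncertainties", {
  b <- fixtureBinding()
  expect_equal(nrow(b), 14L)
  r7e <- b[b$compound == "7e", ]
  expect_equal(r7e$sigma1_ki, 1.40)
  expect_false(r7e$sigma1_censored)
  expect_equal(r7e$sigma2_ki, 854)
  expect_true(r7e$sigma2_censored)
  expect_equal(r7e$ratio_printed, 610L)
  r7b <- b[b$compound == "7b", ]
  expect_true(r7b$sigma1_censored && r7b$sigma2_censored)
  expect_equal(c(r7b$sigma1_ki, r7b$sigma2_ki), c(434, 854))
  ## 8d is above the sigma-1 ceiling yet reported exact: trust the table
  expect_false(b$sigma1_censored[b$compound == "8d"])
})

test_that("binding table loader rejects degenerate input", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("compound,sigma1_ki,sigma2_ki,ratio", empty)
  expect_error(loadBindingTable(empty), "no rows")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,sigma1_ki,sigma2_ki,ratio", "x1,>>4,10,2"), bad)
  expect_error(loadBindingTable(bad), "malformed")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,sigma1_ki,sigma2_ki,ratio", "x1,-2,10,2"), neg)
  expect_error(loadBindingTable(neg), "non-positive")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,sigma1_ki,sigma2_ki,ratio",
               "x1,2,10,5", "x1,3,10,3"), dup)
  expect_error(loadBindingTable(dup), "duplicate")
})

test_that("descriptor table satisfies its invariants on load", {
  t4 <- fixtureTable4()
  expect_equal(nrow(t4), 14L)
  r7a <- t4[t4$compound == "7a", ]
  expect_equal(unlist(r7a[c("d", "S_vdW", "S_wat", "A_vdW", "mu_D",
                            "dG_exp", "dG_pred", "dG_res")], use.names = FALSE),
               c(1.03, 328.65, 550.09, 304.36, 1.55, -0.47, -1.02, 0.55))
  expect_equal(t4$dG_res[t4$compound == "9e"], 0.02)
  expect_true(all(t4$S_wat > t4$S_vdW))
  expect_true(all(t4$A_vdW < t4$S_wat))
  ## residual identity (8f's printed sign slip aside, handled by the loader)
  ok <- t4$compound != "8f"
  expect_true(all(abs(t4$dG_res - (t4$dG_exp - t4$dG_pred))[ok] <= 0.01))
})

test_that("descriptor table loader reports violations by row", {
  t4 <- fixtureTable4()
  bad <- t4
  bad$dG_res[bad$compound == "7c"] <- 9.99
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, f, row.names = FALSE)
  expect_error(suppressWarnings(loadDescriptorTable(f)), "7c")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(t4[1:5, ], f2, row.names = FALSE)
  expect_error(suppressWarnings(loadDescriptorTable(f2, expected_rows = 14L)),
               "expected 14 rows")
})

test_that("structure files round-trip through SMILES and SDF", {
  reg <- compoundRegistry()
  smi <- withr::local_tempfile(fileext = ".smi")
  writeStructures(reg, smi, format = "smiles")
  back <- readStructures(smi, format = "smiles")
  expect_equal(back$id, reg$id)
  expect_equal(back$smiles, canonicalSmiles(reg$smiles))

  sdf <- withr::local_tempfile(fileext = ".sdf")
  writeStructures(reg, sdf, format = "sdf")
  back2 <- readStructures(sdf, format = "sdf")
  expect_equal(back2$id, reg$id)
  expect_equal(back2$smiles, canonicalSmiles(reg$smiles))
})

test_that("unparsable records are skipped with a warning, empty input is ok", {
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "C1CC broken", "c1ccccc1 benzene"), smi)
  expect_warning(got <- readStructures(smi, format = "smiles"),
                 "1 unparsable")
  expect_equal(got$id, c("ethanol", "benzene"))

  empty <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(0), empty)
  expect_equal(nrow(readStructures(empty, format = "smiles")), 0L)
})
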