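test_that("van der Waals radii are the Bondi set", {
  expect_equal(vdwRadius("C"), 1.70)
  expect_equal(vdwRadius("Br"), 1.85)
  expect_equal(vdwRadius(c("N", "O", "H", "F", "Cl")),
               c(1.55, 1.52, 1.20, 1.47, 1.75))
  expect_error(vdwRadius("Xx"), "no van der Waals radius")
})

test_that("embedding is deterministic for a fixed compound and seed", {
  c1 <- embedConformer("7e", seed = 7)
  c2 <- embedConformer("7e", seed = 7)
  expect_identical(atomCoords(c1), atomCoords(c2))
  expect_identical(conformerProvenance(c1)$sub_seed,
                   conformerProvenance(c2)$sub_seed)
})

test_that("minimization lowers the force-field energy", {
  conf <- registryConformers()[["7a"]]
  prov <- conformerProvenance(conf)
  expect_lte(prov$energy, prov$energy_pre)
})

test_that("minimized geometries are physically sane", {
  for (id in c("7a", "8d", "9e")) {
    conf <- registryConformers()[[id]]
    xyz <- atomCoords(conf)
    b <- bondTable(conf)
    dB <- sqrt(rowSums((xyz[b[, 1], ] - xyz[b[, 2], ])^2))
    expect_true(all(dB > 0.7 & dB < 2.0), info = id)
    expect_true(all(is.finite(xyz)), info = id)
    ## atom count matches the parent formula with explicit hydrogens
    reg <- compoundRegistry()
    topo <- sigmaqsar:::smilesTopology(reg$smiles[reg$id == id])
    expect_equal(length(conf), length(topo$elements), info = id)
  }
})

test_that("small molecules embed to their idealized geometry", {
  methane <- embedConformer("C", seed = 1)
  xyz <- atomCoords(methane)
  ci <- which(atomElements(methane) == "C")
  hi <- which(atomElements(methane) == "H")
  dCH <- sqrt(rowSums(sweep(xyz[hi, ], 2, xyz[ci, ])^2))
  expect_true(all(abs(dCH - 1.09) < 0.03))
  pairs <- combn(hi, 2)
  angles <- apply(pairs, 2, function(p) {
    v1 <- xyz[p[1], ] - xyz[ci, ]; v2 <- xyz[p[2], ] - xyz[ci, ]
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  })
  expect_true(all(abs(angles - 109.47) < 2))

  benzene <- embedConformer("c1ccccc1", seed = 1)
  cidx <- which(atomElements(benzene) == "C")
  cen <- colMeans(atomCoords(benzene)[cidx, ])
  dd <- sqrt(rowSums(sweep(atomCoords(benzene)[cidx, ], 2, cen)^2))
  expect_true(all(abs(dd - 1.39) < 0.03))
})

test_that("chiral registry compounds embed with the drawn configuration", {
  reg <- compoundRegistry()
  for (id in c("8e", "9e")) {
    conf <- registryConformers()[[id]]
    got <- sigmaqsar:::conformerCanonicalSmiles(conf)
    expect_identical(got, canonicalSmiles(reg$smiles[reg$id == id]),
                     info = id)
  }
})

test_that("partial charges conserve the total formal charge", {
  conf <- assignPartialCharges(registryConformers()[["7f"]])
  expect_equal(sum(partialCharges(conf)), 0, tolerance = 1e-6)

  methane <- assignPartialCharges(embedConformer("C", seed = 1))
  q <- partialCharges(methane)
  el <- atomElements(methane)
  expect_lt(q[el == "C"], 0)
  expect_true(all(q[el == "H"] > 0))

  ## for an ion, use a scheme that honours the total charge
  cation <- assignPartialCharges(embedConformer("C[NH3+]", seed = 1),
                                 method = "eem")
  expect_equal(sum(partialCharges(cation)), 1, tolerance = 1e-6)

  expect_error(partialCharges(registryConformers()[["7f"]]),
               "no partial charges")
})

test_that("conformers survive an SDF round trip", {
  conf <- registryConformers()[["7c"]]
  txt <- sigmaqsar:::conformerToSdfText(conf)
  parsed <- sigmaqsar:::parseSdfBlock(txt)
  expect_equal(parsed$elements, atomElements(conf))
  expect_equal(parsed$coords, unname(atomCoords(conf)), tolerance = 1e-4)
  expect_equal(parsed$bonds[, 1:2], bondTable(conf)[, 1:2])
})
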