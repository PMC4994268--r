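test_that("feature atoms are identified on the ketone scaffold", {
  conf <- registryConformers()[["7e"]]
  f <- identifyFeatures(conf)
  el <- atomElements(conf)
  expect_equal(el[f$N], "N")
  expect_equal(el[f$secondary], "O")
  expect_equal(f$secondary_site, "oxygen")
  ## Ar2 is the aroyl (fluorine-bearing) ring, not the N-benzyl ring
  b <- bondTable(conf)
  ar2nbrs <- unique(c(b[b[, 1] %in% f$ar2, 2], b[b[, 2] %in% f$ar2, 1]))
  expect_true(any(el[ar2nbrs] == "F"))
  ar1nbrs <- unique(c(b[b[, 1] %in% f$ar1, 2], b[b[, 2] %in% f$ar1, 1]))
  expect_true(any(el[ar1nbrs] == "Br"))
})

test_that("molecules without the motif are rejected, amines are flagged", {
  benzene <- embedConformer("c1ccccc1", seed = 1)
  expect_error(identifyFeatures(benzene), "basic amine nitrogen")
  f9 <- identifyFeatures(registryConformers()[["9e"]])
  expect_equal(f9$secondary_site, "amine")
  m9 <- measurePharmacophore(conformer = registryConformers()[["9e"]])
  expect_equal(m9$secondary_site, "amine")
})

test_that("ring centroids are means with rigid-motion equivariance", {
  toys <- toyConformers()
  expect_equal(ringCentroid(toys$benzene, 1:6), c(0, 0, 0))
  moved <- toys$benzene
  moved@coords <- sweep(moved@coords, 2, c(1, 2, 3), "+")
  expect_equal(ringCentroid(moved, 1:6), c(1, 2, 3))
  benzene <- embedConformer("c1ccccc1", seed = 2)
  cidx <- which(atomElements(benzene) == "C")
  cen <- ringCentroid(benzene, cidx)
  dd <- sqrt(rowSums(sweep(atomCoords(benzene)[cidx, ], 2, cen)^2))
  expect_true(all(abs(dd - 1.39) < 0.03))
})

test_that("the carbonyl fragment matches the closed-form O-centroid oracle", {
  ## law of cosines on O=C(1.22) / C-Cipso(1.49) / ipso-centroid(1.39),
  ## 120-degree sp2 angle, substituent colinear with the ring axis
  oracle <- sqrt(1.22^2 + (1.49 + 1.39)^2 - 2 * 1.22 * (1.49 + 1.39) *
                   cos(2 * pi / 3))
  toys <- toyConformers()
  frag <- toys$benzoyl_fragment
  oi <- which(atomElements(frag) == "O")
  got <- sqrt(sum((atomCoords(frag)[oi, ] - ringCentroid(frag, 1:6))^2))
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_equal(oracle, 3.646, tolerance = 1e-3)
})

test_that("distances are invariant under rigid motion of the conformer", {
  conf <- registryConformers()[["7e"]]
  m0 <- measurePharmacophore(conformer = conf)
  th <- 1.1
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3)
  moved <- conf
  moved@coords <- sweep(conf@coords %*% R, 2, c(-4, 8, 2), "+")
  m1 <- measurePharmacophore(conformer = moved)
  expect_equal(m1$d_centroid_N, m0$d_centroid_N, tolerance = 1e-9)
  expect_equal(m1$d_O_centroid, m0$d_O_centroid, tolerance = 1e-9)
  expect_equal(m1$d_O_N, m0$d_O_N, tolerance = 1e-9)
})

test_that("measurements satisfy the triangle inequality", {
  for (id in c("7a", "8d", "9d")) {
    m <- measurePharmacophore(conformer = registryConformers()[[id]])
    expect_lte(m$d_O_N, m$d_O_centroid + m$d_centroid_N)
    expect_lte(m$d_O_centroid, m$d_O_N + m$d_centroid_N)
    expect_lte(m$d_centroid_N, m$d_O_N + m$d_O_centroid)
    expect_true(all(unlist(m[, 2:4]) > 0))
  }
})

test_that("classification against published ranges is boundary-inclusive", {
  within_all <- classifyMeasurement(list(d_centroid_N = 6.30,
                                         d_O_centroid = 3.71, d_O_N = 4.97))
  expect_true(within_all$all_within)
  ## the classical reference dimensions sit on the boundaries
  gund <- classifyMeasurement(list(d_centroid_N = 7.14,
                                   d_O_centroid = 3.68, d_O_N = 4.17))
  expect_true(gund$all_within)
  outside <- classifyMeasurement(list(d_centroid_N = 8.0,
                                      d_O_centroid = 3.70, d_O_N = 4.5))
  expect_false(outside$centroid_N_within)
  expect_true(outside$O_centroid_within)
  expect_error(classifyMeasurement(list(d_centroid_N = 0,
                                        d_O_centroid = 0, d_O_N = 0)),
               "positive")
  expect_error(classifyMeasurement(list(d_centroid_N = 10,
                                        d_O_centroid = 1, d_O_N = 2)),
               "triangle")
})
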