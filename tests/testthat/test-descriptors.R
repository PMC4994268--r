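test_that("dot-sampled areas hit analytic sphere limits", {
  toys <- toyConformers()
  ## single sphere, probe 1.4: exact 4*pi*(1.7+1.4)^2
  got <- shrakeRupleyArea(toys$carbon_atom, probe = 1.4)$area
  expect_equal(got, 4 * pi * 3.1^2, tolerance = 0.01)
  ## disjoint union is additive
  far <- vdwSurface(toys$carbon_pair_far)
  expect_equal(far, 2 * 4 * pi * 1.7^2, tolerance = 1e-6)
  ## overlapping pair: closed-form two-sphere union, caps of height r - d/2
  h <- 1.7 - 1.5 / 2
  analytic <- 2 * 4 * pi * 1.7^2 - 2 * 2 * pi * 1.7 * h
  close_ <- vdwSurface(toys$carbon_pair_close)
  expect_lt(close_, 2 * 4 * pi * 1.7^2)
  expect_equal(close_, analytic, tolerance = 0.015)
})

test_that("surface preconditions are enforced", {
  toys <- toyConformers()
  expect_error(shrakeRupleyArea(toys$carbon_atom, probe = -1))
  expect_error(shrakeRupleyArea(toys$carbon_atom, nPoints = 50))
  twin <- toys$carbon_pair_far
  twin@coords[2, ] <- twin@coords[1, ]
  expect_error(shrakeRupleyArea(twin), "share a centre")
})

test_that("probe inflation increases the area for every registry conformer", {
  for (conf in registryConformers()) {
    expect_gt(sasa(conf, nPoints = 480), vdwSurface(conf, nPoints = 480))
  }
})

test_that("grid volumes match analytic spheres and converge", {
  toys <- toyConformers()
  vC <- vdwVolume(toys$carbon_atom)
  expect_equal(vC, 4 / 3 * pi * 1.7^3, tolerance = 0.02)
  ## disjoint additivity
  expect_equal(vdwVolume(toys$carbon_pair_far), 2 * vC, tolerance = 0.02)
  ## halving the spacing moves the estimate by < 2%
  vC2 <- vdwVolume(toys$carbon_atom, spacing = 0.1)
  expect_lt(abs(vC2 - vC) / vC2, 0.02)
  ## cyclohexane occupies more volume than benzene
  vBz <- vdwVolume(embedConformer("c1ccccc1", seed = 1))
  vCh <- vdwVolume(embedConformer("C1CCCCC1", seed = 1))
  expect_gt(vCh, vBz)
})

test_that("density follows the mass-over-volume scaling law", {
  ## doubling the radius of an isolated sphere multiplies the volume by 8,
  ## so the density falls 8-fold
  atom <- toyConformers()$carbon_atom
  d1 <- molDensity(atom)
  d2 <- molDensity(atom, volume = vdwVolume(atom, radii = bondiRadii() * 2))
  expect_equal(d1 / d2, 8, tolerance = 0.05)
  ## brominated ketone denser than its methyl analogue
  expect_gt(molDensity(registryConformers()[["7e"]]),
            molDensity(registryConformers()[["7f"]]))
})

test_that("2D surface area uses only the connection table", {
  expect_equal(vsa2D("[He]", radii = c(He = 1.40)), 4 * pi * 1.4^2,
               tolerance = 1e-9)
  conf <- registryConformers()[["7b"]]
  shifted <- conf
  shifted@coords <- conf@coords + 50
  expect_identical(vsa2D(conf), vsa2D(shifted))
})

test_that("point-charge dipoles follow the definition of the Debye", {
  toys <- toyConformers()
  zero <- toys$carbon_pair_far
  zero@charges <- c(0, 0)
  expect_equal(dipoleMoment(zero), 0)
  ## +/- 0.2081 e at 1 A is 1 Debye
  pair <- toys$carbon_pair_close
  pair@coords <- rbind(c(0, 0, 0), c(1, 0, 0))
  pair@charges <- c(0.2081, -0.2081)
  expect_equal(dipoleMoment(pair), 1.0, tolerance = 1e-3)
  ## translation invariance for a neutral charge set
  pair2 <- pair
  pair2@coords <- pair@coords + 17.3
  expect_equal(dipoleMoment(pair2), dipoleMoment(pair), tolerance = 1e-9)
  expect_error(dipoleMoment(toys$benzene), "no partial charges")
})

test_that("3D descriptors are invariant under rigid motion", {
  conf <- assignPartialCharges(registryConformers()[["8a"]])
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- conf
  moved@coords <- sweep(conf@coords %*% R, 2, c(5, -3, 11), "+")
  expect_equal(vdwSurface(moved), vdwSurface(conf), tolerance = 1e-6)
  expect_equal(sasa(moved), sasa(conf), tolerance = 1e-6)
  expect_equal(vdwVolume(moved, spacing = 0.3),
               vdwVolume(conf, spacing = 0.3), tolerance = 0.01)
  expect_equal(dipoleMoment(moved), dipoleMoment(conf), tolerance = 1e-6)
})

test_that("computed descriptors preserve the reference table's ordering", {
  dd <- computedDescriptors()
  t4 <- fixtureTable4()
  expect_identical(dd$compound, t4$compound)
  expect_false(anyNA(as.matrix(dd[, -1])))
  expect_true(all(dd$S_wat > dd$S_vdW))
  expect_true(all(dd$A_vdW < dd$S_wat))
  expect_gt(cor(dd$S_vdW, t4$S_vdW, method = "spearman"), 0.8)
  expect_gt(cor(dd$S_wat, t4$S_wat, method = "spearman"), 0.8)
  ## size ordering: the largest amine exceeds the smallest ketone
  expect_gt(dd$S_vdW[dd$compound == "9e"], dd$S_vdW[dd$compound == "7a"])
  ## the point-charge dipole separates a strongly polar aromatic from an
  ## apolar one (the semiempirical per-compound ordering is not preserved
  ## by sigma-only charges and is not asserted)
  nb <- assignPartialCharges(embedConformer("O=[N+]([O-])c1ccccc1", seed = 1))
  tl <- assignPartialCharges(embedConformer("Cc1ccccc1", seed = 1))
  expect_gt(dipoleMoment(nb), dipoleMoment(tl))
})

test_that("descriptor vectors are reproducible per seed", {
  a <- computeDescriptors("7f", seed = 3, nConformers = 1, spacing = 0.3)
  b <- computeDescriptors("7f", seed = 3, nConformers = 1, spacing = 0.3)
  expect_identical(a, b)
})
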