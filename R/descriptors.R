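## The five molecular descriptors used by the QSAR: density (d), 3D van der
## Waals surface area (S_vdW), water-accessible surface area (S_wat), a
## connection-table 2D van der Waals surface area (A_vdW) and the
## point-charge dipole moment (mu_D). The 3D areas use the Shrake-Rupley
## dot-sampling algorithm with a deterministic golden-spiral point generator,
## so surface areas carry no randomness of their own.

atomicMasses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, S = 32.06, Cl = 35.45, Br = 79.904)

## Deterministic canonical orientation: centre at the centroid and align to
## the principal axes of the coordinate covariance, signs fixed by the third
## central moment. Dot- and grid-sampled quantities computed in this frame
## are invariant under rigid motion of the input (up to principal-axis
## degeneracy of highly symmetric molecules).
canonicalOrientation <- function(xyz) {
  X <- sweep(xyz, 2, colMeans(xyz))
  if (nrow(X) < 3L) return(X)
  e <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  V <- e$vectors
  for (j in 1:3) {
    s <- sum((X %*% V[, j])^3)
    if (abs(s) > 1e-8 && s < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  X %*% V
}

## Deterministic, approximately uniform points on the unit sphere.
goldenSpiralPoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley surface area
#'
#' Dot-sampling estimate of the solvent-accessible (or, with `probe = 0`,
#' van der Waals) surface area: each atom's sphere of radius `r_i + probe` is
#' sampled with a deterministic golden-spiral point set, and its contribution
#' is `4 * pi * (r_i + probe)^2` times the fraction of points outside every
#' other atom's probe-inflated sphere.
#'
#' @param conf A [Conformer-class].
#' @param radii Named vector of van der Waals radii (A); default Bondi.
#' @param probe Probe radius in Angstrom (0 for the bare vdW surface, 1.4
#'   for a water probe).
#' @param nPoints Dots per atom (>= 92; default 960).
#' @return List with `area` (total, A^2) and `per_atom` (A^2 per atom).
#' @examples
#' atom <- toyConformers()$carbon_atom
#' shrakeRupleyArea(atom, probe = 1.4)$area   # ~ 4*pi*(1.7+1.4)^2
#' @export
shrakeRupleyArea <- function(conf, radii = bondiRadii(), probe = 1.4,
                             nPoints = 960L) {
  stopifnot(probe >= 0, nPoints >= 92L)
  el <- conf@elements
  xyz <- canonicalOrientation(conf@coords)
  r <- radii[el]
  if (anyNA(r)) {
    stop("no radius for element(s): ", paste(unique(el[is.na(r)]),
                                             collapse = ", "), call. = FALSE)
  }
  r <- unname(r) + probe
  n <- length(el)
  if (n > 1L) {
    dd <- as.matrix(stats::dist(xyz))
    if (any(dd[upper.tri(dd)] < 1e-9)) {
      stop("two atoms share a centre; surface is undefined", call. = FALSE)
    }
  }
  pts <- goldenSpiralPoints(as.integer(nPoints))
  per <- numeric(n)
  for (i in seq_len(n)) {
    nbr <- if (n > 1L) which(dd[i, ] < r[i] + r & seq_len(n) != i) else
      integer(0)
    if (!length(nbr)) {
      per[i] <- 4 * pi * r[i]^2
      next
    }
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, nrow(p))
    for (j in nbr) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 > r[j]^2
      if (!any(exposed)) break
    }
    per[i] <- 4 * pi * r[i]^2 * mean(exposed)
  }
  list(area = sum(per), per_atom = per)
}

#' Van der Waals and water-accessible surface areas
#'
#' `vdwSurface` is the Shrake-Rupley area at probe 0 (the S_vdW descriptor);
#' `sasa` uses a 1.4-A water probe (the S_wat descriptor).
#'
#' @inheritParams shrakeRupleyArea
#' @return Total area in A^2.
#' @export
vdwSurface <- function(conf, radii = bondiRadii(), nPoints = 960L) {
  shrakeRupleyArea(conf, radii = radii, probe = 0, nPoints = nPoints)$area
}

#' @rdname vdwSurface
#' @param probe Probe radius (A), default 1.4 (water).
#' @export
sasa <- function(conf, radii = bondiRadii(), probe = 1.4, nPoints = 960L) {
  shrakeRupleyArea(conf, radii = radii, probe = probe, nPoints = nPoints)$area
}

#' Grid-based van der Waals volume
#'
#' Union-of-spheres volume on a cubic grid: grid cells whose centre lies in
#' at least one probe-free atomic sphere count toward the volume.
#'
#' @inheritParams shrakeRupleyArea
#' @param spacing Grid spacing in Angstrom (default 0.2; halving the spacing
#'   changes the estimate by under ~2 percent for drug-sized molecules).
#' @return Volume in A^3.
#' @export
vdwVolume <- function(conf, radii = bondiRadii(), spacing = 0.2) {
  stopifnot(spacing > 0)
  el <- conf@elements
  xyz <- canonicalOrientation(conf@coords)
  r <- unname(radii[el])
  if (anyNA(r)) stop("no radius for some element", call. = FALSE)
  lo <- apply(xyz, 2, min) - max(r) - spacing
  gx <- seq(lo[1], max(xyz[, 1]) + max(r) + spacing, by = spacing)
  gy <- seq(lo[2], max(xyz[, 2]) + max(r) + spacing, by = spacing)
  gz <- seq(lo[3], max(xyz[, 3]) + max(r) + spacing, by = spacing)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  ## occupancy per cell: smoothed boundary (linear ramp of width one cell)
  ## to avoid the systematic undercount of hard cell-centre counting; union
  ## of spheres = max occupancy over atoms
  occ <- numeric(nx * ny * nz)
  for (i in seq_along(el)) {
    reach <- r[i] + spacing
    ix <- which(abs(gx - xyz[i, 1]) <= reach)
    iy <- which(abs(gy - xyz[i, 2]) <= reach)
    iz <- which(abs(gz - xyz[i, 3]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - xyz[i, 1])^2
    dy2 <- (gy[iy] - xyz[i, 2])^2
    dz2 <- (gz[iz] - xyz[i, 3])^2
    dxy <- outer(dx2, dy2, "+")
    for (k in seq_along(iz)) {
      w <- 0.5 + (r[i] - sqrt(dxy + dz2[k])) / spacing
      w[w < 0] <- 0
      w[w > 1] <- 1
      sel <- which(w > 0, arr.ind = TRUE)
      if (nrow(sel)) {
        idx <- ix[sel[, 1]] + (iy[sel[, 2]] - 1L) * nx +
          (iz[k] - 1L) * nx * ny
        occ[idx] <- pmax(occ[idx], w[sel])
      }
    }
  }
  sum(occ) * spacing^3
}

#' Molecular density from the van der Waals volume
#'
#' `d = MW / (N_A * V_vdW)`, unit-converted to g/cm^3. This is the package's
#' operational definition of the density descriptor; tabulated literature
#' values for these compounds (~1.0-1.2) are consistent with it.
#'
#' @param conf A [Conformer-class].
#' @param volume Optional precomputed vdW volume (A^3); computed if missing.
#' @param ... Passed to [vdwVolume()].
#' @return Density in g/cm^3.
#' @export
molDensity <- function(conf, volume = NULL, ...) {
  m <- atomicMasses[conf@elements]
  if (anyNA(m)) stop("no atomic mass for some element", call. = FALSE)
  if (is.null(volume)) volume <- vdwVolume(conf, ...)
  ## MW [g/mol] / (6.022e23 [1/mol] * V [A^3] * 1e-24 [cm^3/A^3])
  sum(m) / (0.602214076 * volume)
}

#' Connection-table (2D) van der Waals surface area
#'
#' Per-atom sphere area minus the spherical caps buried by bonded neighbours
#' placed at ideal bond lengths; no 3D coordinates are used. This
#' approximates the 2D surface-area descriptor (A_vdW) from the atom/bond
#' table alone.
#'
#' @param compound A registry id, SMILES string, or [Conformer-class] (only
#'   its elements and bonds are used).
#' @param radii Named vdW radii (A).
#' @return Area in A^2.
#' @export
vsa2D <- function(compound, radii = bondiRadii()) {
  if (methods::is(compound, "Conformer")) {
    topo <- list(elements = compound@elements, bonds = compound@bonds)
  } else {
    cmp <- resolveCompound(compound)
    topo <- smilesTopology(cmp$smiles)
  }
  el <- topo$elements
  r <- unname(radii[el])
  if (anyNA(r)) stop("no radius for some element", call. = FALSE)
  n <- length(el)
  info <- analyzeTopology(topo)
  area <- 4 * pi * r^2
  for (k in seq_len(nrow(topo$bonds))) {
    a <- topo$bonds[k, 1]; b <- topo$bonds[k, 2]
    arom <- info$inAromatic[a] && info$inAromatic[b]
    d <- idealBondLength(el[a], el[b], topo$bonds[k, 3], aromatic = arom)
    ## cap of sphere a hidden by sphere b (and vice versa)
    ha <- r[a] - (d^2 + r[a]^2 - r[b]^2) / (2 * d)
    hb <- r[b] - (d^2 + r[b]^2 - r[a]^2) / (2 * d)
    area[a] <- area[a] - 2 * pi * r[a] * min(max(ha, 0), 2 * r[a])
    area[b] <- area[b] - 2 * pi * r[b] * min(max(hb, 0), 2 * r[b])
  }
  sum(pmax(area, 0))
}

#' Point-charge dipole moment
#'
#' `mu = |sum_i q_i r_i| * 4.80320` Debye (charges in e, positions in A).
#' Translation-invariant for neutral molecules; for ions the origin is the
#' centre of mass and the value is reported under that convention.
#'
#' @param conf A [Conformer-class] with partial charges assigned.
#' @return Dipole magnitude in Debye.
#' @export
dipoleMoment <- function(conf) {
  if (!length(conf@charges)) {
    stop("conformer has no partial charges; run assignPartialCharges() first",
         call. = FALSE)
  }
  xyz <- conf@coords
  if (abs(sum(conf@formalCharges)) > 0) {
    m <- atomicMasses[conf@elements]
    xyz <- sweep(xyz, 2, colSums(xyz * m) / sum(m))
  }
  mu <- colSums(xyz * conf@charges)
  sqrt(sum(mu^2)) * 4.80320
}

#' Compute the full descriptor vector for one compound
#'
#' Embeds and minimizes a small ensemble of seeded conformers, assigns
#' partial charges, and assembles the five QSAR descriptors. The
#' conformer-dependent 3D descriptors (both surface areas, the volume behind
#' the density, the dipole) are reported as means over the seed ensemble:
#' a single random embedding is a noisy estimator of surface areas computed
#' on a locally minimized sketch, and averaging a few seeds stabilizes the
#' compound ordering. The dipole (electronegativity-equalization charges
#' instead of semiempirical ones) and the 2D surface area (ideal-bond-length
#' cap model) are approximations of the descriptor set used in the original
#' study and are flagged as such; computed values are meant to preserve the
#' ordering of the reference table, not to match it numerically.
#'
#' @param compound Registry id, SMILES, or one-row data frame (`id`,
#'   `smiles`).
#' @param seed Integer base seed; conformer i uses `seed + i - 1`.
#' @param nConformers Seeded conformers to average over (default 5).
#' @param probe Water-probe radius for S_wat (A).
#' @param nPoints Shrake-Rupley dots per atom.
#' @param spacing Volume grid spacing (A).
#' @param chargeMethod Partial-charge scheme for the dipole.
#' @return One-row `data.frame` with columns `compound`, `d`, `S_vdW`,
#'   `S_wat`, `A_vdW`, `mu_D`, plus an `"approximations"` attribute naming
#'   the approximated fields.
#' @examples
#' \donttest{
#' computeDescriptors("7a", seed = 1)
#' }
#' @export
computeDescriptors <- function(compound, seed = 1L, nConformers = 5L,
                               probe = 1.4, nPoints = 960L, spacing = 0.2,
                               chargeMethod = "gasteiger") {
  stopifnot(nConformers >= 1L)
  per <- lapply(seq_len(nConformers) - 1L, function(off) {
    conf <- embedConformer(compound, seed = as.integer(seed) + off)
    conf <- assignPartialCharges(conf, method = chargeMethod)
    list(id = conf@compoundId,
         vol = vdwVolume(conf, spacing = spacing),
         svdw = vdwSurface(conf, nPoints = nPoints),
         swat = sasa(conf, probe = probe, nPoints = nPoints),
         mu = dipoleMoment(conf),
         conf = conf)
  })
  conf1 <- per[[1]]$conf
  mvol <- mean(vapply(per, `[[`, numeric(1), "vol"))
  out <- data.frame(
    compound = per[[1]]$id,
    d = molDensity(conf1, volume = mvol),
    S_vdW = mean(vapply(per, `[[`, numeric(1), "svdw")),
    S_wat = mean(vapply(per, `[[`, numeric(1), "swat")),
    A_vdW = vsa2D(conf1),
    mu_D = mean(vapply(per, `[[`, numeric(1), "mu")),
    stringsAsFactors = FALSE
  )
  attr(out, "approximations") <- c(
    mu_D = paste0("point-charge dipole from ", chargeMethod,
                  " charges (approximate-AM1)"),
    A_vdW = "ideal-bond-length spherical-cap model",
    d = "molecular weight over grid vdW volume")
  attr(out, "seed") <- as.integer(seed)
  out
}
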