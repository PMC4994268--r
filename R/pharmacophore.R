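## Pharmacophore geometry: locate the basic ring nitrogen, the secondary-site
## oxygen and the primary hydrophobic aryl centroid on a conformer, and
## measure the three Gund-style distances. The primary aryl (Ar2) is the
## ring reached from the basic nitrogen through the piperidine C4 - the
## aroyl/carbinol phenyl - not the N-benzyl ring (Ar1), which is identified
## and reported but takes no part in the distances.

#' Published pharmacophore distance ranges
#'
#' The distance windows spanned by the classical reference model and the
#' most/least potent ligands of this series: aryl-centroid to basic N
#' 6.30-7.14 A, secondary-site O to centroid 3.68-3.71 A, O to N
#' 4.17-4.97 A.
#'
#' @return List of two-element `c(min, max)` vectors: `centroid_N`,
#'   `O_centroid`, `O_N`.
#' @export
gundRanges <- function() {
  list(centroid_N = c(6.30, 7.14),
       O_centroid = c(3.68, 3.71),
       O_N = c(4.17, 4.97))
}

#' Identify pharmacophore feature atoms on a conformer
#'
#' Locates: the basic amine nitrogen (sp3 N in a saturated six-membered
#' ring); the secondary-site atom on the exocyclic linker carbon attached to
#' the piperidine C4 - a carbonyl or hydroxyl oxygen where present, else
#' (for the amine series) the secondary amine nitrogen, flagged; the primary
#' aryl ring (Ar2), i.e. the six-membered aromatic ring bonded to that
#' linker carbon; and the N-benzyl aryl ring (Ar1), reported but unused by
#' the distance measurement.
#'
#' @param conf A [Conformer-class].
#' @return List with elements `N` (atom index), `secondary` (atom index),
#'   `secondary_site` (`"oxygen"` or `"amine"`), `ar2`, `ar1` (integer
#'   vectors of ring atom indices; `ar1` may be `NULL`), `c4`, `linker`.
#' @export
identifyFeatures <- function(conf) {
  topo <- list(elements = conf@elements, bonds = conf@bonds,
               formalCharges = conf@formalCharges)
  info <- analyzeTopology(topo)
  el <- conf@elements
  failed <- function(what) {
    stop("pharmacophore pattern not found: ", what, call. = FALSE)
  }
  satRings <- info$rings[!info$aromatic]
  nIdx <- NULL; ring <- NULL
  for (rg in satRings) {
    if (length(rg) != 6L) next
    cand <- rg[el[rg] == "N"]
    for (nc in cand) {
      bOrders <- conf@bonds[conf@bonds[, 1] == nc | conf@bonds[, 2] == nc, 3]
      if (all(bOrders == 1L) && conf@formalCharges[nc] == 0) {
        nIdx <- nc; ring <- rg
        break
      }
    }
    if (!is.null(nIdx)) break
  }
  if (is.null(nIdx)) {
    failed("basic amine nitrogen in a saturated six-membered ring")
  }
  pos <- which(ring == nIdx)
  ring <- ring[((seq_len(6) + pos - 2L) %% 6L) + 1L]   # rotate: N first
  c4 <- ring[4]
  linkers <- setdiff(info$adj[[c4]], ring)
  linkers <- linkers[el[linkers] == "C"]
  aromRings <- info$rings[info$aromatic]
  linker <- NULL; ar2 <- NULL
  for (lc in linkers) {
    nb <- info$adj[[lc]]
    hit <- which(vapply(aromRings, function(rg) any(nb %in% rg), logical(1)))
    if (length(hit)) {
      linker <- lc
      ar2 <- aromRings[[hit[1]]]
      break
    }
  }
  if (is.null(linker)) failed("exocyclic linker carbon bearing an aryl ring")
  nb <- setdiff(info$adj[[linker]], c(c4, ar2))
  oIdx <- nb[el[nb] == "O"]
  site <- "oxygen"
  if (length(oIdx)) {
    secondary <- oIdx[1]
  } else {
    n2 <- nb[el[nb] == "N"]
    if (!length(n2)) {
      failed("secondary-site heteroatom (O or exocyclic N) on the linker carbon")
    }
    secondary <- n2[1]
    site <- "amine"
  }
  ## Ar1: N-benzyl ring (through the exocyclic CH2 on the basic nitrogen)
  ar1 <- NULL
  for (b1 in setdiff(info$adj[[nIdx]], ring)) {
    nb1 <- info$adj[[b1]]
    hit <- which(vapply(aromRings, function(rg) any(nb1 %in% rg), logical(1)))
    if (length(hit)) {
      ar1 <- aromRings[[hit[1]]]
      break
    }
  }
  list(N = nIdx, secondary = secondary, secondary_site = site,
       ar2 = ar2, ar1 = ar1, c4 = c4, linker = linker)
}

#' Centroid of a ring
#'
#' Arithmetic mean of the member atoms' coordinates.
#'
#' @param conf A [Conformer-class].
#' @param ring Integer vector of atom indices.
#' @return Length-3 numeric vector (A).
#' @export
ringCentroid <- function(conf, ring) {
  stopifnot(length(ring) >= 3L)
  colMeans(conf@coords[ring, , drop = FALSE])
}

#' Measure the pharmacophore distances on a conformer
#'
#' Euclidean distances between the identified features: primary-aryl
#' centroid to basic N, secondary-site atom to centroid, and secondary-site
#' atom to N. For the amine series (no oxygen) the secondary amine nitrogen
#' stands in, and the `secondary_site` column flags it.
#'
#' @param compound Registry id, SMILES, or one-row data frame; ignored when
#'   `conformer` is supplied.
#' @param conformer Optional prebuilt [Conformer-class].
#' @param seed Embedding seed used when `conformer` is `NULL`.
#' @param ... Passed to [embedConformer()].
#' @return One-row `data.frame`: `compound`, `d_centroid_N`,
#'   `d_O_centroid`, `d_O_N`, `secondary_site`; feature indices are attached
#'   as the `"features"` attribute.
#' @examples
#' \donttest{
#' measurePharmacophore("7e", seed = 1)
#' }
#' @export
measurePharmacophore <- function(compound = NULL, conformer = NULL,
                                 seed = 1L, ...) {
  if (is.null(conformer)) {
    conformer <- embedConformer(compound, seed = seed, ...)
  }
  f <- identifyFeatures(conformer)
  cen <- ringCentroid(conformer, f$ar2)
  xyz <- conformer@coords
  d <- function(p, q) sqrt(sum((p - q)^2))
  out <- data.frame(
    compound = conformer@compoundId,
    d_centroid_N = d(cen, xyz[f$N, ]),
    d_O_centroid = d(xyz[f$secondary, ], cen),
    d_O_N = d(xyz[f$secondary, ], xyz[f$N, ]),
    secondary_site = f$secondary_site,
    stringsAsFactors = FALSE
  )
  attr(out, "features") <- f
  attr(out, "provenance") <- conformer@provenance
  out
}

#' Classify a measurement against pharmacophore ranges
#'
#' Boundary-inclusive containment of each measured distance in its published
#' range. Degenerate measurements (non-positive distances or a triangle-
#' inequality violation among the three) are an error, not "outside".
#'
#' @param measurement Output of [measurePharmacophore()], or a named list /
#'   one-row data frame with `d_centroid_N`, `d_O_centroid`, `d_O_N`.
#' @param ranges As [gundRanges()].
#' @return One-row `data.frame` of logicals `centroid_N_within`,
#'   `O_centroid_within`, `O_N_within`, `all_within`.
#' @export
classifyMeasurement <- function(measurement, ranges = gundRanges()) {
  dCN <- measurement$d_centroid_N
  dOC <- measurement$d_O_centroid
  dON <- measurement$d_O_N
  dd <- c(dCN, dOC, dON)
  if (any(!is.finite(dd)) || any(dd <= 0)) {
    stop("invalid measurement: distances must be positive", call. = FALSE)
  }
  if (dCN > dOC + dON || dOC > dCN + dON || dON > dCN + dOC) {
    stop("invalid measurement: triangle inequality violated", call. = FALSE)
  }
  within <- function(x, r) x >= r[1] & x <= r[2]
  res <- data.frame(
    centroid_N_within = within(dCN, ranges$centroid_N),
    O_centroid_within = within(dOC, ranges$O_centroid),
    O_N_within = within(dON, ranges$O_N)
  )
  res$all_within <- res$centroid_N_within & res$O_centroid_within &
    res$O_N_within
  res
}
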