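## Synthetic data emulating the statistical structure of the study's tables:
## a 14-row descriptor/affinity table with a known linear model (for
## parameter-recovery and validation tests) and a censored binding table.
## Defaults are calibrated once to the reference table's column locations and
## spreads; see the methods vignette for the rationale.

syntheticDefaults <- function() {
  list(
    means = c(d = 1.06, S_vdW = 372, S_wat = 606, A_vdW = 334, mu_D = 2.5),
    sds = c(d = 0.06, S_vdW = 52, S_wat = 74, A_vdW = 38, mu_D = 1.8),
    intercept = -4.1,
    coefficients = c(d = -3, S_vdW = 0.02, S_wat = 0.01,
                     A_vdW = -0.02, mu_D = -0.3)
  )
}

#' Generate a synthetic descriptor/affinity table
#'
#' Draws descriptor columns from normal distributions calibrated to the
#' reference table (with a configurable correlation between the two 3D
#' surface areas, which are nearly collinear in the real data), builds the
#' response as a known linear model plus Gaussian noise, and returns a table
#' in the same nine-column schema as the packaged fixture: `dG_pred` holds
#' the noiseless linear part and `dG_res` the noise, so the residual identity
#' holds by construction.
#'
#' @param n Rows (compounds); default 14, the study's regime.
#' @param seed Integer seed; fixes the whole table.
#' @param noise_sd Standard deviation of the Gaussian response noise.
#' @param intercept,coefficients True model (named per descriptor).
#' @param means,sds Descriptor distributions (named).
#' @param surface_cor Correlation between `S_vdW` and `S_wat` draws
#'   (default 0.9).
#' @return A `data.frame` with columns `compound`, the five descriptors,
#'   `dG_exp`, `dG_pred`, `dG_res`.
#' @examples
#' tab <- syntheticDescriptorTable(seed = 1, noise_sd = 0)
#' fitQsar(tab, c("S_vdW", "A_vdW", "S_wat"))@R2   # exactly 1
#' @export
syntheticDescriptorTable <- function(n = 14L, seed = 1L, noise_sd = 0.5,
                                     intercept = NULL, coefficients = NULL,
                                     means = NULL, sds = NULL,
                                     surface_cor = 0.9) {
  def <- syntheticDefaults()
  if (is.null(intercept)) intercept <- def$intercept
  if (is.null(coefficients)) coefficients <- def$coefficients
  if (is.null(means)) means <- def$means
  if (is.null(sds)) sds <- def$sds
  if (any(sds <= 0)) stop("descriptor sds must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  k <- length(coefficients)
  if (n < k + 2L) stop("need n >= k + 2", call. = FALSE)
  nms <- names(coefficients)
  stopifnot(!is.null(nms), all(nms %in% names(means)),
            all(nms %in% names(sds)))
  withSeed(as.integer(seed), {
    z1 <- stats::rnorm(n)
    z2 <- surface_cor * z1 + sqrt(1 - surface_cor^2) * stats::rnorm(n)
    X <- sapply(nms, function(nm) {
      z <- switch(nm, S_vdW = z1, S_wat = z2, stats::rnorm(n))
      v <- means[nm] + sds[nm] * z
      if (nm == "mu_D") v <- abs(v)   # dipole magnitudes are non-negative
      if (nm == "d") v <- pmax(v, 0.05)
      v
    })
    colnames(X) <- nms
    linear <- intercept + as.numeric(X %*% coefficients)
    noise <- if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else numeric(n)
    data.frame(compound = sprintf("s%02d", seq_len(n)), X,
               dG_exp = linear + noise, dG_pred = linear, dG_res = noise,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic censored binding table
#'
#' Ki values are drawn log-uniformly; draws above the assay ceiling are
#' replaced by the ceiling and flagged censored, emulating the ">" entries
#' of the reference binding tables.
#'
#' @param n Rows.
#' @param seed Integer seed.
#' @param log10_range Range of `log10(Ki/nM)` for the uniform draw
#'   (default 0.5 nM to 5000 nM).
#' @param bounds Censoring ceilings in nM, named `sigma1` and `sigma2`.
#' @return A `data.frame` in the schema of [loadBindingTable()]'s output.
#' @export
syntheticBindingTable <- function(n = 14L, seed = 1L,
                                  log10_range = log10(c(0.5, 5000)),
                                  bounds = c(sigma1 = 434, sigma2 = 854)) {
  withSeed(as.integer(seed), {
    k1 <- 10^stats::runif(n, log10_range[1], log10_range[2])
    k2 <- 10^stats::runif(n, log10_range[1], log10_range[2])
    c1 <- k1 > bounds[["sigma1"]]
    c2 <- k2 > bounds[["sigma2"]]
    k1[c1] <- bounds[["sigma1"]]
    k2[c2] <- bounds[["sigma2"]]
    data.frame(
      compound = sprintf("s%02d", seq_len(n)),
      sigma1_ki = k1, sigma1_censored = c1,
      sigma2_ki = k2, sigma2_censored = c2,
      ratio_printed = selectivityRatio(k2, k1),
      stringsAsFactors = FALSE
    )
  })
}

#' Analytic toy conformers
#'
#' Small hand-built geometries with closed-form reference values, used to
#' validate the surface-area, volume and pharmacophore code: a single carbon
#' atom, disjoint and overlapping carbon pairs, ideal methane, an ideal
#' benzene hexagon, and a planar benzaldehyde-like carbonyl-phenyl fragment
#' with textbook bond lengths (C=O 1.22, C-C(ipso) 1.49, aromatic C-C 1.39,
#' 120-degree sp2 angles).
#'
#' @return Named list of [Conformer-class] objects: `carbon_atom`,
#'   `carbon_pair_far` (100 A apart), `carbon_pair_close` (1.5 A),
#'   `methane`, `benzene`, `benzoyl_fragment`.
#' @export
toyConformers <- function() {
  mk <- function(id, el, xyz, bonds = matrix(0L, 0, 3)) {
    colnames(bonds) <- c("a", "b", "order")
    methods::new("Conformer", compoundId = id, elements = el,
                 coords = xyz, bonds = bonds,
                 formalCharges = numeric(length(el)),
                 provenance = list(method = "analytic toy geometry"))
  }
  out <- list()
  out$carbon_atom <- mk("carbon_atom", "C", matrix(0, 1, 3))
  out$carbon_pair_far <- mk("carbon_pair_far", c("C", "C"),
                            rbind(c(0, 0, 0), c(100, 0, 0)))
  out$carbon_pair_close <- mk("carbon_pair_close", c("C", "C"),
                              rbind(c(0, 0, 0), c(1.5, 0, 0)),
                              matrix(c(1L, 2L, 1L), 1))
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3)
  out$methane <- mk("methane", c("C", rep("H", 4)),
                    rbind(c(0, 0, 0), 1.09 * tet),
                    cbind(1L, 2:5, 1L))
  ang <- (0:5) * pi / 3
  ringC <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  ringH <- cbind(2.48 * cos(ang), 2.48 * sin(ang), 0)
  bz <- rbind(
    cbind(1:6, c(2:6, 1L), rep(c(2L, 1L), 3)),   # alternating ring bonds
    cbind(1:6, 7:12, 1L)                          # C-H
  )
  out$benzene <- mk("benzene", c(rep("C", 6), rep("H", 6)),
                    rbind(ringC, ringH), bz)
  ## carbonyl-phenyl fragment: ipso at (1.39, 0, 0); exocyclic carbonyl
  ## carbon along +x; O and H at +/-120 degrees in the ring plane
  cexo <- c(1.39 + 1.49, 0, 0)
  oxy <- cexo + 1.22 * c(cos(pi / 3), sin(pi / 3), 0)
  hal <- cexo + 1.09 * c(cos(-pi / 3), sin(-pi / 3), 0)
  ringH5 <- ringH[2:6, , drop = FALSE]
  el <- c(rep("C", 6), "C", "O", "H", rep("H", 5))
  xyz <- rbind(ringC, cexo, oxy, hal, ringH5)
  bonds <- rbind(
    cbind(1:6, c(2:6, 1L), rep(c(2L, 1L), 3)),
    c(1L, 7L, 1L), c(7L, 8L, 2L), c(7L, 9L, 1L),
    cbind(2:6, 10:14, 1L)
  )
  out$benzoyl_fragment <- mk("benzoyl_fragment", el, xyz, bonds)
  out
}
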