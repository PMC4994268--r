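## Conformer generation: seeded distance-geometry embedding followed by
## deterministic force-field minimization (GAFF by default). The semiempirical optimization used to
## produce the study's reference geometries is not reproducible at desk scale;
## the contract here is a classical one: bounds from ideal bond lengths and
## angles, metric-matrix embedding of a seeded distance sample, restraint
## polishing, then force-field minimization to a stated convergence criterion.

#' Bondi van der Waals radii
#'
#' @return Named numeric vector of radii in Angstrom for the elements this
#'   chemistry uses (H, C, N, O, F, S, Cl, Br).
#' @export
bondiRadii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
    S = 1.80, Cl = 1.75, Br = 1.85)
}

#' Van der Waals radius of an element
#'
#' @param element Element symbol (case sensitive, e.g. `"Br"`).
#' @return Radius in Angstrom (Bondi).
#' @examples
#' vdwRadius("C")   # 1.70
#' @export
vdwRadius <- function(element) {
  r <- bondiRadii()[element]
  if (anyNA(r)) {
    stop("no van der Waals radius tabulated for element(s): ",
         paste(element[is.na(r)], collapse = ", "), call. = FALSE)
  }
  unname(r)
}

covalentRadii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                   S = 1.05, Cl = 1.02, Br = 1.20)

## Reference bond lengths (Angstrom) keyed "el1-el2-order" with elements
## sorted; "a" = aromatic. Fallback: sum of covalent radii.
idealBondLength <- function(e1, e2, order, aromatic = FALSE) {
  key <- paste(sort(c(e1, e2)), collapse = "-")
  tab <- c(
    "C-C-1" = 1.53, "C-C-2" = 1.34, "C-C-3" = 1.20, "C-C-a" = 1.39,
    "C-N-1" = 1.47, "C-N-2" = 1.28, "C-N-a" = 1.34,
    "C-O-1" = 1.43, "C-O-2" = 1.22,
    "N-N-1" = 1.45, "N-O-1" = 1.36, "N-O-2" = 1.21,
    "C-F-1" = 1.35, "C-Cl-1" = 1.77, "Br-C-1" = 1.94, "C-S-1" = 1.81,
    "C-H-1" = 1.09, "H-N-1" = 1.01, "H-O-1" = 0.96, "H-S-1" = 1.34
  )
  k <- paste0(key, "-", if (aromatic) "a" else order)
  if (!is.na(tab[k])) return(unname(tab[k]))
  k1 <- paste0(key, "-1")
  if (!is.na(tab[k1])) return(unname(tab[k1]))
  unname(covalentRadii[e1] + covalentRadii[e2])
}

## Adjacency list from a bond matrix.
adjacencyList <- function(bonds, n) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1]; b <- bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

## All-pairs graph (bond-count) distances by repeated BFS.
graphDistances <- function(adj) {
  n <- length(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(dist[nxt])]
      dist[nxt] <- dist[frontier[1]] + 1
      ## breadth level bookkeeping: all frontier nodes share one level
      dist[nxt] <- min(dist[frontier]) + 1
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

## Smallest rings (size <= maxSize): for each bond, shortest alternative path
## between its endpoints. Returns a list of integer vectors (ring atom paths).
findRings <- function(bonds, n, maxSize = 6L) {
  adj <- adjacencyList(bonds, n)
  rings <- list()
  seen <- character(0)
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1]; b <- bonds[r, 2]
    ## BFS from a to b avoiding the direct edge
    prev <- rep(NA_integer_, n)
    dist <- rep(Inf, n)
    dist[a] <- 0
    q <- a
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) {
        if (v == a && w == b) next
        if (!is.finite(dist[w])) {
          dist[w] <- dist[v] + 1
          prev[w] <- v
          if (w != b) q <- c(q, w)
        }
      }
    }
    if (is.finite(dist[b]) && dist[b] + 1 <= maxSize) {
      path <- b
      while (path[1] != a) path <- c(prev[path[1]], path)
      key <- paste(sort(path), collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- path
      }
    }
  }
  rings
}

## Aromatic test for a ring given kekulized bond orders: six-membered, all
## C/N, alternating single/double (or explicit aromatic order 4).
isAromaticRing <- function(ring, bonds, elements) {
  if (length(ring) != 6L) return(FALSE)
  if (!all(elements[ring] %in% c("C", "N"))) return(FALSE)
  orders <- integer(0)
  for (i in seq_along(ring)) {
    a <- ring[i]; b <- ring[if (i == 6L) 1L else i + 1L]
    hit <- which((bonds[, 1] == a & bonds[, 2] == b) |
                   (bonds[, 1] == b & bonds[, 2] == a))
    if (!length(hit)) return(FALSE)
    orders <- c(orders, unname(bonds[hit[1], 3]))
  }
  all(orders == 4L) || identical(sort(orders), c(1L, 1L, 1L, 2L, 2L, 2L))
}

## Internal: per-molecule structural analysis shared by the embedding and the
## pharmacophore feature finder.
analyzeTopology <- function(topo) {
  n <- length(topo$elements)
  adj <- adjacencyList(topo$bonds, n)
  rings <- findRings(topo$bonds, n)
  aromatic <- vapply(rings, isAromaticRing, logical(1),
                     bonds = topo$bonds, elements = topo$elements)
  inAromatic <- rep(FALSE, n)
  for (rg in rings[aromatic]) inAromatic[rg] <- TRUE
  hasDouble <- rep(FALSE, n)
  hasTriple <- rep(FALSE, n)
  for (r in seq_len(nrow(topo$bonds))) {
    if (topo$bonds[r, 3] == 2L) hasDouble[topo$bonds[r, 1:2]] <- TRUE
    if (topo$bonds[r, 3] == 3L) hasTriple[topo$bonds[r, 1:2]] <- TRUE
  }
  hyb <- ifelse(hasTriple, "sp", ifelse(hasDouble | inAromatic, "sp2", "sp3"))
  list(n = n, adj = adj, rings = rings, aromatic = aromatic,
       inAromatic = inAromatic, hyb = hyb)
}

## Distance restraints: exact targets (bonds, geminal 1-3 pairs, aromatic
## ring cross-distances) and one-sided lower bounds for everything else.
distanceRestraints <- function(topo, info) {
  el <- topo$elements
  n <- info$n
  exact <- list(a = integer(0), b = integer(0), t = numeric(0))
  addExact <- function(a, b, t) {
    exact$a <<- c(exact$a, a); exact$b <<- c(exact$b, b)
    exact$t <<- c(exact$t, t)
  }
  blen <- matrix(NA_real_, n, n)
  for (r in seq_len(nrow(topo$bonds))) {
    a <- topo$bonds[r, 1]; b <- topo$bonds[r, 2]
    arom <- info$inAromatic[a] && info$inAromatic[b] &&
      any(vapply(info$rings[info$aromatic], function(rg)
        a %in% rg && b %in% rg, logical(1)))
    t <- idealBondLength(el[a], el[b], topo$bonds[r, 3], aromatic = arom)
    addExact(a, b, t)
    blen[a, b] <- blen[b, a] <- t
  }
  for (c0 in seq_len(n)) {
    nbrs <- info$adj[[c0]]
    if (length(nbrs) < 2L) next
    theta <- switch(info$hyb[c0], sp = pi, sp2 = 2 * pi / 3,
                    109.47 * pi / 180)
    for (i in seq_len(length(nbrs) - 1L)) {
      for (j in seq(i + 1L, length(nbrs))) {
        a <- nbrs[i]; b <- nbrs[j]
        d13 <- sqrt(blen[c0, a]^2 + blen[c0, b]^2 -
                      2 * blen[c0, a] * blen[c0, b] * cos(theta))
        addExact(a, b, d13)
      }
    }
  }
  for (rg in info$rings[info$aromatic]) {
    L <- 1.39
    for (i in 1:6) {
      addExact(rg[i], rg[if (i > 3) i - 3 else i + 3], 2 * L)       # para
      addExact(rg[i], rg[if (i > 4) i - 4 else i + 2], L * sqrt(3)) # meta
    }
  }
  ## collapse duplicate exact pairs
  key <- paste(pmin(exact$a, exact$b), pmax(exact$a, exact$b))
  keep <- !duplicated(key)
  exact <- lapply(exact, `[`, keep)
  gd <- graphDistances(info$adj)
  rv <- bondiRadii()[el]
  pairIdx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ga <- pairIdx[, 1]; gb <- pairIdx[, 2]
  g <- gd[pairIdx]
  free <- g >= 3
  lb <- ifelse(g == 3, 0.65, 0.80) * (rv[ga] + rv[gb])
  list(exact = exact,
       lower = list(a = ga[free], b = gb[free], t = lb[free]),
       graphDist = gd)
}

## Metric-matrix (classical MDS) embedding of a sampled distance matrix.
embedFromDistances <- function(D) {
  n <- nrow(D)
  D2 <- D^2
  rm_ <- rowMeans(D2)
  G <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(D2))
  e <- eigen(G, symmetric = TRUE)
  X <- e$vectors[, 1:3, drop = FALSE] %*%
    diag(sqrt(pmax(e$values[1:3], 1e-6)), 3)
  X
}

scatterAdd <- function(n, idx, m) {
  out <- matrix(0, n, 3)
  r <- rowsum(m, idx)
  out[as.integer(rownames(r)), ] <- r
  out
}

## Gradient polish of embedded coordinates against the restraints.
polishCoords <- function(X, restraints, maxit = 300L) {
  n <- nrow(X)
  ea <- restraints$exact$a; eb <- restraints$exact$b
  et <- restraints$exact$t
  la <- restraints$lower$a; lb_ <- restraints$lower$b
  lt <- restraints$lower$t
  fn <- function(p) {
    X <- matrix(p, n, 3)
    de <- sqrt(rowSums((X[ea, , drop = FALSE] - X[eb, , drop = FALSE])^2))
    dl <- sqrt(rowSums((X[la, , drop = FALSE] - X[lb_, , drop = FALSE])^2))
    sum((de - et)^2) + 0.3 * sum(pmax(lt - dl, 0)^2)
  }
  gr <- function(p) {
    X <- matrix(p, n, 3)
    diffE <- X[ea, , drop = FALSE] - X[eb, , drop = FALSE]
    de <- sqrt(rowSums(diffE^2)) + 1e-12
    cE <- 2 * (de - et) / de
    contribE <- diffE * cE
    diffL <- X[la, , drop = FALSE] - X[lb_, , drop = FALSE]
    dl <- sqrt(rowSums(diffL^2)) + 1e-12
    cL <- -2 * 0.3 * pmax(lt - dl, 0) / dl
    contribL <- diffL * cL
    G <- scatterAdd(n, ea, contribE) - scatterAdd(n, eb, contribE) +
      scatterAdd(n, la, contribL) - scatterAdd(n, lb_, contribL)
    as.vector(G)
  }
  res <- stats::optim(as.vector(X), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  matrix(res$par, n, 3)
}

## Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## Geometry sanity checks on a minimized conformer.
validateConformerGeometry <- function(conf, info, graphDist) {
  xyz <- conf@coords
  b <- conf@bonds
  dB <- sqrt(rowSums((xyz[b[, 1], , drop = FALSE] -
                        xyz[b[, 2], , drop = FALSE])^2))
  if (any(dB < 0.7 | dB > 2.0)) return(FALSE)
  n <- nrow(xyz)
  pairIdx <- which(upper.tri(matrix(0, n, n)) & graphDist >= 3, arr.ind = TRUE)
  dN <- sqrt(rowSums((xyz[pairIdx[, 1], , drop = FALSE] -
                        xyz[pairIdx[, 2], , drop = FALSE])^2))
  if (any(dN < 1.2)) return(FALSE)
  for (rg in info$rings[info$aromatic]) {
    P <- xyz[rg, , drop = FALSE]
    P <- sweep(P, 2, colMeans(P))
    dev <- svd(P)$d[3] / sqrt(6)
    if (dev > 0.25) return(FALSE)
  }
  TRUE
}

newConformer <- function(id, topo, coords, provenance = list()) {
  methods::new("Conformer", compoundId = id, elements = topo$elements,
               coords = coords, bonds = topo$bonds,
               formalCharges = topo$formalCharges, provenance = provenance)
}

resolveCompound <- function(compound) {
  if (is.data.frame(compound) && nrow(compound) == 1L &&
      all(c("id", "smiles") %in% names(compound))) {
    return(list(id = compound$id, smiles = compound$smiles))
  }
  stopifnot(is.character(compound), length(compound) == 1L)
  reg <- compoundRegistry()
  if (compound %in% reg$id) {
    return(list(id = compound, smiles = reg$smiles[reg$id == compound]))
  }
  list(id = "molecule", smiles = compound)
}

#' Embed and minimize a 3D conformer
#'
#' Builds a 3D geometry for a compound by seeded distance-geometry embedding
#' (ideal bond-length/angle restraints, metric-matrix embedding of a sampled
#' distance matrix, restraint polishing) followed by classical force-field
#' minimization (GAFF by default; MMFF94, UFF and Ghemical are accepted). The result is deterministic for a fixed `(compound, seed)`:
#' all randomness is drawn from seeds derived from `seed`, and the minimizer
#' is deterministic given its input. When the parent structure carries a
#' stereocentre the embedded geometry is checked against the intended
#' configuration (via canonical-SMILES round trip) and mirrored if needed, so
#' chiral compounds come out as drawn (the R-isomers for this registry).
#' With `ensembleSize > 1` several seeded embeddings are minimized and the
#' lowest-energy one is returned.
#'
#' @param compound A registry id (e.g. `"7e"`), a SMILES string, or a one-row
#'   data frame with columns `id` and `smiles`.
#' @param seed Integer seed fixing the embedding.
#' @param ensembleSize Number of seeded embeddings to minimize (default 1);
#'   the lowest-energy valid member is returned.
#' @param maxAttempts Embedding attempts per ensemble member before erroring.
#' @param ff,crit Force field and convergence criterion for minimization.
#' @return A [Conformer-class] with provenance recording method, seeds and
#'   pre-/post-minimization energies (kcal/mol).
#' @examples
#' \donttest{
#' conf <- embedConformer("7e", seed = 7)
#' conf
#' }
#' @export
embedConformer <- function(compound, seed = 1L, ensembleSize = 1L,
                           maxAttempts = 20L, ff = "GAFF", crit = 1e-3) {
  cmp <- resolveCompound(compound)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  seed <- as.integer(seed)
  topo <- smilesTopology(cmp$smiles)
  info <- analyzeTopology(topo)
  restraints <- distanceRestraints(topo, info)
  target <- canonicalSmiles(cmp$smiles)
  hasStereo <- grepl("@", target, fixed = TRUE)
  best <- NULL
  for (k in seq_len(ensembleSize)) {
    got <- NULL
    for (attempt in seq_len(maxAttempts)) {
      subSeed <- (abs(seed) * 10007L + k * 211L + attempt) %%
        .Machine$integer.max
      conf0 <- withSeed(subSeed, {
        ex <- restraints$exact
        n <- info$n
        D <- matrix(0, n, n)
        D[cbind(ex$a, ex$b)] <- ex$t
        D[cbind(ex$b, ex$a)] <- ex$t
        loose <- D == 0 & upper.tri(D)
        idx <- which(loose, arr.ind = TRUE)
        g <- restraints$graphDist[idx]
        lo <- 1.5 + 0.3 * pmin(g, 4)
        hi <- pmin(1.8 * g, 12)
        smp <- lo + stats::runif(nrow(idx)) * pmax(hi - lo, 0)
        D[idx] <- smp
        D[cbind(idx[, 2], idx[, 1])] <- smp
        X <- embedFromDistances(D)
        X <- polishCoords(X, restraints)
        newConformer(cmp$id, topo, X)
      })
      ePre <- tryCatch(obEnergy(conf0, ff), error = function(e) NA_real_)
      if (!is.finite(ePre)) next
      conf1 <- tryCatch(obMinimize(conf0, ff = ff, crit = crit),
                        error = function(e) NULL)
      if (is.null(conf1)) next
      mirrored <- FALSE
      if (hasStereo && !identical(conformerCanonicalSmiles(conf1), target)) {
        conf1@coords[, 1] <- -conf1@coords[, 1]
        conf1 <- obMinimize(conf1, ff = ff, crit = crit)
        mirrored <- TRUE
        if (!identical(conformerCanonicalSmiles(conf1), target)) next
      }
      if (!validateConformerGeometry(conf1, info, restraints$graphDist)) next
      ePost <- tryCatch(obEnergy(conf1, ff), error = function(e) NA_real_)
      if (!is.finite(ePost)) next
      got <- list(conf = conf1, ePre = ePre, ePost = ePost,
                  subSeed = subSeed, attempt = attempt, mirrored = mirrored)
      break
    }
    if (is.null(got)) {
      stop("conformer embedding failed for ", cmp$id, " after ", maxAttempts,
           " attempts (ensemble member ", k, ")", call. = FALSE)
    }
    if (is.null(best) || got$ePost < best$ePost) best <- got
  }
  conf <- best$conf
  conf@provenance <- list(
    method = "distance-geometry embedding + force-field minimization",
    seed = seed, sub_seed = best$subSeed, attempt = best$attempt,
    ensemble_size = ensembleSize,
    minimizer = paste0(ff, " crit=", format(crit)),
    energy_pre = best$ePre, energy = best$ePost,
    mirrored_for_configuration = best$mirrored,
    smiles = target)
  conf
}

#' Assign partial atomic charges to a conformer
#'
#' Charges come from an iterative electronegativity-equalization scheme
#' (Gasteiger-Marsili by default) and sum to the molecule's total formal
#' charge. They stand in for the semiempirical charge sets used in the
#' original modelling and are flagged as approximate in descriptor output.
#'
#' @param conf A [Conformer-class].
#' @param method Charge model passed to OpenBabel (`"gasteiger"`, `"eem"`,
#'   `"mmff94"`, ...).
#' @return The conformer with the `charges` slot filled and the method
#'   recorded in its provenance.
#' @export
assignPartialCharges <- function(conf, method = "gasteiger") {
  q <- obPartialCharges(conf, method = method)
  total <- sum(conf@formalCharges)
  if (abs(sum(q) - total) > 0.01) {
    stop("partial charges sum to ", format(sum(q)),
         " but total formal charge is ", total, call. = FALSE)
  }
  ## spread the interchange-format rounding residual uniformly so the sum
  ## matches the total formal charge exactly
  q <- q - (sum(q) - total) / length(q)
  conf@charges <- q
  conf@provenance$charge_method <- method
  conf
}
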