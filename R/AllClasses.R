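#' Conformer: one 3D embedding of a compound
#'
#' Holds per-atom element symbols, Cartesian coordinates in Angstrom, the
#' bond list with orders, formal charges, optional partial charges (e) and a
#' provenance record (embedding method, seed, minimizer, energies). Atom
#' indices are 1-based throughout the package's R interfaces.
#'
#' @slot compoundId Identifier of the parent compound.
#' @slot elements Character vector of element symbols, one per atom.
#' @slot coords Numeric matrix, n x 3, Angstrom.
#' @slot bonds Integer matrix, m x 3 (`a`, `b`, `order`).
#' @slot formalCharges Numeric vector of formal charges per atom.
#' @slot charges Numeric vector of partial charges per atom (length 0 until
#'   assigned).
#' @slot provenance Named list recording how the geometry was produced.
#' @aliases Conformer
#' @exportClass Conformer
setClass("Conformer",
  representation(
    compoundId = "character",
    elements = "character",
    coords = "matrix",
    bonds = "matrix",
    formalCharges = "numeric",
    charges = "numeric",
    provenance = "list"
  ),
  prototype(charges = numeric(0), provenance = list())
)

setValidity("Conformer", function(object) {
  n <- length(object@elements)
  msg <- character()
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L ||
      nrow(object@coords) != n) {
    msg <- c(msg, "coords must be an n x 3 numeric matrix")
  } else if (!all(is.finite(object@coords))) {
    msg <- c(msg, "coordinates must be finite")
  }
  if (length(object@formalCharges) != n) {
    msg <- c(msg, "formalCharges must have one entry per atom")
  }
  if (length(object@charges) && length(object@charges) != n) {
    msg <- c(msg, "charges, when present, must have one entry per atom")
  }
  b <- object@bonds
  if (nrow(b) && (any(b[, 1:2] < 1L) || any(b[, 1:2] > n))) {
    msg <- c(msg, "bond indices out of range")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Conformer-class Number of atoms.
#' @param x,object A `Conformer`.
#' @export
setMethod("length", "Conformer", function(x) length(x@elements))

#' @export
setMethod("show", "Conformer", function(object) {
  cat("Conformer of", object@compoundId, "-", length(object@elements),
      "atoms,", nrow(object@bonds), "bonds\n")
  if (!is.null(object@provenance$method)) {
    cat("  geometry:", object@provenance$method, "\n")
  }
  if (!is.null(object@provenance$energy)) {
    cat("  energy:", format(object@provenance$energy), "kcal/mol\n")
  }
  if (length(object@charges)) {
    cat("  partial charges:", object@provenance$charge_method %||% "assigned",
        "(sum", format(round(sum(object@charges), 4)), "e)\n")
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accessors for Conformer slots
#'
#' @param conf A [Conformer-class] object.
#' @return `atomElements`: character vector; `atomCoords`: n x 3 matrix (A);
#'   `bondTable`: integer matrix with columns `a`, `b`, `order`;
#'   `partialCharges`: numeric vector (error if not yet assigned);
#'   `conformerProvenance`: named list.
#' @name conformer-accessors
NULL

#' @rdname conformer-accessors
#' @export
atomElements <- function(conf) conf@elements

#' @rdname conformer-accessors
#' @export
atomCoords <- function(conf) conf@coords

#' @rdname conformer-accessors
#' @export
bondTable <- function(conf) conf@bonds

#' @rdname conformer-accessors
#' @export
partialCharges <- function(conf) {
  if (!length(conf@charges)) {
    stop("conformer has no partial charges; run assignPartialCharges() first",
         call. = FALSE)
  }
  conf@charges
}

#' @rdname conformer-accessors
#' @export
conformerProvenance <- function(conf) conf@provenance

#' QsarModel: a fitted multilinear structure-activity model
#'
#' Ordinary least squares with intercept of a log-affinity response on a
#' named subset of molecular descriptors, together with the model statistics
#' used in this study: R^2 = 1 - SSE/SST (SST about the mean),
#' RMSE = sqrt(SSE/N), and the Fisher statistic
#' F = (R^2/k) / ((1 - R^2)/(N - k - 1)).
#'
#' @slot descriptors Ordered character vector of descriptor names.
#' @slot coefficients Named numeric vector, intercept first.
#' @slot N,k Sample count and descriptor count.
#' @slot R2,RMSE,F Model statistics as defined above.
#' @slot fitted,residuals Named per-compound predicted affinities and
#'   residuals (observed minus predicted).
#' @slot response Name of the response column.
#' @slot mode `"paper-reproduction"` (fixture descriptors) or
#'   `"new-compound"` (computed descriptors).
#' @aliases QsarModel
#' @exportClass QsarModel
setClass("QsarModel",
  representation(
    descriptors = "character",
    coefficients = "numeric",
    N = "integer",
    k = "integer",
    R2 = "numeric",
    RMSE = "numeric",
    F = "numeric",
    fitted = "numeric",
    residuals = "numeric",
    response = "character",
    mode = "character"
  )
)

setValidity("QsarModel", function(object) {
  msg <- character()
  if (object@RMSE < 0) msg <- c(msg, "RMSE must be non-negative")
  if (length(object@coefficients) != object@k + 1L) {
    msg <- c(msg, "coefficient count must be k + 1")
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "QsarModel", function(object) {
  cat("QsarModel (", object@mode, " mode): ", object@response, " ~ ",
      paste(object@descriptors, collapse = " + "), "\n", sep = "")
  cat(" ", equationString(object), "\n")
  cat(sprintf("  N = %d, k = %d, R2 = %.3f, RMSE = %.3f, F = %s\n",
              object@N, object@k, object@R2, object@RMSE,
              if (is.finite(object@F)) sprintf("%.2f", object@F) else "Inf"))
})
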