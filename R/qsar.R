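## Multilinear QSAR: ordinary least squares of log-affinity on descriptor
## subsets with the study's statistics conventions: R^2 = 1 - SSE/SST,
## RMSE = sqrt(SSE/N) (denominator N, not residual df), and the Fisher
## statistic F = (R^2/k) / ((1 - R^2)/(N - k - 1)).

#' Fit a multilinear QSAR model
#'
#' Ordinary least squares with intercept of a response column on a named
#' descriptor subset.
#'
#' @param data A descriptor table (e.g. from [loadDescriptorTable()] or
#'   [syntheticDescriptorTable()]); rows are compounds.
#' @param subset Character vector of descriptor column names.
#' @param response Response column name (default `"dG_exp"`).
#' @param mode Provenance tag: `"paper-reproduction"` for the packaged
#'   fixture descriptors, `"new-compound"` for computed descriptors.
#' @return A [QsarModel-class].
#' @examples
#' tab4 <- loadDescriptorTable(fixturePath("descriptors"))
#' fitQsar(tab4, c("S_vdW", "A_vdW", "S_wat"))
#' @export
fitQsar <- function(data, subset, response = "dG_exp",
                    mode = c("paper-reproduction", "new-compound")) {
  mode <- match.arg(mode)
  missing <- setdiff(c(subset, response), names(data))
  if (length(missing)) {
    stop("column(s) not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  N <- nrow(data)
  k <- length(subset)
  if (N <= k + 1L) {
    stop("need N > k + 1 observations (N = ", N, ", k = ", k, ")",
         call. = FALSE)
  }
  X <- as.matrix(data[, subset, drop = FALSE])
  if (qr(cbind(1, X))$rank < k + 1L) {
    cors <- stats::cor(X)
    pairs <- which(abs(cors) > 1 - 1e-8 & upper.tri(cors), arr.ind = TRUE)
    detail <- if (nrow(pairs)) {
      paste(apply(pairs, 1, function(p)
        paste(subset[p[1]], subset[p[2]], sep = " ~ ")), collapse = ", ")
    } else "see design matrix"
    stop("rank-deficient design; collinear columns: ", detail, call. = FALSE)
  }
  y <- data[[response]]
  fit <- stats::lm(y ~ X)
  nm <- if (!is.null(data$compound)) data$compound else as.character(seq_len(N))
  fitted <- stats::setNames(as.numeric(stats::fitted(fit)), nm)
  res <- stats::setNames(as.numeric(stats::residuals(fit)), nm)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  R2 <- 1 - sse / sst
  Fst <- if (R2 >= 1) Inf else (R2 / k) / ((1 - R2) / (N - k - 1))
  methods::new("QsarModel",
               descriptors = subset,
               coefficients = stats::setNames(as.numeric(stats::coef(fit)),
                                              c("(Intercept)", subset)),
               N = as.integer(N), k = as.integer(k),
               R2 = R2, RMSE = sqrt(sse / N), F = Fst,
               fitted = fitted, residuals = res,
               response = response, mode = mode)
}

#' Model statistics used by the study
#'
#' `rSquared` is `1 - SSE/SST` with SST about the mean of the observations;
#' `rmse` is `sqrt(SSE/N)` (denominator N); `fStatistic` is
#' `(R2/k) / ((1-R2)/(N-k-1))`, infinite for a perfect fit.
#'
#' @param fitted,observed Numeric vectors.
#' @param residuals Numeric residual vector.
#' @param N,k Sample and descriptor counts.
#' @param R2 Coefficient of determination.
#' @return A number.
#' @export
rSquared <- function(fitted, observed) {
  1 - sum((observed - fitted)^2) / sum((observed - mean(observed))^2)
}

#' @rdname rSquared
#' @export
rmse <- function(residuals, N = length(residuals)) {
  sqrt(sum(residuals^2) / N)
}

#' @rdname rSquared
#' @export
fStatistic <- function(R2, k, N) {
  if (R2 >= 1) return(Inf)
  (R2 / k) / ((1 - R2) / (N - k - 1))
}

#' Predict log-affinity for new descriptor rows
#'
#' @param object A [QsarModel-class].
#' @param newdata A data frame containing the model's descriptor columns.
#' @param ... Ignored.
#' @return Numeric predictions.
#' @export
setMethod("predict", "QsarModel", function(object, newdata, ...) {
  X <- as.matrix(newdata[, object@descriptors, drop = FALSE])
  as.numeric(object@coefficients[1] +
               X %*% object@coefficients[-1])
})

#' Residual affinity
#'
#' The residual `observed - predicted`, the per-compound error estimate of
#' the regression.
#'
#' @param observed,predicted Numeric vectors on the log-affinity scale.
#' @return `observed - predicted`.
#' @export
residualAffinity <- function(observed, predicted) observed - predicted

#' Exhaustive descriptor-subset search
#'
#' Enumerates every descriptor subset of size `k`, fits each by OLS, and
#' ranks the models by R^2 (ties by F, then lexicographically by descriptor
#' names, for determinism). Subsets whose design is rank-deficient are
#' dropped with a warning.
#'
#' @inheritParams fitQsar
#' @param k Subset size (`k <` number of candidate descriptors, except
#'   `k =` all of them, which yields the single full model).
#' @param descriptors Candidate columns; default the five standard ones
#'   present in `data`.
#' @return List of [QsarModel-class] objects, best first, with a
#'   `"ranking"` attribute (data frame of subset, R2, RMSE, F).
#' @examples
#' tab4 <- loadDescriptorTable(fixturePath("descriptors"))
#' top <- subsetSearch(tab4, k = 3)
#' attr(top, "ranking")
#' @export
subsetSearch <- function(data, k, response = "dG_exp", descriptors = NULL,
                         mode = c("paper-reproduction", "new-compound")) {
  mode <- match.arg(mode)
  if (is.null(descriptors)) {
    descriptors <- intersect(c("d", "S_vdW", "S_wat", "A_vdW", "mu_D"),
                             names(data))
  }
  stopifnot(k >= 1L, k <= length(descriptors))
  sets <- utils::combn(sort(descriptors), k, simplify = FALSE)
  models <- list()
  for (s in sets) {
    m <- tryCatch(fitQsar(data, s, response = response, mode = mode),
                  error = function(e) NULL)
    if (is.null(m)) {
      warning("subset {", paste(s, collapse = ", "),
              "} dropped (rank-deficient)", call. = FALSE)
    } else {
      models[[length(models) + 1L]] <- m
    }
  }
  key <- vapply(models, function(m) paste(m@descriptors, collapse = ","),
                character(1))
  ord <- order(-vapply(models, methods::slot, numeric(1), "R2"),
               -vapply(models, methods::slot, numeric(1), "F"),
               key)
  models <- models[ord]
  attr(models, "ranking") <- data.frame(
    subset = key[ord],
    R2 = vapply(models, methods::slot, numeric(1), "R2"),
    RMSE = vapply(models, methods::slot, numeric(1), "RMSE"),
    F = vapply(models, methods::slot, numeric(1), "F"),
    stringsAsFactors = FALSE
  )
  models
}

#' Leave-one-out cross-validation
#'
#' Refits the model N times, each time holding out one compound, and
#' summarizes predictivity as `Q2 = 1 - PRESS/SST`.
#'
#' @inheritParams fitQsar
#' @return List with `predictions` (held-out predictions, in row order),
#'   `Q2`, and `press`.
#' @export
looCv <- function(data, subset, response = "dG_exp") {
  N <- nrow(data)
  preds <- numeric(N)
  for (i in seq_len(N)) {
    m <- fitQsar(data[-i, , drop = FALSE], subset, response = response)
    preds[i] <- predict(m, data[i, , drop = FALSE])
  }
  y <- data[[response]]
  press <- sum((y - preds)^2)
  list(predictions = preds, Q2 = 1 - press / sum((y - mean(y))^2),
       press = press)
}

#' Format a fitted model as an equation string
#'
#' @param model A [QsarModel-class].
#' @param digits Coefficient digits.
#' @return A string like
#'   `"dG = -4.19 + 0.13*S_vdW - 0.20*A_vdW + 0.04*S_wat"`.
#' @export
equationString <- function(model, digits = 2) {
  co <- model@coefficients
  terms <- sprintf("%s %s*%s", ifelse(co[-1] < 0, "-", "+"),
                   formatC(abs(co[-1]), format = "f", digits = digits),
                   model@descriptors)
  paste0("dG = ", formatC(co[1], format = "f", digits = digits), " ",
         paste(terms, collapse = " "))
}

#' Serialize a fitted model to a report list
#'
#' @param model A [QsarModel-class].
#' @param observed Optional observed response (adds a per-compound table).
#' @return A list suitable for `jsonlite::toJSON()`.
#' @export
qsarReport <- function(model, observed = NULL) {
  rep_ <- list(
    mode = model@mode,
    response = model@response,
    descriptors = model@descriptors,
    equation = equationString(model),
    coefficients = as.list(model@coefficients),
    N = model@N, k = model@k,
    R2 = model@R2, RMSE = model@RMSE, F = model@F
  )
  tab <- data.frame(compound = names(model@fitted),
                    dG_pred = as.numeric(model@fitted),
                    dG_res = as.numeric(model@residuals),
                    stringsAsFactors = FALSE)
  if (!is.null(observed)) tab <- cbind(dG_exp = observed, tab)
  rep_$per_compound <- tab
  rep_
}
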