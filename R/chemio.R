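#' Registry of the fourteen 1,4-disubstituted piperidine ligands
#'
#' Returns the study's compound set: six 4-aroylpiperidine ketones (series
#' "7"), six 4-(alpha-hydroxybenzyl)piperidine alcohols (series "8") and two
#' N-(3-bromobenzyl)amine analogues (series "9"). Structures are encoded as
#' SMILES derived from the systematic names; chiral members (the carbinol
#' carbon of series 8, the benzylic amine carbon of series 9) are stored as
#' the R-isomers, the configuration used throughout the modelling.
#'
#' @return A `data.frame` with columns `id`, `series` (`"ketone"`,
#'   `"alcohol"` or `"amine"`), `substituent` (pattern on the N-benzyl ring),
#'   `iupac_name` and `smiles`.
#' @examples
#' reg <- compoundRegistry()
#' reg[reg$id == "7e", ]
#' @export
compoundRegistry <- function() {
  reg <- data.frame(
    id = c("7a", "7b", "7c", "7d", "7e", "7f",
           "8a", "8b", "8c", "8d", "8e", "8f",
           "9d", "9e"),
    series = rep(c("ketone", "alcohol", "amine"), c(6L, 6L, 2L)),
    substituent = c("4''-F", "3'',4''-Cl2", "4''-Cl", "2''-NO2", "4''-Br",
                    "4''-Me",
                    "4''-F", "3'',4''-Cl2", "4''-Cl", "2''-NO2", "4''-Br",
                    "4''-Me",
                    "2''-NO2", "4''-Br"),
    iupac_name = c(
      "4-(4-fluorobenzoyl)-1-[(4-fluorophenyl)methyl]piperidine",
      "1-[(3,4-dichlorophenyl)methyl]-4-(4-fluorobenzoyl)piperidine",
      "1-[(4-chlorophenyl)methyl]-4-(4-fluorobenzoyl)piperidine",
      "4-(4-fluorobenzoyl)-1-[(2-nitrophenyl)methyl]piperidine",
      "1-[(4-bromophenyl)methyl]-4-(4-fluorobenzoyl)piperidine",
      "4-(4-fluorobenzoyl)-1-[(4-methylphenyl)methyl]piperidine",
      "(R)-(4-fluorophenyl)({1-[(4-fluorophenyl)methyl]piperidin-4-yl})methanol",
      "(R)-{1-[(3,4-dichlorophenyl)methyl]piperidin-4-yl}(4-fluorophenyl)methanol",
      "(R)-{1-[(4-chlorophenyl)methyl]piperidin-4-yl}(4-fluorophenyl)methanol",
      "(R)-(4-fluorophenyl)({1-[(2-nitrophenyl)methyl]piperidin-4-yl})methanol",
      "(R)-{1-[(4-bromophenyl)methyl]piperidin-4-yl}(4-fluorophenyl)methanol",
      "(R)-(4-fluorophenyl)({1-[(4-methylphenyl)methyl]piperidin-4-yl})methanol",
      "(R)-[(3-bromophenyl)methyl][(4-fluorophenyl)({1-[(2-nitrophenyl)methyl]piperidin-4-yl})methyl]amine",
      "(R)-[(3-bromophenyl)methyl]({1-[(4-bromophenyl)methyl]piperidin-4-yl}(4-fluorophenyl)methyl)amine"
    ),
    smiles = c(
      "O=C(c1ccc(F)cc1)C1CCN(Cc2ccc(F)cc2)CC1",
      "O=C(c1ccc(F)cc1)C1CCN(Cc2ccc(Cl)c(Cl)c2)CC1",
      "O=C(c1ccc(F)cc1)C1CCN(Cc2ccc(Cl)cc2)CC1",
      "O=C(c1ccc(F)cc1)C1CCN(Cc2ccccc2[N+](=O)[O-])CC1",
      "O=C(c1ccc(F)cc1)C1CCN(Cc2ccc(Br)cc2)CC1",
      "O=C(c1ccc(F)cc1)C1CCN(Cc2ccc(C)cc2)CC1",
      "O[C@@H](c1ccc(F)cc1)C1CCN(Cc2ccc(F)cc2)CC1",
      "O[C@@H](c1ccc(F)cc1)C1CCN(Cc2ccc(Cl)c(Cl)c2)CC1",
      "O[C@@H](c1ccc(F)cc1)C1CCN(Cc2ccc(Cl)cc2)CC1",
      "O[C@@H](c1ccc(F)cc1)C1CCN(Cc2ccccc2[N+](=O)[O-])CC1",
      "O[C@@H](c1ccc(F)cc1)C1CCN(Cc2ccc(Br)cc2)CC1",
      "O[C@@H](c1ccc(F)cc1)C1CCN(Cc2ccc(C)cc2)CC1",
      "Brc1cccc(CN[C@@H](c2ccc(F)cc2)C2CCN(Cc3ccccc3[N+](=O)[O-])CC2)c1",
      "Brc1cccc(CN[C@@H](c2ccc(F)cc2)C2CCN(Cc3ccc(Br)cc3)CC2)c1"
    ),
    stringsAsFactors = FALSE
  )
  reg
}

#' Path to a packaged fixture table
#'
#' @param name `"binding"` for the sigma-1/sigma-2 Ki table (with censoring
#'   marks and printed selectivity ratios) or `"descriptors"` for the
#'   14-compound descriptor/affinity table.
#' @return Path to the installed CSV file.
#' @export
fixturePath <- function(name = c("binding", "descriptors")) {
  name <- match.arg(name)
  file <- c(binding = "table1_3_binding.csv",
            descriptors = "table4_descriptors.csv")[[name]]
  path <- system.file("extdata", file, package = "sigmaqsar", mustWork = TRUE)
  path
}

## Parse one Ki cell: "2.96±0.52" (uncertainty discarded), ">434" (left-censored
## at the assay ceiling, i.e. only a lower bound on Ki is known), or "5.98".
parseKiToken <- function(token, what = "Ki") {
  token <- gsub("±", "+/-", trimws(token))
  censored <- startsWith(token, ">")
  if (censored) token <- substring(token, 2L)
  value <- suppressWarnings(as.numeric(sub("\\+/-.*$", "", token)))
  if (is.na(value)) {
    stop("malformed ", what, " token: ", sQuote(token), call. = FALSE)
  }
  if (value <= 0) {
    stop("non-positive ", what, " value: ", value, call. = FALSE)
  }
  list(value = value, censored = censored)
}

#' Load a binding-affinity table with censored Ki values
#'
#' Reads a CSV with columns `compound,sigma1_ki,sigma2_ki,ratio`. Ki cells may
#' carry a `±` uncertainty (parsed and discarded; only the central value is
#' used downstream) or a `>` censoring mark (`>434` for sigma-1, `>854` for
#' sigma-2), meaning the affinity was weaker than the assay ceiling so only a
#' lower bound on Ki is known.
#'
#' @param path CSV file path.
#' @return A `data.frame` with columns `compound`, `sigma1_ki`,
#'   `sigma1_censored`, `sigma2_ki`, `sigma2_censored`, `ratio_printed`
#'   (the ratio column as printed, `NA` when absent).
#' @examples
#' binding <- loadBindingTable(fixturePath("binding"))
#' binding[binding$compound == "7e", ]
#' @export
loadBindingTable <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE,
                         fileEncoding = "UTF-8")
  needed <- c("compound", "sigma1_ki", "sigma2_ki", "ratio")
  if (!all(needed %in% names(raw))) {
    stop("binding table must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    stop("binding table ", sQuote(path), " contains no rows", call. = FALSE)
  }
  if (anyDuplicated(raw$compound)) {
    stop("duplicate compound id(s): ",
         paste(unique(raw$compound[duplicated(raw$compound)]), collapse = ", "),
         call. = FALSE)
  }
  s1 <- lapply(raw$sigma1_ki, parseKiToken, what = "sigma1 Ki")
  s2 <- lapply(raw$sigma2_ki, parseKiToken, what = "sigma2 Ki")
  data.frame(
    compound = raw$compound,
    sigma1_ki = vapply(s1, `[[`, numeric(1), "value"),
    sigma1_censored = vapply(s1, `[[`, logical(1), "censored"),
    sigma2_ki = vapply(s2, `[[`, numeric(1), "value"),
    sigma2_censored = vapply(s2, `[[`, logical(1), "censored"),
    ratio_printed = suppressWarnings(as.integer(raw$ratio)),
    stringsAsFactors = FALSE
  )
}

#' Load the descriptor/affinity table
#'
#' Reads a CSV with the nine-column layout
#' `compound,d,S_vdW,S_wat,A_vdW,mu_D,dG_exp,dG_pred,dG_res` and validates it:
#' surface areas must be positive with `S_wat > S_vdW` in every row, and the
#' residual column must satisfy `dG_res = dG_exp - dG_pred` to the stated
#' tolerance. A row whose residual matches only after a sign flip is accepted
#' with a warning (the bundled literature table contains one such printed sign
#' slip); any other violation is an error naming the row.
#'
#' @param path CSV file path.
#' @param expected_rows If non-`NULL`, error unless the table has exactly this
#'   many rows (the packaged fixture has 14).
#' @param tol Tolerance on the residual identity (printed rounding), default
#'   `0.01`.
#' @return A `data.frame` with the nine columns, numeric except `compound`.
#' @examples
#' tab4 <- loadDescriptorTable(fixturePath("descriptors"), expected_rows = 14)
#' tab4[tab4$compound == "7a", ]
#' @export
loadDescriptorTable <- function(path, expected_rows = NULL, tol = 0.01) {
  x <- utils::read.csv(path, strip.white = TRUE)
  needed <- c("compound", "d", "S_vdW", "S_wat", "A_vdW", "mu_D",
              "dG_exp", "dG_pred", "dG_res")
  if (!all(needed %in% names(x))) {
    stop("descriptor table must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, needed]
  if (!is.null(expected_rows) && nrow(x) != expected_rows) {
    stop("expected ", expected_rows, " rows, found ", nrow(x), call. = FALSE)
  }
  if (anyDuplicated(x$compound)) {
    stop("duplicate compound id(s) in descriptor table", call. = FALSE)
  }
  areas <- c("S_vdW", "S_wat", "A_vdW")
  if (any(as.matrix(x[areas]) <= 0) || any(x$d <= 0)) {
    stop("surface areas and density must be positive", call. = FALSE)
  }
  if (any(x$S_wat <= x$S_vdW)) {
    stop("S_wat must exceed S_vdW; violated for: ",
         paste(x$compound[x$S_wat <= x$S_vdW], collapse = ", "),
         call. = FALSE)
  }
  delta <- x$dG_exp - x$dG_pred
  ok <- abs(x$dG_res - delta) <= tol
  flipped <- !ok & abs(-x$dG_res - delta) <= tol
  if (any(flipped)) {
    warning("residual column sign slip (|dG_res| matches |dG_exp - dG_pred| ",
            "only after a sign flip) for: ",
            paste(x$compound[flipped], collapse = ", "), call. = FALSE)
  }
  bad <- !ok & !flipped
  if (any(bad)) {
    stop("dG_res != dG_exp - dG_pred (tol ", tol, ") for: ",
         paste(x$compound[bad], collapse = ", "), call. = FALSE)
  }
  x
}

#' Read chemical structures from an SDF or SMILES file
#'
#' Unparsable records are skipped with a warning giving their count; the
#' remaining records are canonicalized.
#'
#' @param path Input file.
#' @param format `"sdf"` or `"smiles"` (one record per line,
#'   `SMILES[<space>name]`).
#' @return A `data.frame` with columns `id` and `smiles` (canonical).
#' @export
readStructures <- function(path, format = c("sdf", "smiles")) {
  format <- match.arg(format)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      return(data.frame(id = character(), smiles = character(),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    smi <- vapply(parts, `[[`, character(1), 1L)
    id <- vapply(parts, function(p) if (length(p) > 1L) p[[2]] else "",
                 character(1))
    can <- canonicalSmiles(smi)
    keep <- !is.na(can)
    if (any(!keep)) {
      warning(sum(!keep), " unparsable SMILES record(s) skipped",
              call. = FALSE)
    }
    id[!nzchar(id)] <- paste0("mol", seq_along(id))[!nzchar(id)]
    return(data.frame(id = id[keep], smiles = can[keep],
                      stringsAsFactors = FALSE))
  }
  nrec <- sum(grepl("^\\${4}", readLines(path, warn = FALSE)))
  out <- obabelRun(path, informat = "sdf", outformat = "can")
  out <- out[nzchar(trimws(out))]
  parts <- strsplit(trimws(out), "[[:space:]]+")
  smi <- vapply(parts, `[[`, character(1), 1L)
  id <- vapply(parts, function(p) if (length(p) > 1L)
    paste(p[-1], collapse = " ") else "", character(1))
  if (length(smi) < nrec) {
    warning(nrec - length(smi), " unparsable SDF record(s) skipped",
            call. = FALSE)
  }
  id[!nzchar(id)] <- paste0("mol", seq_along(id))[!nzchar(id)]
  data.frame(id = id, smiles = smi, stringsAsFactors = FALSE)
}

#' Write chemical structures to an SDF or SMILES file
#'
#' @param compounds A `data.frame` with columns `id` and `smiles` (e.g. from
#'   [compoundRegistry()]), or a list of [Conformer-class] objects for
#'   coordinate-bearing SDF output.
#' @param path Output file.
#' @param format `"sdf"` or `"smiles"`.
#' @return `path`, invisibly.
#' @export
writeStructures <- function(compounds, path, format = c("sdf", "smiles")) {
  format <- match.arg(format)
  if (is.list(compounds) && !is.data.frame(compounds) &&
      all(vapply(compounds, methods::is, logical(1), "Conformer"))) {
    txt <- unlist(lapply(compounds, conformerToSdfText))
    writeLines(txt, path)
    return(invisible(path))
  }
  stopifnot(is.data.frame(compounds), all(c("id", "smiles") %in%
                                            names(compounds)))
  if (format == "smiles") {
    writeLines(paste(compounds$smiles, compounds$id), path)
    return(invisible(path))
  }
  tmp <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp))
  writeLines(paste(compounds$smiles, compounds$id), tmp)
  obabelRun(tmp, informat = "smi", outformat = "sdf", outfile = path)
  invisible(path)
}
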