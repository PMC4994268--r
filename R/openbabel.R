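## Thin wrappers around the OpenBabel command-line tools (obabel, obenergy).
## All stochastic steps live in R; OpenBabel is only used for deterministic
## operations: format conversion, canonicalization, force-field minimization
## from a given starting geometry, energies and partial charges.

obabelPath <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    stop("OpenBabel's 'obabel' executable was not found on PATH; ",
         "it is required for structure conversion and minimization",
         call. = FALSE)
  }
  p
}

## Run obabel on an input file; returns stdout lines unless outfile is given.
obabelRun <- function(infile, informat, outformat, outfile = NULL,
                      args = character()) {
  a <- c(paste0("-i", informat), infile, paste0("-o", outformat), args)
  if (!is.null(outfile)) a <- c(a, "-O", outfile)
  out <- suppressWarnings(system2(obabelPath(), shQuote(a), stdout = TRUE,
                                  stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("obabel exited with status ", status, call. = FALSE)
  }
  out
}

#' Canonical SMILES
#'
#' Canonicalizes a vector of SMILES strings; unparsable entries come back as
#' `NA`.
#'
#' @param smiles Character vector.
#' @return Character vector of canonical SMILES.
#' @export
canonicalSmiles <- function(smiles) {
  tmp <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp))
  writeLines(paste(smiles, seq_along(smiles)), tmp)
  out <- obabelRun(tmp, "smi", "can")
  out <- out[nzchar(trimws(out))]
  res <- rep(NA_character_, length(smiles))
  for (line in out) {
    p <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    idx <- suppressWarnings(as.integer(p[length(p)]))
    if (!is.na(idx) && idx >= 1 && idx <= length(smiles)) {
      res[idx] <- p[1]
    }
  }
  ## obabel stops a batch at a fatal parse error; retry leftovers singly so
  ## one bad record cannot mask the rest
  if (anyNA(res) && length(smiles) > 1L) {
    for (i in which(is.na(res))) {
      res[i] <- canonicalSmiles(smiles[i])
    }
  }
  res
}

## SMILES -> molecular graph with explicit hydrogens (no coordinates).
## Returns list(elements, bonds [m x 3: a, b, order], formalCharges).
smilesTopology <- function(smiles) {
  tmp <- tempfile(fileext = ".smi")
  sdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tmp, sdf)))
  writeLines(smiles, tmp)
  obabelRun(tmp, "smi", "sdf", outfile = sdf, args = "-h")
  txt <- readLines(sdf, warn = FALSE)
  if (length(txt) < 4L) stop("could not parse SMILES: ", smiles, call. = FALSE)
  parseSdfBlock(txt)
}

## Parse one V2000 molfile (first record) from its text lines.
parseSdfBlock <- function(txt) {
  counts <- txt[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1L) stop("malformed molfile counts line", call. = FALSE)
  atoms <- txt[5:(4 + na)]
  elements <- trimws(substr(atoms, 32, 34))
  coords <- cbind(
    as.numeric(substr(atoms, 1, 10)),
    as.numeric(substr(atoms, 11, 20)),
    as.numeric(substr(atoms, 21, 30))
  )
  bonds <- matrix(0L, nrow = nb, ncol = 3,
                  dimnames = list(NULL, c("a", "b", "order")))
  if (nb > 0L) {
    bl <- txt[(5 + na):(4 + na + nb)]
    bonds[, 1] <- as.integer(substr(bl, 1, 3))
    bonds[, 2] <- as.integer(substr(bl, 4, 6))
    bonds[, 3] <- as.integer(substr(bl, 7, 9))
  }
  fc <- numeric(na)
  for (line in grep("^M  CHG", txt, value = TRUE)) {
    f <- strsplit(trimws(sub("^M  CHG", "", line)), "[[:space:]]+")[[1]]
    f <- as.integer(f)
    k <- f[1]
    for (j in seq_len(k)) {
      fc[f[2 * j]] <- f[2 * j + 1]
    }
  }
  list(elements = elements, coords = coords, bonds = bonds,
       formalCharges = fc)
}

## V2000 molfile text for a Conformer (coordinates + graph + formal charges,
## provenance as SDF data fields).
conformerToSdfText <- function(conf) {
  el <- conf@elements
  xyz <- conf@coords
  b <- conf@bonds
  lines <- c(conf@compoundId, "  sigmaqsar", "")
  lines <- c(lines, sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                            length(el), nrow(b)))
  lines <- c(lines, sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    xyz[, 1], xyz[, 2], xyz[, 3], el))
  if (nrow(b) > 0L) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", b[, 1], b[, 2], b[, 3]))
  }
  chg <- which(conf@formalCharges != 0)
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg,
                                            conf@formalCharges[chg]),
                                    collapse = "")))
  }
  lines <- c(lines, "M  END")
  prov <- conf@provenance
  if (length(prov)) {
    for (nm in names(prov)) {
      val <- prov[[nm]]
      if (length(val) == 1L && is.atomic(val)) {
        lines <- c(lines, paste0("> <", nm, ">"), as.character(val), "")
      }
    }
  }
  if (length(conf@charges)) {
    lines <- c(lines, "> <partial_charges>",
               paste(sprintf("%.6f", conf@charges), collapse = " "), "")
  }
  c(lines, "$$$$")
}

## Force-field minimization of a conformer's coordinates (deterministic for a
## given input geometry). Returns the conformer with updated coordinates.
obMinimize <- function(conf, ff = "GAFF", crit = 1e-3, steps = 2500L) {
  fin <- tempfile(fileext = ".sdf")
  fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)))
  writeLines(conformerToSdfText(conf), fin)
  obabelRun(fin, "sdf", "sdf", outfile = fout,
            args = c("--minimize", "--ff", ff, "--crit", format(crit),
                     "--steps", format(steps)))
  parsed <- parseSdfBlock(readLines(fout, warn = FALSE))
  if (length(parsed$elements) != length(conf@elements)) {
    stop("minimization changed the atom count", call. = FALSE)
  }
  conf@coords <- parsed$coords
  conf
}

## Force-field energy (units are the force field's: kcal/mol for MMFF94,
## kJ/mol for GAFF/UFF/Ghemical; only comparisons within one field are used).
obEnergy <- function(conf, ff = "GAFF") {
  p <- Sys.which("obenergy")
  if (!nzchar(p)) stop("'obenergy' not found on PATH", call. = FALSE)
  fin <- tempfile(fileext = ".sdf")
  on.exit(unlink(fin))
  writeLines(conformerToSdfText(conf), fin)
  out <- suppressWarnings(system2(p, c("-ff", ff, shQuote(fin)),
                                  stdout = TRUE, stderr = FALSE))
  line <- grep("^TOTAL ENERGY", out, value = TRUE)
  if (!length(line)) stop("could not evaluate force-field energy",
                          call. = FALSE)
  as.numeric(strsplit(trimws(line[length(line)]), "[[:space:]]+")[[1]][4])
}

## Partial charges from OpenBabel (default Gasteiger-Marsili sigma charges,
## an iterative partial-equalization-of-orbital-electronegativity scheme).
obPartialCharges <- function(conf, method = "gasteiger") {
  fin <- tempfile(fileext = ".sdf")
  fout <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(fin, fout)))
  writeLines(conformerToSdfText(conf), fin)
  obabelRun(fin, "sdf", "mol2", outfile = fout,
            args = c("--partialcharge", method))
  txt <- readLines(fout, warn = FALSE)
  a0 <- grep("^@<TRIPOS>ATOM", txt)
  if (!length(a0)) {
    stop("partial-charge assignment failed (method ", method, ")",
         call. = FALSE)
  }
  sections <- grep("^@<TRIPOS>", txt)
  a1 <- min(c(sections[sections > a0], length(txt) + 1L))
  rows <- txt[(a0 + 1):(a1 - 1)]
  rows <- rows[nzchar(trimws(rows))]
  q <- vapply(strsplit(trimws(rows), "[[:space:]]+"), function(f)
    as.numeric(f[9]), numeric(1))
  if (length(q) != length(conf@elements) || anyNA(q)) {
    stop("partial-charge table does not cover every atom", call. = FALSE)
  }
  q
}

## Canonical SMILES of a 3D conformer (used to verify that embedding
## preserved the intended stereochemistry).
conformerCanonicalSmiles <- function(conf) {
  fin <- tempfile(fileext = ".sdf")
  on.exit(unlink(fin))
  writeLines(conformerToSdfText(conf), fin)
  out <- obabelRun(fin, "sdf", "can")
  out <- out[nzchar(trimws(out))]
  if (!length(out)) return(NA_character_)
  strsplit(trimws(out[1]), "[[:space:]]+")[[1]][1]
}
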