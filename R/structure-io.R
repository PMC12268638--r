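#' @include AllClasses.R AllGenerics.R
NULL

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.WATER_RESID <- c("HOH", "WAT")

# monatomic-ion element symbols recognised as cations/solvent ions
.ION_ELEMENTS <- c("K", "NA", "MG", "MN", "CA", "ZN", "LI", "RB", "CS", "CL")

.blank_na <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

# Canonical atom ordering and single-altloc normalisation.
# Policy: keep the highest-occupancy altloc; ties go to the
# alphabetically first label ("" sorts before "A").
.normalize_atoms <- function(a) {
  a$alt <- .blank_na(a$alt)
  a$insert <- .blank_na(a$insert)
  a$o[is.na(a$o)] <- 1
  a$b[is.na(a$b)] <- 0
  a$elesy <- toupper(.blank_na(a$elesy))
  # derive missing element symbols from the atom name; monatomic-ion
  # names matching their residue name (K, NA, MG, ...) keep both letters
  miss <- a$elesy == ""
  if (any(miss)) {
    tok <- toupper(gsub("[^A-Za-z]", "", a$elety[miss]))
    ion <- tok %in% .ION_ELEMENTS & tok == toupper(a$resid[miss])
    a$elesy[miss] <- ifelse(ion, tok, substr(tok, 1, 1))
  }
  key <- paste(a$chain, a$resno, a$insert, a$resid, a$elety, sep = "\r")
  if (anyDuplicated(key)) {
    keep <- unsplit(lapply(split(seq_along(key), key), function(idx) {
      o <- a$o[idx]
      best <- idx[o == max(o)]
      best <- best[order(a$alt[best])][1]
      idx == best
    }), key)
    a <- a[keep, , drop = FALSE]
  }
  a <- a[order(a$chain, a$resno, a$insert, a$elety), , drop = FALSE]
  a$eleno <- seq_len(nrow(a))
  rownames(a) <- NULL
  a[, .ATOM_COLS]
}

.read_cell_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) return(list(cell = numeric(0), sg = character(0)))
  ln <- cr[1]
  cell <- suppressWarnings(as.numeric(c(
    substr(ln, 7, 15), substr(ln, 16, 24), substr(ln, 25, 33),
    substr(ln, 34, 40), substr(ln, 41, 47), substr(ln, 48, 54))))
  sg <- trimws(substr(ln, 56, 66))
  list(cell = if (any(is.na(cell))) numeric(0) else cell,
       sg = if (nzchar(sg)) sg else character(0))
}

.read_cell_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    hit <- grep(paste0("^_", tag, "\\s"), lines, value = TRUE)
    if (!length(hit)) return(NA_real_)
    suppressWarnings(as.numeric(strsplit(trimws(hit[1]), "\\s+")[[1]][2]))
  }
  cell <- c(grab("cell.length_a"), grab("cell.length_b"),
            grab("cell.length_c"), grab("cell.angle_alpha"),
            grab("cell.angle_beta"), grab("cell.angle_gamma"))
  sg_line <- grep("^_(symmetry\\.space_group_name_H-M|space_group\\.name_H-M_alt)\\s",
                  lines, value = TRUE)
  sg <- if (length(sg_line)) {
    v <- trimws(sub("^\\S+\\s+", "", sg_line[1]))
    gsub("^['\"]|['\"]$", "", v)
  } else character(0)
  list(cell = if (any(is.na(cell))) numeric(0) else cell,
       sg = if (length(sg) && nzchar(sg)) sg else character(0))
}

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses the first model of a coordinate file into a [Structure-class].
#' Alternate locations are collapsed to the highest-occupancy copy
#' (ties resolved to the alphabetically first altloc label); waters and
#' heteroatoms are retained; the unit cell and space group are captured
#' when present.
#'
#' @param path path to the coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param id identifier to store; default is the filename stem.
#' @return a [Structure-class] object.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif"),
                          id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  parsed <- tryCatch({
    if (format == "pdb")
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    else
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  }, error = function(e)
    stop("failed to parse ", sQuote(path), " as ", format, ": ",
         conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0)
    stop("empty structure: no atoms parsed from ", sQuote(path))
  a$chain <- .blank_na(a$chain)
  a$chain[a$chain == ""] <- "A"
  a$type <- if ("type" %in% names(a) &&
                all(a$type %in% c("ATOM", "HETATM"))) a$type else "ATOM"
  a <- .normalize_atoms(a)
  meta <- if (format == "pdb") .read_cell_pdb(path) else .read_cell_cif(path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  new("Structure", identifier = id, atoms = a, model = 1L,
      unitCell = meta$cell, spaceGroup = meta$sg)
}

#' Construct a Structure from an atom table
#'
#' Mainly used by the synthetic-structure generators and tests.
#' The table is normalised (altloc collapse, canonical ordering).
#'
#' @param atoms data.frame with at least `chain, resno, resid, elety,
#'   x, y, z`; missing metadata columns are filled with defaults.
#' @param id identifier.
#' @param unitCell optional numeric(6).
#' @param spaceGroup optional character(1).
#' @return a [Structure-class].
#' @export
newStructure <- function(atoms, id = "structure", unitCell = numeric(0),
                         spaceGroup = character(0)) {
  defaults <- list(type = "ATOM", eleno = NA_integer_, alt = "",
                   insert = "", o = 1, b = 0, elesy = "")
  for (nm in names(defaults))
    if (!nm %in% names(atoms)) atoms[[nm]] <- defaults[[nm]]
  a <- .normalize_atoms(atoms)
  new("Structure", identifier = id, atoms = a, model = 1L,
      unitCell = unitCell, spaceGroup = spaceGroup)
}

#' Create an atom selection
#'
#' @param chain chain identifier or `"*"` for any chain.
#' @param ranges `NULL` (all residues), a 2-column matrix, or a list of
#'   `c(lower, upper)` inclusive residue-number intervals.  Overlapping
#'   or adjacent intervals are merged.
#' @param atomNames atom names to select (default `"CA"`).
#' @return an [AtomSelection-class].
#' @export
atomSelection <- function(chain = "*", ranges = NULL, atomNames = "CA") {
  if (is.null(ranges)) {
    m <- matrix(integer(0), ncol = 2)
  } else {
    if (is.list(ranges)) ranges <- do.call(rbind, ranges)
    m <- matrix(as.integer(ranges), ncol = 2)
    if (any(m[, 1] > m[, 2])) stop("interval with lower > upper")
    m <- m[order(m[, 1]), , drop = FALSE]
    # merge overlapping intervals
    if (nrow(m) > 1) {
      out <- m[1, , drop = FALSE]
      for (i in 2:nrow(m)) {
        if (m[i, 1] <= out[nrow(out), 2] + 1L)
          out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
        else out <- rbind(out, m[i, ])
      }
      m <- out
    }
  }
  colnames(m) <- c("lower", "upper")
  new("AtomSelection", chain = chain, ranges = m, atomNames = atomNames)
}

#' Parse a selection string
#'
#' Accepts the config syntax `"A:180-270,271-450"` (chain, colon,
#' comma-separated residue intervals).  `"*"` or an omitted chain part
#' selects all chains; a bare chain (`"A"`) selects the whole chain.
#'
#' @param text selection string.
#' @param atomNames atom names (default `"CA"`).
#' @return an [AtomSelection-class].
#' @export
parseSelection <- function(text, atomNames = "CA") {
  text <- trimws(text)
  if (grepl(":", text, fixed = TRUE)) {
    parts <- strsplit(text, ":", fixed = TRUE)[[1]]
    chain <- trimws(parts[1])
    body <- if (length(parts) > 1) trimws(parts[2]) else ""
  } else if (grepl("^[*A-Za-z0-9]$|^\\*$", text)) {
    chain <- text; body <- ""
  } else {
    chain <- "*"; body <- text
  }
  if (!nzchar(body)) return(atomSelection(chain, NULL, atomNames))
  iv <- lapply(strsplit(body, ",", fixed = TRUE)[[1]], function(tok) {
    tok <- trimws(tok)
    nums <- suppressWarnings(as.integer(strsplit(tok, "-", fixed = TRUE)[[1]]))
    if (any(is.na(nums))) stop("cannot parse interval: ", sQuote(tok))
    if (length(nums) == 1) c(nums, nums) else nums[1:2]
  })
  atomSelection(chain, iv, atomNames)
}

.in_selection_res <- function(a, sel) {
  ok <- rep(TRUE, nrow(a))
  if (sel@chain != "*") ok <- ok & a$chain == sel@chain
  if (nrow(sel@ranges) > 0) {
    inr <- rep(FALSE, nrow(a))
    for (i in seq_len(nrow(sel@ranges)))
      inr <- inr | (a$resno >= sel@ranges[i, 1] & a$resno <= sel@ranges[i, 2])
    ok <- ok & inr
  }
  ok
}

#' Select atoms from a structure
#'
#' Returns the atom records matching a selection, preserving the
#' structure's residue order.  Residues missing from the model are
#' silently absent (crystallographic disorder semantics); an empty
#' result is allowed.
#'
#' @param s a [Structure-class].
#' @param sel an [AtomSelection-class].
#' @return data.frame of atom records (possibly 0 rows).
#' @export
selectAtoms <- function(s, sel) {
  a <- atoms(s)
  ok <- .in_selection_res(a, sel) & a$elety %in% sel@atomNames
  out <- a[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.is_polymer_ca <- function(a) {
  a$elety == "CA" & a$elesy == "C" & !(a$resid %in% .WATER_RESID)
}

#' Extract the one-letter sequence of a chain
#'
#' Polymer residues are those carrying a Calpha atom (carbon element,
#' so calcium ions are excluded).  Residues outside the standard twenty
#' amino acids (e.g. phosphoserine SEP) become `"X"`.
#'
#' @param s a [Structure-class].
#' @param chain chain identifier.
#' @return a list with `sequence` (character string), `resno` (integer
#'   vector mapping string position to author residue number) and
#'   `insert` (insertion codes).
#' @export
chainSequence <- function(s, chain) {
  a <- atoms(s)
  if (!chain %in% a$chain)
    stop("chain ", sQuote(chain), " not present in ",
         sQuote(identifier(s)))
  ca <- a[a$chain == chain & .is_polymer_ca(a), , drop = FALSE]
  if (nrow(ca) == 0)
    return(list(sequence = "", resno = integer(0), insert = character(0)))
  letters1 <- unname(.AA3TO1[ca$resid])
  letters1[is.na(letters1)] <- "X"
  list(sequence = paste(letters1, collapse = ""),
       resno = ca$resno, insert = ca$insert)
}

#' Write a structure as PDB
#'
#' Produces PDB-format output that round-trips through [readStructure]
#' with identical atom count, names and coordinates to 3 decimals.  A
#' CRYST1 record is emitted when the structure carries a unit cell.
#'
#' @param s a [Structure-class]; must be non-empty.
#' @param path output file path.
#' @param format only `"pdb"` is supported.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(s, path, format = "pdb") {
  format <- match.arg(format, "pdb")
  a <- atoms(s)
  if (nrow(a) == 0) stop("refusing to write an empty structure")
  if (any(a$resno > 9999L | a$resno < -999L))
    stop("residue numbers outside the PDB fixed-column range ",
         "(-999..9999); cannot format without truncation")
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = a$type, resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$elety,
                     chain = a$chain, insert = ifelse(a$insert == "", NA,
                                                     a$insert),
                     alt = ifelse(a$alt == "", NA, a$alt),
                     o = a$o, b = a$b, elesy = a$elesy)
    TRUE
  }, error = function(e)
    stop("cannot write ", sQuote(path), ": ", conditionMessage(e),
         call. = FALSE))
  if (length(unitCell(s)) == 6) {
    cell <- unitCell(s)
    sg <- if (length(spaceGroup(s))) spaceGroup(s) else "P 1"
    cr <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                  cell[1], cell[2], cell[3], cell[4], cell[5], cell[6],
                  sg, 1L)
    writeLines(c(cr, readLines(path, warn = FALSE)), path)
  }
  invisible(path)
}

#' Rigidly transform all atoms of a structure
#'
#' Applies `x' = R x + t` to every atom position.
#'
#' @param s a [Structure-class].
#' @param R 3x3 rotation matrix.
#' @param t numeric(3) translation (A).
#' @return the transformed [Structure-class].
#' @export
transformStructure <- function(s, R, t = c(0, 0, 0)) {
  a <- atoms(s)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + t[1]
  a$y <- xyz[, 2] + t[2]
  a$z <- xyz[, 3] + t[3]
  initialize(s, atoms = a)
}

# Calpha coordinates of specific residues, in the given key order.
# keys: data.frame(chain, resno, insert). Errors listing missing keys
# when strict.
.residue_atom_coords <- function(s, keys, atomName = "CA", strict = TRUE) {
  a <- atoms(s)
  a <- a[a$elety == atomName, , drop = FALSE]
  akey <- paste(a$chain, a$resno, a$insert, sep = "\r")
  want <- paste(keys$chain, keys$resno, keys$insert, sep = "\r")
  idx <- match(want, akey)
  if (strict && anyNA(idx)) {
    missing <- keys[is.na(idx), , drop = FALSE]
    stop("missing ", atomName, " for residue(s): ",
         paste(paste0(missing$chain, ":", missing$resno, missing$insert),
               collapse = ", "))
  }
  cbind(a$x[idx], a$y[idx], a$z[idx])
}
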