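## structio: PDB coordinate input/output and labelled atom selection with
## robust handling of altlocs, unmodeled residues and ligands.  Fixed-column
## parsing and writing are delegated to bio3d; altloc resolution, MODEL-1
## restriction and the selection semantics live here.

#' Parsed macromolecular structure
#'
#' Atom records of the first MODEL of a PDB entry, with one atom per
#' (chain, residue, insertion code, atom name): alternate locations are
#' resolved to the highest-occupancy conformer (ties alphabetically).
#' Ligand (HETATM) records are retained and flagged `is_hetero`.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `altloc`,
#'   `res_name`, `chain_id`, `res_seq`, `i_code`, `x`, `y`, `z`,
#'   `occupancy`, `b_factor`, `element`, `is_hetero`.
#' @slot pdbID identifier string.
#' @export
setClass("PDBStructure",
  representation(atoms = "data.frame", pdbID = "character"),
  validity = function(object) {
    need <- c("serial", "name", "altloc", "res_name", "chain_id", "res_seq",
              "i_code", "x", "y", "z", "occupancy", "b_factor", "element",
              "is_hetero")
    if (!all(need %in% names(object@atoms)))
      return("atoms is missing required columns")
    if (nrow(object@atoms) == 0) return("structure must contain atoms")
    if (any(!is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
      return("coordinates must be finite")
    key <- with(object@atoms,
                paste(chain_id, res_seq, i_code, name, altloc))
    if (anyDuplicated(key)) return("duplicate atom records")
    TRUE
  })

#' @rdname PDBStructure-class
#' @param atoms atom data.frame (see slots).
#' @param pdbID identifier.
#' @export
newStructure <- function(atoms, pdbID = "XXXX") {
  new("PDBStructure", atoms = atoms, pdbID = pdbID)
}

setMethod("show", "PDBStructure", function(object) {
  a <- object@atoms
  cat(sprintf("PDBStructure %s: %d atoms (%d hetero), chains %s\n",
              object@pdbID, nrow(a), sum(a$is_hetero),
              paste(unique(a$chain_id), collapse = ", ")))
})

#' @rdname PDBStructure-class
#' @param s a `PDBStructure`.
#' @export
structureAtoms <- function(s) s@atoms

#' Chains of a structure
#' @param s a [PDBStructure-class].
#' @export
structureChains <- function(s) unique(s@atoms$chain_id)

## quick fixed-column sanity pass so malformed records fail with a line
## number instead of propagating NA coordinates
.validatePDBLines <- function(lines) {
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (!length(rec)) stop("no ATOM or HETATM records found")
  for (i in rec) {
    l <- lines[i]
    if (nchar(l) < 54)
      stop("malformed ATOM/HETATM record at line ", i, ": too short")
    coords <- suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                            substr(l, 39, 46),
                                            substr(l, 47, 54))))
    if (anyNA(coords))
      stop("malformed ATOM/HETATM record at line ", i,
           ": non-numeric coordinates")
    if (is.na(suppressWarnings(as.integer(substr(l, 23, 26)))))
      stop("malformed ATOM/HETATM record at line ", i,
           ": non-numeric residue number")
  }
  invisible(TRUE)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records of the first MODEL.  Alternate locations are
#' resolved by keeping the highest-occupancy conformer (ties broken
#' alphabetically by altloc identifier).  Waters (HOH) and hydrogens are
#' dropped by default; other HETATM residues (e.g. the estradiol ligand
#' EST) are kept with `is_hetero = TRUE`.
#'
#' @param file path to a PDB file, or `NULL` when `text` is given.
#' @param text character vector (or single newline-separated string) of
#'   PDB lines, parsed instead of `file`.
#' @param keepWaters keep HOH residues.
#' @param keepHydrogens keep hydrogen atoms.
#' @param pdbID identifier; defaults to the HEADER id or file name.
#' @return a [PDBStructure-class].
#' @export
readPDB <- function(file = NULL, text = NULL, keepWaters = FALSE,
                    keepHydrogens = FALSE, pdbID = NULL) {
  if (is.null(file) && is.null(text)) stop("supply file or text")
  if (!is.null(text)) {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file))
    writeLines(lines, file)
  } else {
    if (!file.exists(file)) stop("no such file: ", file)
    lines <- readLines(file, warn = FALSE)
  }
  ## restrict to the first MODEL before validation/parsing
  mdl <- grep("^ENDMDL", lines)
  if (length(mdl)) {
    first <- grep("^MODEL", lines)
    if (length(first) && mdl[1] > first[1]) {
      lines <- lines[seq_len(mdl[1])]
      file2 <- tempfile(fileext = ".pdb")
      writeLines(lines, file2)
      file <- file2
      on.exit(unlink(file2), add = TRUE)
    }
  }
  .validatePDBLines(lines)
  pdb <- bio3d::read.pdb(file, verbose = FALSE, multi = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = as.character(a$elety),
    altloc = ifelse(is.na(a$alt), "", as.character(a$alt)),
    res_name = as.character(a$resid),
    chain_id = ifelse(is.na(a$chain), "", as.character(a$chain)),
    res_seq = as.integer(a$resno),
    i_code = ifelse(is.na(a$insert), "", as.character(a$insert)),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b_factor = ifelse(is.na(a$b), 0, a$b),
    element = ifelse(is.na(a$elesy), "", as.character(a$elesy)),
    is_hetero = a$type == "HETATM",
    stringsAsFactors = FALSE)
  if (!keepWaters) atoms <- atoms[atoms$res_name != "HOH", , drop = FALSE]
  if (!keepHydrogens) {
    el <- toupper(trimws(atoms$element))
    guess <- ifelse(el == "", toupper(substr(trimws(atoms$name), 1, 1)), el)
    atoms <- atoms[guess != "H" & guess != "D", , drop = FALSE]
  }
  if (!nrow(atoms)) stop("structure is empty after filtering")
  ## altloc resolution: keep the highest-occupancy conformer per atom site,
  ## ties broken alphabetically ("" sorts first and wins over labelled)
  key <- with(atoms, paste(chain_id, res_seq, i_code, name, sep = "\r"))
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(match(atoms$chain_id, unique(atoms$chain_id)),
                       atoms$res_seq, atoms$i_code, atoms$serial), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  if (is.null(pdbID)) {
    hdr <- grep("^HEADER", lines, value = TRUE)
    pdbID <- if (length(hdr) && nchar(hdr[1]) >= 66)
      trimws(substr(hdr[1], 63, 66)) else
        toupper(sub("\\.pdb$", "", basename(if (is.character(file))
          file else "XXXX")))
    if (!nzchar(pdbID)) pdbID <- "XXXX"
  }
  newStructure(atoms, pdbID = pdbID)
}

#' Write a structure in PDB format
#'
#' Coordinates are written at the format's 3-decimal precision, so a
#' read/write/read round trip preserves them to 0.001 Angstrom.
#'
#' @param s a [PDBStructure-class].
#' @param file output path.
#' @export
writePDB <- function(s, file) {
  a <- s@atoms
  bio3d::write.pdb(file = file,
                   type = ifelse(a$is_hetero, "HETATM", "ATOM"),
                   eleno = a$serial, elety = a$name, alt = a$altloc,
                   resid = a$res_name, chain = a$chain_id,
                   resno = a$res_seq, insert = a$i_code,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   o = a$occupancy, b = a$b_factor, elesy = a$element)
  invisible(file)
}

#' Residue range selection
#'
#' @slot chain chain identifier.
#' @slot start,end inclusive residue bounds (author numbering); ranges
#'   match records with an empty insertion code.
#' @slot atomFilter `"CA"`, `"backbone"` (N, CA, C, O) or `"heavy"`.
#' @export
setClass("ResidueRange",
  representation(chain = "character", start = "integer", end = "integer",
                 atomFilter = "character"),
  validity = function(object) {
    if (object@start > object@end) return("start must be <= end")
    if (!object@atomFilter %in% c("CA", "backbone", "heavy"))
      return("atomFilter must be CA, backbone or heavy")
    TRUE
  })

#' @rdname ResidueRange-class
#' @param chain,start,end,atomFilter see slots.
#' @export
residueRange <- function(chain, start, end,
                         atomFilter = c("backbone", "CA", "heavy")) {
  new("ResidueRange", chain = as.character(chain),
      start = as.integer(start), end = as.integer(end),
      atomFilter = match.arg(atomFilter))
}

setMethod("show", "ResidueRange", function(object) {
  cat(sprintf("ResidueRange %s:%d-%d (%s)\n", object@chain, object@start,
              object@end, object@atomFilter))
})

#' Parse range specifications like `"A:263-468,A:502-530"`
#'
#' @param spec comma-separated `chain:start-end` tokens.
#' @param atomFilter filter applied to every range.
#' @return list of [ResidueRange-class].
#' @export
parseRangeSpec <- function(spec, atomFilter = "backbone") {
  toks <- strsplit(trimws(strsplit(spec, ",", fixed = TRUE)[[1]]), ":")
  lapply(toks, function(t) {
    if (length(t) != 2) stop("bad range token: ", paste(t, collapse = ":"))
    be <- as.integer(strsplit(t[2], "-", fixed = TRUE)[[1]])
    residueRange(t[1], be[1], be[2], atomFilter)
  })
}

#' Labelled coordinate set
#'
#' An ordered set of labelled points extracted from a structure; `labels`
#' and `xyz` are index-aligned.
#'
#' @slot labels data.frame with columns `chain`, `res_seq`, `atom`.
#' @slot xyz n x 3 coordinate matrix (Angstrom).
#' @slot coverage number of requested residues actually present.
#' @slot requested number of residues requested.
#' @export
setClass("CoordinateSet",
  representation(labels = "data.frame", xyz = "matrix",
                 coverage = "integer", requested = "integer"),
  validity = function(object) {
    if (nrow(object@labels) != nrow(object@xyz))
      return("labels and xyz must have equal length")
    if (ncol(object@xyz) != 3) return("xyz must be n x 3")
    TRUE
  })

setMethod("show", "CoordinateSet", function(object) {
  cat(sprintf("CoordinateSet: %d atoms, %d/%d residues covered\n",
              nrow(object@xyz), object@coverage, object@requested))
})

#' @rdname CoordinateSet-class
#' @param cs a `CoordinateSet`.
#' @export
coords <- function(cs) cs@xyz

#' @rdname CoordinateSet-class
#' @export
coordLabels <- function(cs) cs@labels

#' @rdname CoordinateSet-class
#' @export
coverage <- function(cs) c(found = cs@coverage, requested = cs@requested)

.backboneOrder <- c("N", "CA", "C", "O")

#' Select atoms by residue range
#'
#' Atoms are returned in residue order; within a residue, backbone
#' selections follow the canonical N, CA, C, O order.  Residues missing
#' from the model are silently skipped but reflected in the coverage
#' count.  Hydrogens and waters are assumed already excluded by
#' [readPDB()].
#'
#' @param s a [PDBStructure-class].
#' @param range a [ResidueRange-class] or a list of them (concatenated in
#'   order).
#' @return a [CoordinateSet-class].
#' @export
selectAtoms <- function(s, range) {
  ranges <- if (is(range, "ResidueRange")) list(range) else range
  lab <- list(); pts <- list()
  found <- 0L; requested <- 0L
  for (r in ranges) {
    if (!r@chain %in% s@atoms$chain_id)
      stop("chain ", r@chain, " not present in structure ", s@pdbID)
    a <- s@atoms[s@atoms$chain_id == r@chain &
                   s@atoms$res_seq >= r@start &
                   s@atoms$res_seq <= r@end &
                   s@atoms$i_code == "", , drop = FALSE]
    if (r@atomFilter == "CA") {
      a <- a[a$name == "CA", , drop = FALSE]
    } else if (r@atomFilter == "backbone") {
      a <- a[a$name %in% .backboneOrder, , drop = FALSE]
      a <- a[order(a$res_seq, match(a$name, .backboneOrder)), , drop = FALSE]
    }
    requested <- requested + (r@end - r@start + 1L)
    found <- found + length(unique(a$res_seq))
    lab[[length(lab) + 1L]] <-
      data.frame(chain = a$chain_id, res_seq = a$res_seq, atom = a$name,
                 stringsAsFactors = FALSE)
    pts[[length(pts) + 1L]] <- as.matrix(a[, c("x", "y", "z")])
  }
  labels <- do.call(rbind, lab)
  xyz <- do.call(rbind, pts)
  if (is.null(xyz) || nrow(xyz) == 0)
    stop("selection matched zero atoms")
  rownames(labels) <- NULL; rownames(xyz) <- NULL
  new("CoordinateSet", labels = labels, xyz = xyz,
      coverage = found, requested = requested)
}

#' Restrict two coordinate sets to their common atoms
#'
#' Atoms are matched on residue number and atom name (chain-agnostic, so
#' that equivalent selections from structures with different chain labels
#' pair up).  Order follows the first set.
#'
#' @param a,b [CoordinateSet-class] objects.
#' @return list with elements `a` and `b`, equal-length subsets.
#' @export
pairCommonAtoms <- function(a, b) {
  ka <- paste(a@labels$res_seq, a@labels$atom)
  kb <- paste(b@labels$res_seq, b@labels$atom)
  common <- intersect(ka, kb)
  if (!length(common))
    stop("coordinate sets share no atoms (disjoint residue numbering?)")
  ia <- which(ka %in% common)
  ib <- match(ka[ia], kb)
  sub <- function(cs, i) {
    new("CoordinateSet", labels = cs@labels[i, , drop = FALSE],
        xyz = cs@xyz[i, , drop = FALSE],
        coverage = length(unique(cs@labels$res_seq[i])),
        requested = cs@requested)
  }
  list(a = sub(a, ia), b = sub(b, ib))
}

#' Chain and residue inventory
#'
#' One row per (chain, residue) with atom counts and hetero flag; the
#' table printed by the `fetch-check` command-line tool.
#'
#' @param s a [PDBStructure-class].
#' @return data.frame with columns `chain`, `res_seq`, `res_name`,
#'   `n_atoms`, `hetero`.
#' @export
residueInventory <- function(s) {
  a <- s@atoms
  key <- paste(a$chain_id, a$res_seq, a$res_name)
  agg <- aggregate(a$serial, by = list(chain = a$chain_id,
                                       res_seq = a$res_seq,
                                       res_name = a$res_name,
                                       hetero = a$is_hetero), FUN = length)
  names(agg)[5] <- "n_atoms"
  agg <- agg[order(agg$chain, agg$res_seq), c("chain", "res_seq",
                                              "res_name", "n_atoms",
                                              "hetero")]
  rownames(agg) <- NULL
  agg
}

#' Residues of a chain present in the model
#'
#' @param s a [PDBStructure-class].
#' @param chain chain id.
#' @param heteroOk include hetero residues.
#' @return sorted integer vector of residue numbers.
#' @export
modeledResidues <- function(s, chain, heteroOk = FALSE) {
  a <- s@atoms[s@atoms$chain_id == chain, , drop = FALSE]
  if (!heteroOk) a <- a[!a$is_hetero, , drop = FALSE]
  sort(unique(a$res_seq))
}
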