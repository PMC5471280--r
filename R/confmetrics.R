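## confmetrics: pairwise structural metrics between conformers --
## superposition, core-aligned region RMSD, helix displacement angles,
## charge-clamp distance, contact maps, geometric hydrogen bonds,
## projection onto RMSD reaction coordinates and trajectory RMSD
## distributions.

#' Rigid-body superposition result
#'
#' Least-squares fit of a mobile set onto a reference, restricted to
#' proper rotations (no reflection).  The transform maps mobile
#' coordinates as `x' = x R^T + t` (row-vector convention).
#'
#' @slot rotation 3 x 3 proper rotation matrix.
#' @slot translation length-3 translation (Angstrom).
#' @slot rmsd post-fit root-mean-square deviation (Angstrom).
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric"),
  validity = function(object) {
    R <- object@rotation
    if (max(abs(t(R) %*% R - diag(3))) > 1e-8)
      return("rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-8)
      return("rotation must be proper (determinant +1)")
    if (object@rmsd < 0) return("rmsd must be >= 0")
    TRUE
  })

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd = %.4f A\n", object@rmsd))
})

.asXYZ <- function(x) {
  if (is(x, "CoordinateSet")) x@xyz else as.matrix(x)
}

.rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Kabsch superposition
#'
#' Optimal least-squares rigid fit of `mobile` onto `reference` using the
#' SVD formulation, with the determinant correction that forbids
#' reflections (so a chiral set fitted onto its mirror image retains a
#' positive RMSD).
#'
#' @param mobile,reference [CoordinateSet-class] objects or n x 3 matrices
#'   of equal length (n >= 3, not all collinear).
#' @return a [SuperpositionResult-class].
#' @export
kabschSuperpose <- function(mobile, reference) {
  X <- .asXYZ(mobile); Y <- .asXYZ(reference)
  if (nrow(X) != nrow(Y)) stop("coordinate sets differ in length")
  if (nrow(X) < 3) stop("need at least 3 points to superpose")
  xc <- colMeans(X); yc <- colMeans(Y)
  X0 <- sweep(X, 2, xc); Y0 <- sweep(Y, 2, yc)
  s <- svd(t(X0) %*% Y0)
  dsign <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, dsign))
  R <- s$v %*% D %*% t(s$u)
  t <- as.numeric(yc - R %*% xc)
  fitted <- X %*% t(R) + matrix(t, nrow(X), 3, byrow = TRUE)
  new("SuperpositionResult", rotation = R, translation = t,
      rmsd = .rmsd(fitted, Y))
}

#' Apply a superposition transform
#'
#' @param x a [CoordinateSet-class] or n x 3 matrix.
#' @param fit a [SuperpositionResult-class].
#' @return object of the same kind with transformed coordinates.
#' @export
applySuperposition <- function(x, fit) {
  xyz <- .asXYZ(x)
  out <- xyz %*% t(fit@rotation) +
    matrix(fit@translation, nrow(xyz), 3, byrow = TRUE)
  if (is(x, "CoordinateSet")) {
    x@xyz <- out
    x
  } else out
}

## superpose structure b onto a over paired core atoms; returns the fit
.coreFit <- function(a, b, core) {
  ca <- selectAtoms(a, core)
  cb <- selectAtoms(b, core)
  pr <- pairCommonAtoms(ca, cb)
  kabschSuperpose(pr$b, pr$a)
}

#' Region RMSD after core alignment
#'
#' Superposes `b` onto `a` using the paired atoms of the `core` ranges,
#' then reports the RMSD over the paired atoms of the `region` range
#' *without further fitting*.  This is the quantity that separates a
#' repositioned helix from a merely re-oriented whole structure.
#'
#' @param a,b [PDBStructure-class] objects (same residue numbering).
#' @param core [ResidueRange-class] or list of ranges used for the fit;
#'   must not overlap `region`.
#' @param region [ResidueRange-class] scored after the fit.
#' @return RMSD in Angstrom.
#' @export
regionRMSD <- function(a, b, core, region) {
  fit <- .coreFit(a, b, core)
  ra <- selectAtoms(a, region)
  rb <- selectAtoms(b, region)
  pr <- pairCommonAtoms(ra, rb)
  .rmsd(applySuperposition(coords(pr$b), fit), coords(pr$a))
}

#' Helix reference frame
#'
#' @slot axis unit vector along the helix, oriented from the N-terminal
#'   towards the C-terminal end.
#' @slot centroid helix centre of geometry (Angstrom).
#' @export
setClass("HelixFrame",
  representation(axis = "numeric", centroid = "numeric"),
  validity = function(object) {
    if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
      return("axis must be a unit vector")
    TRUE
  })

setMethod("show", "HelixFrame", function(object) {
  cat(sprintf("HelixFrame: axis (%.3f, %.3f, %.3f)\n",
              object@axis[1], object@axis[2], object@axis[3]))
})

#' Helix axis from C-alpha coordinates
#'
#' The axis is the first principal direction of the centred C-alpha
#' cloud, oriented so that the projection of (last - first) C-alpha onto
#' it is positive (N- to C-terminal).
#'
#' @param helixCA a [CoordinateSet-class] or matrix of >= 4 C-alpha
#'   positions in sequence order.
#' @return a [HelixFrame-class].
#' @export
helixFrame <- function(helixCA) {
  X <- .asXYZ(helixCA)
  if (nrow(X) < 4) stop("need at least 4 C-alpha positions")
  ctr <- colMeans(X)
  X0 <- sweep(X, 2, ctr)
  ax <- svd(X0)$v[, 1]
  if (sum((X[nrow(X), ] - X[1, ]) * ax) < 0) ax <- -ax
  new("HelixFrame", axis = as.numeric(ax), centroid = ctr)
}

#' Helix displacement angle between two conformers
#'
#' Superposes `b` onto `a` over the `core` ranges, computes the helix axis
#' of the `helix` range in each structure (with `b`'s axis rotated by the
#' core fit) and returns the angle between the two axes in degrees,
#' in `[0, 180]`.
#'
#' @param a,b [PDBStructure-class] objects.
#' @param core fit ranges (see [regionRMSD()]).
#' @param helix [ResidueRange-class] of the helix; its C-alpha atoms are
#'   used regardless of the range's `atomFilter`.
#' @return angle in degrees.
#' @export
helixDisplacementAngle <- function(a, b, core, helix) {
  fit <- .coreFit(a, b, core)
  hx <- residueRange(helix@chain, helix@start, helix@end, "CA")
  fa <- helixFrame(selectAtoms(a, hx))
  hb <- helix
  hb@atomFilter <- "CA"
  fb <- helixFrame(selectAtoms(b, hb))
  axB <- as.numeric(fit@rotation %*% fb@axis)
  cosang <- max(-1, min(1, sum(fa@axis * axB)))
  acos(cosang) * 180 / pi
}

#' Charge-clamp distance
#'
#' Distance between the lysine side-chain nitrogen (NZ) and the midpoint
#' of the glutamate carboxylate oxygens (OE1/OE2); the midpoint makes the
#' metric robust to OE1/OE2 naming swaps.
#'
#' @param s a [PDBStructure-class].
#' @param lysRes,gluRes residue numbers of the clamp lysine and glutamate.
#' @param chain chain id.
#' @return distance in Angstrom.
#' @export
chargeClampDistance <- function(s, lysRes, gluRes, chain = "A") {
  a <- s@atoms
  nz <- a[a$chain_id == chain & a$res_seq == lysRes & a$name == "NZ", ,
          drop = FALSE]
  oe <- a[a$chain_id == chain & a$res_seq == gluRes &
            a$name %in% c("OE1", "OE2"), , drop = FALSE]
  if (nrow(nz) != 1)
    stop("residue ", lysRes, " has no NZ atom (missing lysine side chain)")
  if (nrow(oe) != 2)
    stop("residue ", gluRes, " lacks OE1/OE2 atoms ",
         "(missing glutamate carboxylate)")
  mid <- colMeans(as.matrix(oe[, c("x", "y", "z")]))
  sqrt(sum((as.numeric(nz[, c("x", "y", "z")]) - mid)^2))
}

.heavyAtoms <- function(s, range) {
  r <- range
  r@atomFilter <- "heavy"
  a <- s@atoms[s@atoms$chain_id == r@chain &
                 s@atoms$res_seq >= r@start & s@atoms$res_seq <= r@end &
                 s@atoms$i_code == "", , drop = FALSE]
  a
}

#' Residue contact map between two regions
#'
#' Reports every residue pair (one residue from each range) whose minimal
#' heavy-atom distance is at most `cutoff`, sorted by distance.  The
#' result is symmetric in the two ranges; self-pairs are excluded.
#'
#' @param s a [PDBStructure-class].
#' @param rangeA,rangeB [ResidueRange-class] objects.
#' @param cutoff heavy-atom distance cutoff (Angstrom); the default
#'   4.5 is the common hydrophobic-contact convention.
#' @return data.frame with columns `res_a`, `name_a`, `res_b`, `name_b`,
#'   `distance`.
#' @export
contactMap <- function(s, rangeA, rangeB, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  aa <- .heavyAtoms(s, rangeA)
  ab <- .heavyAtoms(s, rangeB)
  if (!nrow(aa) || !nrow(ab)) stop("empty selection for contact map")
  dx <- outer(aa$x, ab$x, "-")
  dy <- outer(aa$y, ab$y, "-")
  dz <- outer(aa$z, ab$z, "-")
  dmat <- sqrt(dx^2 + dy^2 + dz^2)
  keyA <- paste(aa$chain_id, aa$res_seq)
  keyB <- paste(ab$chain_id, ab$res_seq)
  pairs <- expand.grid(ia = seq_len(nrow(aa)), ib = seq_len(nrow(ab)))
  pk <- paste(keyA[pairs$ia], keyB[pairs$ib], sep = "|")
  dmin <- tapply(as.vector(dmat), pk, min)
  out <- do.call(rbind, lapply(names(dmin), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    ra <- strsplit(p[1], " ")[[1]]; rb <- strsplit(p[2], " ")[[1]]
    data.frame(chain_a = ra[1], res_a = as.integer(ra[2]),
               chain_b = rb[1], res_b = as.integer(rb[2]),
               distance = as.numeric(dmin[[k]]),
               stringsAsFactors = FALSE)
  }))
  ## drop self pairs, attach residue names, apply cutoff
  out <- out[!(out$chain_a == out$chain_b & out$res_a == out$res_b), ,
             drop = FALSE]
  out <- out[out$distance <= cutoff, , drop = FALSE]
  rname <- function(ch, rs) {
    vapply(seq_along(ch), function(i) {
      s@atoms$res_name[s@atoms$chain_id == ch[i] &
                         s@atoms$res_seq == rs[i]][1]
    }, character(1))
  }
  if (nrow(out)) {
    out$name_a <- rname(out$chain_a, out$res_a)
    out$name_b <- rname(out$chain_b, out$res_b)
    out <- out[order(out$distance), c("chain_a", "res_a", "name_a",
                                      "chain_b", "res_b", "name_b",
                                      "distance")]
  } else {
    out <- data.frame(chain_a = character(0), res_a = integer(0),
                      name_a = character(0), chain_b = character(0),
                      res_b = integer(0), name_b = character(0),
                      distance = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Default donor/acceptor role table
#'
#' Heavy-atom hydrogen-bond roles for standard side chains, the backbone,
#' and the estradiol ligand (EST: phenolic O3 and 17-beta hydroxyl O17).
#'
#' @return data.frame with columns `res_name` (`"*"` matches any),
#'   `atom`, `role` (`donor`, `acceptor` or `both`).
#' @export
hbondRoles <- function() {
  rbind(
    data.frame(res_name = "*", atom = "N", role = "donor"),
    data.frame(res_name = "*", atom = "O", role = "acceptor"),
    data.frame(res_name = "LYS", atom = "NZ", role = "donor"),
    data.frame(res_name = "ARG", atom = c("NE", "NH1", "NH2"),
               role = "donor"),
    data.frame(res_name = "HIS", atom = c("ND1", "NE2"), role = "both"),
    data.frame(res_name = "TRP", atom = "NE1", role = "donor"),
    data.frame(res_name = "ASN", atom = "ND2", role = "donor"),
    data.frame(res_name = "ASN", atom = "OD1", role = "acceptor"),
    data.frame(res_name = "GLN", atom = "NE2", role = "donor"),
    data.frame(res_name = "GLN", atom = "OE1", role = "acceptor"),
    data.frame(res_name = "SER", atom = "OG", role = "both"),
    data.frame(res_name = "THR", atom = "OG1", role = "both"),
    data.frame(res_name = "TYR", atom = "OH", role = "both"),
    data.frame(res_name = "ASP", atom = c("OD1", "OD2"), role = "acceptor"),
    data.frame(res_name = "GLU", atom = c("OE1", "OE2"), role = "acceptor"),
    data.frame(res_name = "EST", atom = c("O3", "O17"), role = "both"))
}

#' Geometric hydrogen bonds
#'
#' Distance-only criterion on heavy atoms: donor--acceptor pairs closer
#' than `dCut` (default 3.5 Angstrom).  Crystal structures carry no
#' hydrogens, so no angular term is applied.  Pairs within the same
#' residue are excluded.
#'
#' @param s a [PDBStructure-class].
#' @param roles role table as from [hbondRoles()].
#' @param dCut donor--acceptor distance cutoff (Angstrom).
#' @return data.frame of bonds sorted by distance, with donor and
#'   acceptor chain/residue/atom columns.
#' @export
hydrogenBonds <- function(s, roles = hbondRoles(), dCut = 3.5) {
  stopifnot(dCut > 0, nrow(roles) > 0)
  a <- s@atoms
  roleOf <- function(res, atom) {
    hit <- roles[(roles$res_name == res | roles$res_name == "*") &
                   roles$atom == atom, "role"]
    if (!length(hit)) return(NA_character_)
    if (any(hit == "both") || all(c("donor", "acceptor") %in% hit))
      "both" else hit[1]
  }
  role <- mapply(roleOf, a$res_name, a$name)
  don <- which(role %in% c("donor", "both"))
  acc <- which(role %in% c("acceptor", "both"))
  if (!length(don) || !length(acc))
    return(data.frame())
  xyz <- as.matrix(a[, c("x", "y", "z")])
  out <- list()
  for (i in don) {
    d2 <- colSums((t(xyz[acc, , drop = FALSE]) - xyz[i, ])^2)
    hit <- acc[d2 <= dCut^2]
    hit <- hit[!(a$chain_id[hit] == a$chain_id[i] &
                   a$res_seq[hit] == a$res_seq[i])]
    for (j in hit) {
      out[[length(out) + 1L]] <- data.frame(
        donor_chain = a$chain_id[i], donor_res = a$res_seq[i],
        donor_name = a$res_name[i], donor_atom = a$name[i],
        acceptor_chain = a$chain_id[j], acceptor_res = a$res_seq[j],
        acceptor_name = a$res_name[j], acceptor_atom = a$name[j],
        distance = sqrt(d2[[match(j, acc)]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  ## a donor-acceptor pair where both atoms are "both" would appear twice;
  ## keep the lexicographically first orientation
  key <- apply(res, 1, function(r) {
    paste(sort(c(paste(r[1:4], collapse = ":"),
                 paste(r[5:8], collapse = ":"))), collapse = "|")
  })
  res <- res[!duplicated(key), , drop = FALSE]
  res <- res[order(res$distance), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Project a structure onto RMSD reaction coordinates
#'
#' Returns the coordinates of `s` on the two-dimensional landscape axes
#' (RMSD_C, RMSD_A): the C-alpha RMSD of the collective-variable region
#' against the canonical and the alternative reference, each computed
#' after superposing on the core (the chain's modeled residues outside
#' `cvRegion`).
#'
#' @param s structure to project.
#' @param refC,refA canonical and alternative reference
#'   [PDBStructure-class] objects.
#' @param cvRegion [ResidueRange-class] of the collective-variable
#'   residues (C-alpha atoms are always used).
#' @return named numeric vector `c(rmsd_c, rmsd_a)`.
#' @export
projectStructure <- function(s, refC, refA, cvRegion) {
  cv <- residueRange(cvRegion@chain, cvRegion@start, cvRegion@end, "CA")
  coreOf <- function(st) {
    res <- modeledResidues(st, cv@chain)
    res <- res[res < cv@start | res > cv@end]
    if (!length(res)) stop("no core residues outside the CV region")
    ## contiguous runs -> ranges
    br <- c(0, which(diff(res) > 1), length(res))
    lapply(seq_len(length(br) - 1), function(i) {
      residueRange(cv@chain, res[br[i] + 1], res[br[i + 1]], "CA")
    })
  }
  one <- function(ref) {
    fit <- .coreFit(ref, s, coreOf(ref))   # fit s onto ref over shared core
    pr <- pairCommonAtoms(selectAtoms(ref, cv), selectAtoms(s, cv))
    .rmsd(applySuperposition(coords(pr$b), fit), coords(pr$a))
  }
  c(rmsd_c = one(refC), rmsd_a = one(refA))
}

#' RMSD distribution against the trajectory average structure
#'
#' Iterative fit-average: every frame is superposed onto the running mean
#' structure, the mean is recomputed, and the cycle repeats until the mean
#' moves less than `tol` (max 100 iterations).  Per-frame RMSDs against
#' the converged average are histogrammed.
#'
#' @param frames list of [CoordinateSet-class] objects or n x 3 matrices
#'   of identical dimension (>= 2 frames).
#' @param nBins number of histogram bins.
#' @param tol convergence tolerance on the average structure (Angstrom).
#' @return list with `rmsd` (per frame), `average` (matrix), `mids` and
#'   `counts` (histogram), `iterations`.
#' @export
rmsdDistribution <- function(frames, nBins = 30, tol = 1e-6) {
  mats <- lapply(frames, .asXYZ)
  if (length(mats) < 2) stop("need at least 2 frames")
  n <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, integer(1)) != n))
    stop("frames differ in atom count")
  avg <- mats[[1]]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fitted <- lapply(mats, function(m)
      applySuperposition(m, kabschSuperpose(m, avg)))
    newAvg <- Reduce(`+`, fitted) / length(fitted)
    shift <- max(abs(newAvg - avg))
    avg <- newAvg
    if (shift < tol || iter >= 100L) break
  }
  rmsds <- vapply(fitted, function(m) .rmsd(m, avg), numeric(1))
  h <- hist(rmsds, breaks = nBins, plot = FALSE)
  list(rmsd = rmsds, average = avg, mids = h$mids, counts = h$counts,
       breaks = h$breaks, iterations = iter)
}

#' Aggregate conformer comparison report
#'
#' Bundles the pairwise metrics between an alternative and a reference
#' conformer: core-aligned region RMSD, helix displacement angle, the
#' charge-clamp distance of the first structure (if clamp residues are
#' given), helix contacts and hydrogen bonds.
#'
#' @slot regionRmsd Angstrom.
#' @slot displacementAngle degrees in `[0, 180]`.
#' @slot chargeClamp Angstrom, or `NA`.
#' @slot contacts contact data.frame (see [contactMap()]).
#' @slot hbonds hydrogen-bond data.frame (see [hydrogenBonds()]).
#' @export
setClass("ConformerReport",
  representation(regionRmsd = "numeric", displacementAngle = "numeric",
                 chargeClamp = "numeric", contacts = "data.frame",
                 hbonds = "data.frame"),
  validity = function(object) {
    if (!is.na(object@displacementAngle) &&
        (object@displacementAngle < 0 || object@displacementAngle > 180))
      return("displacementAngle must lie in [0, 180]")
    ok <- c(object@regionRmsd, object@chargeClamp,
            object@contacts$distance, object@hbonds$distance)
    if (any(ok[!is.na(ok)] < 0)) return("distances must be >= 0")
    TRUE
  })

setMethod("show", "ConformerReport", function(object) {
  cat("ConformerReport\n")
  cat(sprintf("  region RMSD:        %.2f A\n", object@regionRmsd))
  cat(sprintf("  displacement angle: %.1f deg\n", object@displacementAngle))
  if (!is.na(object@chargeClamp))
    cat(sprintf("  charge clamp:       %.2f A\n", object@chargeClamp))
  cat(sprintf("  contacts: %d, hydrogen bonds: %d\n",
              nrow(object@contacts), nrow(object@hbonds)))
})

#' @rdname ConformerReport-class
#' @param alt,ref structures to compare (`alt` provides contacts, bonds
#'   and the clamp).
#' @param core,region,helix ranges, see [regionRMSD()] and
#'   [helixDisplacementAngle()].
#' @param contactRange optional second range for [contactMap()] (defaults
#'   to the core).
#' @param clampLys,clampGlu optional clamp residue numbers.
#' @param chain chain for the clamp.
#' @param cutoff,dCut contact and hydrogen-bond cutoffs.
#' @export
conformerReport <- function(alt, ref, core, region, helix,
                            contactRange = NULL, clampLys = NULL,
                            clampGlu = NULL, chain = "A", cutoff = 4.5,
                            dCut = 3.5) {
  clamp <- if (!is.null(clampLys) && !is.null(clampGlu))
    chargeClampDistance(alt, clampLys, clampGlu, chain) else NA_real_
  if (is.null(contactRange)) contactRange <- core
  cts <- tryCatch(contactMap(alt, region,
                             if (is.list(contactRange)) contactRange[[1]]
                             else contactRange, cutoff),
                  error = function(e) data.frame())
  new("ConformerReport",
      regionRmsd = regionRMSD(alt, ref, core, region),
      displacementAngle = helixDisplacementAngle(alt, ref, core, helix),
      chargeClamp = clamp,
      contacts = cts,
      hbonds = hydrogenBonds(alt, dCut = dCut))
}

#' Write a conformer report as JSON (+ optional contact TSV)
#'
#' @param report a [ConformerReport-class].
#' @param file JSON output path.
#' @param contactsFile optional TSV path for the contact table.
#' @export
writeConformerReport <- function(report, file, contactsFile = NULL) {
  out <- list(region_rmsd = report@regionRmsd,
              displacement_angle = report@displacementAngle,
              charge_clamp_distance = if (is.na(report@chargeClamp)) NULL
                else report@chargeClamp,
              contacts = report@contacts,
              hydrogen_bonds = report@hbonds)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(contactsFile))
    write.table(report@contacts, contactsFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(file)
}

#' Conformer metrics on the deposited crystal structures
#'
#' Computes the benchmark metric set between the alternative ERbeta
#' LBD-estradiol structure (5TOA) and the canonical agonist (3OLS or
#' 3OLL) and antagonist-like (1QKM) references, when those PDB files are
#' available locally: region RMSD of the H12 backbone (residues 489-497)
#' after fitting the LBD core (C-alpha outside residues 469-501), and the
#' H12 displacement angles.  Files are looked up as `<id>.pdb` (lower or
#' upper case) under `dir`.
#'
#' @param dir directory holding the PDB files.
#' @param chain chain used from each entry.
#' @param caOnly score the region RMSD on C-alpha atoms instead of the
#'   full backbone.
#' @return data.frame with one row per comparison (`metric`, `value`).
#' @export
crystalBenchmark <- function(dir, chain = "A", caOnly = FALSE) {
  find <- function(id) {
    for (f in file.path(dir, paste0(c(tolower(id), toupper(id)), ".pdb")))
      if (file.exists(f)) return(f)
    stop("PDB entry ", id, " not found under ", dir)
  }
  alt <- readPDB(find("5toa"))
  can <- tryCatch(readPDB(find("3ols")), error = function(e)
    readPDB(find("3oll")))
  ant <- readPDB(find("1qkm"))
  filt <- if (caOnly) "CA" else "backbone"
  coreOf <- function(s) {
    res <- modeledResidues(s, chain)
    res <- res[res < 469 | res > 501]
    br <- c(0, which(diff(res) > 1), length(res))
    lapply(seq_len(length(br) - 1), function(i)
      residueRange(chain, res[br[i] + 1], res[br[i + 1]], "CA"))
  }
  region <- residueRange(chain, 489, 497, filt)
  helix <- residueRange(chain, 489, 500, "CA")
  rr <- function(a, b) regionRMSD(a, b, coreOf(a), region)
  ang <- function(a, b) helixDisplacementAngle(a, b, coreOf(a), helix)
  data.frame(
    metric = c("rmsd_alt_vs_canonical", "rmsd_alt_vs_antagonist",
               "rmsd_canonical_vs_antagonist", "angle_alt_vs_canonical",
               "angle_alt_vs_antagonist"),
    value = c(rr(alt, can), rr(alt, ant), rr(can, ant),
              ang(alt, can), ang(alt, ant)),
    stringsAsFactors = FALSE)
}
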