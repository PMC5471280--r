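## abf: adaptive-biasing-force estimator -- binned accumulation of the
## instantaneous collective-variable force, ramped bias application, and
## harmonic boundary restraints.

#' ABF parameters
#'
#' Defaults follow common practice for RMSD-coordinate landscape
#' calculations: square bins of 0.1 Angstrom per axis over a 1--10 Angstrom
#' domain, full bias application after 4000 samples in a bin, and boundary
#' restraints of 10 kcal/mol/Angstrom^2 outside the domain.
#'
#' @slot binWidth per-axis bin width (Angstrom).
#' @slot domain d x 2 matrix of per-axis domain limits (Angstrom).
#' @slot nFull minimum per-bin sample count before the accumulated mean
#'   force is applied in full; below it the bias is ramped linearly.
#' @slot boundaryK harmonic boundary force constant (kcal/mol/Angstrom^2).
#' @export
setClass("ABFParams",
  representation(binWidth = "numeric", domain = "matrix", nFull = "integer",
                 boundaryK = "numeric"),
  validity = function(object) {
    if (any(object@binWidth <= 0)) return("binWidth must be > 0")
    if (object@nFull < 1) return("nFull must be >= 1")
    if (object@boundaryK < 0) return("boundaryK must be >= 0")
    if (ncol(object@domain) != 2) return("domain must be a d x 2 matrix")
    if (any(object@domain[, 1] >= object@domain[, 2]))
      return("domain min must be < max per axis")
    if (!length(object@binWidth) %in% c(1L, nrow(object@domain)))
      return("binWidth must be scalar or one per axis")
    TRUE
  })

#' @rdname ABFParams-class
#' @param binWidth,domain,nFull,boundaryK see slots.
#' @export
abfParams <- function(binWidth = 0.1, domain = rbind(c(1, 10), c(1, 10)),
                      nFull = 4000L, boundaryK = 10) {
  new("ABFParams", binWidth = binWidth, domain = as.matrix(domain),
      nFull = as.integer(nFull), boundaryK = boundaryK)
}

setMethod("show", "ABFParams", function(object) {
  d <- nrow(object@domain)
  cat(sprintf("ABFParams (%dD): width %s A, nFull %d, boundary k %g\n",
              d, paste(rep(object@binWidth, length.out = d), collapse = "x"),
              object@nFull, object@boundaryK))
  for (i in seq_len(d))
    cat(sprintf("  axis %d: [%g, %g]\n", i, object@domain[i, 1],
                object@domain[i, 2]))
})

.gridAxes <- function(params) {
  d <- nrow(params@domain)
  w <- rep(params@binWidth, length.out = d)
  lapply(seq_len(d), function(i) {
    lo <- params@domain[i, 1]; hi <- params@domain[i, 2]
    ## nudge before ceiling so an exact multiple of the width does not
    ## gain a spurious extra bin from representation error
    n <- as.integer(ceiling((hi - lo) / w[i] - 1e-9))
    list(min = lo, max = hi, width = w[i], n = n)
  })
}

#' Binned force accumulator
#'
#' The raw ABF state: per-bin sample counts and accumulated sums of the
#' instantaneous collective-variable force.  The mean force of a bin is its
#' force sum divided by its count; bins with zero samples have no mean
#' force (they are masked, never zero-filled).
#'
#' @slot axes list of per-axis descriptors `list(min, max, width, n)`.
#' @slot counts integer array of per-bin sample counts (dim = bins per
#'   axis).
#' @slot forceSums numeric matrix, bins x d, of accumulated forces in
#'   column-major bin order.
#' @export
setClass("BinGrid",
  representation(axes = "list", counts = "array", forceSums = "matrix"),
  validity = function(object) {
    nb <- vapply(object@axes, function(a) a$n, integer(1))
    if (prod(nb) != length(object@counts)) return("counts size mismatch")
    if (nrow(object@forceSums) != prod(nb) ||
        ncol(object@forceSums) != length(nb))
      return("forceSums must be (total bins) x d")
    if (any(object@counts < 0)) return("counts must be non-negative")
    if (any(!is.finite(object@forceSums))) return("force sums must be finite")
    TRUE
  })

#' @rdname BinGrid-class
#' @param params an [ABFParams-class] describing the axes.
#' @return an empty `BinGrid`.
#' @export
binGrid <- function(params = abfParams()) {
  axes <- .gridAxes(params)
  nb <- vapply(axes, function(a) a$n, integer(1))
  new("BinGrid", axes = axes,
      counts = array(0L, dim = nb),
      forceSums = matrix(0, nrow = prod(nb), ncol = length(nb)))
}

setMethod("show", "BinGrid", function(object) {
  nb <- vapply(object@axes, function(a) a$n, integer(1))
  cat(sprintf("BinGrid %s: %d samples in %d/%d bins\n",
              paste(nb, collapse = " x "), sum(object@counts),
              sum(object@counts > 0), prod(nb)))
})

#' @rdname BinGrid-class
#' @param g a `BinGrid`.
#' @export
binCounts <- function(g) g@counts

#' @rdname BinGrid-class
#' @export
binForceSums <- function(g) g@forceSums

#' @rdname BinGrid-class
#' @export
gridAxes <- function(g) g@axes

#' Per-axis bin-centre coordinates
#' @param g a [BinGrid-class] or [FreeEnergyLandscape-class].
#' @return list of numeric vectors, one per axis.
#' @export
binCenters <- function(g) {
  lapply(g@axes, function(a) a$min + (seq_len(a$n) - 0.5) * a$width)
}

#' Mean-force field of a grid
#'
#' @param g a [BinGrid-class].
#' @return bins x d matrix of per-bin mean forces; rows for empty bins are
#'   `NA` (an empty bin has no mean force).
#' @export
meanForce <- function(g) {
  n <- as.vector(g@counts)
  mf <- g@forceSums / n
  mf[n == 0L, ] <- NA_real_
  mf
}

#' Locate the bin containing a point
#'
#' Half-open binning: bin `i` covers `[edge_i, edge_{i+1})`.
#'
#' @param g a [BinGrid-class].
#' @param x numeric point.
#' @return integer vector of per-axis bin indices (1-based), or `NA` if the
#'   point lies outside the domain on any axis.
#' @export
locateBin <- function(g, x) {
  x <- as.numeric(x)
  stopifnot(length(x) == length(g@axes))
  idx <- integer(length(x))
  for (i in seq_along(x)) {
    a <- g@axes[[i]]
    z <- floor((x[i] - a$min) / a$width + 1e-9)
    if (z < 0 || z >= a$n) return(NA_integer_)
    idx[i] <- as.integer(z) + 1L
  }
  idx
}

.linearIndex <- function(g, idx) {
  nb <- vapply(g@axes, function(a) a$n, integer(1))
  if (length(nb) == 1L) idx[1] else idx[1] + nb[1] * (idx[2] - 1L)
}

#' Accrue one instantaneous force sample
#'
#' @param g a [BinGrid-class].
#' @param x sampling position.
#' @param f instantaneous collective-variable force (finite).
#' @return the updated grid; unchanged if `x` lies outside the domain.
#' @export
accrue <- function(g, x, f) {
  f <- as.numeric(f)
  if (any(!is.finite(f))) stop("non-finite force sample")
  idx <- locateBin(g, x)
  if (anyNA(idx)) return(g)
  li <- .linearIndex(g, idx)
  g@counts[li] <- g@counts[li] + 1L
  g@forceSums[li, ] <- g@forceSums[li, ] + f
  g
}

#' Ramped ABF bias force at a point
#'
#' Returns `-ramp(n) * (running mean force)` of the point's bin, with
#' `ramp(n) = min(1, n / nFull)`; zero for empty bins and outside the
#' domain (the boundary restraint is handled separately by
#' [boundaryForce()]).
#'
#' @param g a [BinGrid-class].
#' @param x position.
#' @param params an [ABFParams-class] (supplies `nFull`).
#' @export
biasForce <- function(g, x, params) {
  d <- length(g@axes)
  idx <- locateBin(g, x)
  if (anyNA(idx)) return(numeric(d))
  li <- .linearIndex(g, idx)
  n <- g@counts[li]
  if (n == 0L) return(numeric(d))
  -min(1, n / params@nFull) * g@forceSums[li, ] / n
}

#' Harmonic boundary restraint force
#'
#' Zero inside the domain; beyond an edge the restoring force is
#' `-k * (x - edge)` per axis (the potential is `k/2 * excess^2`).
#'
#' @param x position.
#' @param params an [ABFParams-class].
#' @export
boundaryForce <- function(x, params) {
  x <- as.numeric(x)
  lo <- params@domain[, 1]; hi <- params@domain[, 2]
  f <- numeric(length(x))
  over <- x > hi
  under <- x < lo
  f[over] <- -params@boundaryK * (x[over] - hi[over])
  f[under] <- -params@boundaryK * (x[under] - lo[under])
  f
}

#' Run one ABF simulation on an analytic potential
#'
#' At every step the instantaneous systematic force \eqn{-\nabla U} is
#' recorded into the bin grid, then overdamped Langevin dynamics advances
#' under the external force `biasForce + boundaryForce` (the bias uses the
#' bin's running mean including the current sample).  Deterministic given
#' `lp@seed`.
#'
#' @param p an [AnalyticPotential-class] with `dim` matching the ABF domain.
#' @param params an [ABFParams-class].
#' @param lp a [LangevinParams-class].
#' @param nSteps number of steps (>= 1).
#' @param bias apply the adaptive bias (`TRUE`) or only accumulate
#'   (`FALSE`, useful for unbiased mean-force estimates).
#' @param record keep the full trajectory (positions and systematic
#'   forces).
#' @return list with components `grid` ([BinGrid-class]) and `trajectory`
#'   ([Trajectory-class], `NULL` unless `record`).
#' @export
runABF <- function(p, params = abfParams(), lp = langevinParams(),
                   nSteps, bias = TRUE, record = FALSE) {
  stopifnot(is(p, "AnalyticPotential"), is(params, "ABFParams"),
            is(lp, "LangevinParams"), nSteps >= 1)
  if (nrow(params@domain) != p@dim)
    stop("ABF domain dimensionality does not match the potential")
  g <- binGrid(params)
  x0 <- lp@initialPosition
  if (length(x0) != p@dim) stop("initialPosition must have length ", p@dim)
  nb <- vapply(g@axes, function(a) a$n, integer(1))
  set.seed(lp@seed)
  res <- run_dynamics_cpp(
    spec = p@cppSpec, grad_fun = p@gradient, x0 = as.numeric(x0),
    n_steps = as.integer(nSteps), dt = lp@timestep, gamma = lp@friction,
    kT = .kB * lp@temperature,
    abf = list(enabled = TRUE, bias = bias, n_bins = as.integer(nb),
               lo = vapply(g@axes, function(a) a$min, numeric(1)),
               width = vapply(g@axes, function(a) a$width, numeric(1)),
               n_full = params@nFull, boundary_k = params@boundaryK,
               dom_lo = params@domain[, 1], dom_hi = params@domain[, 2],
               counts = as.vector(g@counts), force_sums = g@forceSums),
    record = record)
  g@counts <- array(res$counts, dim = nb)
  g@forceSums <- res$force_sums
  traj <- NULL
  if (record)
    traj <- new("Trajectory", positions = res$positions,
                forces = res$forces)
  list(grid = g, trajectory = traj)
}

#' Serialize a bin grid to TSV
#'
#' Axis specifications go into `#axis` header lines; each data row holds
#' the per-axis bin indices, the count, and the force sums printed with
#' full precision (`%.17g`), so a write/read round trip is bit-exact.
#'
#' @param g a [BinGrid-class].
#' @param file output path.
#' @export
writeBinGrid <- function(g, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(g@axes)) {
    a <- g@axes[[i]]
    writeLines(sprintf("#axis\t%d\t%.17g\t%.17g\t%.17g\t%d",
                       i, a$min, a$max, a$width, a$n), con)
  }
  d <- length(g@axes)
  nb <- vapply(g@axes, function(a) a$n, integer(1))
  writeLines(paste(c(paste0("bin", seq_len(d)), "count",
                     paste0("fsum", seq_len(d))), collapse = "\t"), con)
  nz <- which(as.vector(g@counts) > 0L)
  for (li in nz) {
    if (d == 1L) idx <- li
    else idx <- c((li - 1L) %% nb[1] + 1L, (li - 1L) %/% nb[1] + 1L)
    writeLines(paste(c(idx, g@counts[li],
                       sprintf("%.17g", g@forceSums[li, ])),
                     collapse = "\t"), con)
  }
  invisible(file)
}

#' Read a bin grid written by [writeBinGrid()]
#'
#' @param file path to a grid TSV.
#' @return a [BinGrid-class].
#' @export
readBinGrid <- function(file) {
  lines <- readLines(file)
  ax <- grep("^#axis\t", lines, value = TRUE)
  if (!length(ax)) stop("not a bin-grid file: no #axis header")
  axes <- lapply(ax, function(l) {
    p <- strsplit(l, "\t", fixed = TRUE)[[1]]
    list(min = as.numeric(p[3]), max = as.numeric(p[4]),
         width = as.numeric(p[5]), n = as.integer(p[6]))
  })
  d <- length(axes)
  nb <- vapply(axes, function(a) a$n, integer(1))
  g <- new("BinGrid", axes = axes, counts = array(0L, dim = nb),
           forceSums = matrix(0, prod(nb), d))
  body <- lines[!startsWith(lines, "#")][-1]
  for (l in body) {
    p <- strsplit(l, "\t", fixed = TRUE)[[1]]
    idx <- as.integer(p[seq_len(d)])
    li <- if (d == 1L) idx[1] else idx[1] + nb[1] * (idx[2] - 1L)
    g@counts[li] <- as.integer(p[d + 1L])
    g@forceSums[li, ] <- as.numeric(p[(d + 2L):(2L * d + 1L)])
  }
  g
}
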