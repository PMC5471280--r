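## toysystems: analytic potentials, overdamped Langevin sampling, and
## synthetic-structure builders used to emulate the statistical structure of
## biased molecular-dynamics data at desk scale.

#' Analytic potential energy surface
#'
#' An `AnalyticPotential` couples closed-form energy and gradient functions
#' on a 1D or 2D collective-variable (CV) space, in kcal/mol and Angstrom
#' units.  Potentials built by the package constructors additionally carry a
#' compiled-code specification (`cppSpec`) so that the Langevin/ABF inner
#' loop can evaluate them without calling back into R; user-supplied R
#' functions are supported through the callback path of [runLangevin()] and
#' [runABF()].
#'
#' @slot dim CV-space dimensionality, 1 or 2.
#' @slot energy `function(x)` returning energy (kcal/mol).
#' @slot gradient `function(x)` returning the gradient vector
#'   (kcal/mol/Angstrom).
#' @slot domain `dim x 2` matrix of declared axis limits (Angstrom).
#' @slot cppSpec list consumed by the compiled sampler, or empty list.
#' @slot name short identifier.
#' @export
setClass("AnalyticPotential",
  representation(dim = "integer", energy = "function", gradient = "function",
                 domain = "matrix", cppSpec = "list", name = "character"),
  validity = function(object) {
    if (!object@dim %in% c(1L, 2L)) return("dim must be 1 or 2")
    if (nrow(object@domain) != object@dim || ncol(object@domain) != 2)
      return("domain must be a dim x 2 matrix")
    if (any(object@domain[, 1] >= object@domain[, 2]))
      return("domain min must be < max on every axis")
    TRUE
  })

setMethod("show", "AnalyticPotential", function(object) {
  cat(sprintf("AnalyticPotential '%s' (%dD)\n", object@name, object@dim))
  for (i in seq_len(object@dim))
    cat(sprintf("  axis %d domain: [%g, %g]\n", i,
                object@domain[i, 1], object@domain[i, 2]))
})

#' Evaluate a potential
#'
#' @param p an [AnalyticPotential-class].
#' @param x numeric position of length `dim(p)`.
#' @return list with components `energy` (scalar, kcal/mol) and `gradient`
#'   (vector, kcal/mol/Angstrom).
#' @examples
#' evaluate(harmonicPotential(k = 2), 3)   # energy 9, gradient 6
#' @export
evaluate <- function(p, x) {
  stopifnot(is(p, "AnalyticPotential"))
  x <- as.numeric(x)
  if (length(x) != p@dim)
    stop("position has length ", length(x), ", potential is ", p@dim, "D")
  if (any(x < p@domain[, 1]) || any(x > p@domain[, 2]))
    stop("position (", paste(signif(x, 6), collapse = ", "),
         ") outside declared domain")
  list(energy = p@energy(x), gradient = p@gradient(x))
}

#' Dimensionality of a potential
#' @param p an [AnalyticPotential-class].
#' @export
potentialDim <- function(p) p@dim

#' Harmonic potential
#'
#' \eqn{U(x) = k |x|^2 / 2} centred at the origin.
#'
#' @param k force constant, kcal/mol/Angstrom^2.
#' @param dim dimensionality (1 or 2).
#' @param halfwidth declared domain half-width per axis (Angstrom).
#' @export
harmonicPotential <- function(k, dim = 1L, halfwidth = 50) {
  stopifnot(k > 0)
  dim <- as.integer(dim)
  new("AnalyticPotential", dim = dim,
      energy = function(x) 0.5 * k * sum(x^2),
      gradient = function(x) k * as.numeric(x),
      domain = matrix(rep(c(-halfwidth, halfwidth), each = dim), ncol = 2),
      cppSpec = list(type = "harmonic", k = k, dim = dim),
      name = sprintf("harmonic(k=%g)", k))
}

## Piecewise C1 profile through alternating stationary points.
## `stations` is an n x 2 matrix (position, energy); consecutive points are
## joined by a scaled smoothstep (zero slope at both ends), so every listed
## position is an exact stationary point with the exact listed energy.
## Beyond the two end points the profile rises as wall * (t - t_end)^2.
.profileEnergy <- function(t, stations, wall) {
  n <- nrow(stations)
  if (t <= stations[1, 1]) return(stations[1, 2] + wall * (t - stations[1, 1])^2)
  if (t >= stations[n, 1]) return(stations[n, 2] + wall * (t - stations[n, 1])^2)
  k <- findInterval(t, stations[, 1], rightmost.closed = TRUE)
  t0 <- stations[k, 1]; u0 <- stations[k, 2]
  t1 <- stations[k + 1, 1]; u1 <- stations[k + 1, 2]
  z <- (t - t0) / (t1 - t0)
  u0 + (u1 - u0) * (3 * z^2 - 2 * z^3)
}

.profileGradient <- function(t, stations, wall) {
  n <- nrow(stations)
  if (t <= stations[1, 1]) return(2 * wall * (t - stations[1, 1]))
  if (t >= stations[n, 1]) return(2 * wall * (t - stations[n, 1]))
  k <- findInterval(t, stations[, 1], rightmost.closed = TRUE)
  t0 <- stations[k, 1]; u0 <- stations[k, 2]
  t1 <- stations[k + 1, 1]; u1 <- stations[k + 1, 2]
  z <- (t - t0) / (t1 - t0)
  (u1 - u0) * 6 * z * (1 - z) / (t1 - t0)
}

#' One-dimensional channel potential through stationary points
#'
#' Builds a piecewise-smoothstep profile whose listed positions are exact
#' stationary points with the exact listed energies (wells and saddles
#' alternate).  Outside the end wells the energy rises quadratically with
#' curvature `wall`.
#'
#' @param stations n x 2 matrix: column 1 positions (Angstrom, increasing),
#'   column 2 energies (kcal/mol).
#' @param wall confinement curvature beyond the end wells
#'   (kcal/mol/Angstrom^2).
#' @param domain declared 1 x 2 domain matrix; defaults to the stations
#'   extended by 5 Angstrom.
#' @export
channelPotential1D <- function(stations, wall = 25,
                               domain = NULL) {
  stations <- as.matrix(stations)
  stopifnot(ncol(stations) == 2, nrow(stations) >= 1,
            !is.unsorted(stations[, 1], strictly = TRUE))
  if (is.null(domain))
    domain <- matrix(c(stations[1, 1] - 5, stations[nrow(stations), 1] + 5), 1)
  new("AnalyticPotential", dim = 1L,
      energy = function(x) .profileEnergy(x[1], stations, wall),
      gradient = function(x) .profileGradient(x[1], stations, wall),
      domain = domain,
      cppSpec = list(type = "channel1d", stations = stations, wall = wall),
      name = "channel1d")
}

#' Symmetric-or-asymmetric 1D double well
#'
#' Wells at -1 and +1 Angstrom; the left well is the global minimum at
#' energy 0, the saddle at the origin has height `barrier`, and the right
#' well sits at energy `asymmetry` (its escape barrier is therefore
#' `barrier - asymmetry`).
#'
#' @param barrier saddle height above the global minimum (kcal/mol).
#' @param asymmetry energy of the right well above the global minimum
#'   (kcal/mol); 0 gives a symmetric well pair.
#' @param wall confinement curvature beyond the wells.
#' @export
doubleWell1D <- function(barrier, asymmetry = 0, wall = 25) {
  stopifnot(barrier > 0, asymmetry >= 0, asymmetry < barrier)
  p <- channelPotential1D(rbind(c(-1, 0), c(0, barrier), c(1, asymmetry)),
                          wall = wall, domain = matrix(c(-3, 3), 1))
  p@name <- sprintf("double_well_1d(barrier=%g, asymmetry=%g)",
                    barrier, asymmetry)
  p
}

## 2D channel machinery: the profile runs along the straight line from p0
## through p1; transverse displacement s is confined harmonically.
.channel2dFuns <- function(p0, p1, stations, wall, kperp) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  d <- sqrt(sum((p1 - p0)^2))
  u <- (p1 - p0) / d
  energy <- function(x) {
    r <- as.numeric(x) - p0
    t <- sum(r * u)
    sv <- r - t * u
    .profileEnergy(t, stations, wall) + 0.5 * kperp * sum(sv^2)
  }
  gradient <- function(x) {
    r <- as.numeric(x) - p0
    t <- sum(r * u)
    sv <- r - t * u
    .profileGradient(t, stations, wall) * u + kperp * sv
  }
  list(energy = energy, gradient = gradient, u = u, d = d)
}

#' Two-dimensional multi-basin channel potential
#'
#' The energy profile of [channelPotential1D()] is laid along the straight
#' line from `p0` through `p1` (arc-length coordinate `t`, with `t = 0` at
#' `p0`); motion transverse to the line is confined harmonically with
#' stiffness `kperp`.  Every station is an exact stationary point of the 2D
#' surface with the exact listed energy, which makes configured saddle
#' heights and basin depths hold by construction.
#'
#' @param p0,p1 channel end points (2-vectors, Angstrom).  Stations are
#'   positions along the `p0 -> p1` line measured from `p0`.
#' @param stations n x 2 matrix (arc position, energy).
#' @param kperp transverse confinement stiffness (kcal/mol/Angstrom^2).
#' @param wall longitudinal confinement beyond the end wells.
#' @param domain 2 x 2 domain matrix (default `[1, 10]` Angstrom per axis,
#'   matching the RMSD-coordinate range of the landscape calculations).
#' @export
channelPotential2D <- function(p0, p1, stations, kperp = 150, wall = 25,
                               domain = rbind(c(1, 10), c(1, 10))) {
  stations <- as.matrix(stations)
  stopifnot(length(p0) == 2, length(p1) == 2, ncol(stations) == 2)
  f <- .channel2dFuns(p0, p1, stations, wall, kperp)
  new("AnalyticPotential", dim = 2L,
      energy = f$energy, gradient = f$gradient, domain = domain,
      cppSpec = list(type = "channel2d", p0 = as.numeric(p0),
                     u = f$u, stations = stations, wall = wall,
                     kperp = kperp),
      name = "channel2d")
}

#' Two-state 2D potential
#'
#' Two basins of unequal depth separated by a single saddle placed midway
#' between them, realised as a [channelPotential2D()].  Depths are escape
#' barriers: the energy of minimum `i` is `saddleHeight - depths[i]`, and
#' the surface is shifted so the deeper (global) minimum sits at 0.
#'
#' @param minima 2 x 2 matrix, one minimum position per row (Angstrom).
#' @param depths length-2 vector of basin depths (kcal/mol), i.e. escape
#'   barriers over the saddle.  The deeper well is the global minimum, so
#'   the saddle sits `max(depths)` above it.
#' @param saddleHeight saddle energy above the global minimum (kcal/mol);
#'   defaults to, and must equal, `max(depths)`.
#' @param ... passed to [channelPotential2D()].
#' @export
twoState2D <- function(minima, depths, saddleHeight = max(depths), ...) {
  minima <- as.matrix(minima)
  stopifnot(nrow(minima) == 2, length(depths) == 2,
            isTRUE(all.equal(saddleHeight, max(depths))))
  u <- max(depths) - depths          # well energies, global minimum at 0
  d <- sqrt(sum((minima[2, ] - minima[1, ])^2))
  st <- rbind(c(0, u[1]), c(d / 2, max(depths)), c(d, u[2]))
  p <- channelPotential2D(minima[1, ], minima[2, ], st, ...)
  p@name <- "two_state_2d"
  p
}

#' Landscape presets for the two histidine protonation states
#'
#' Returns the analytic stand-in surface for one protonation state of the
#' LBD system.  Both presets are three-basin channel potentials whose
#' stationary energies mirror the reported landscape scale: for the neutral
#' (epsilon-protonated) state `"state_e"` the alternative-like basin A is
#' the global minimum, a weak intermediate I sits on the path, the
#' canonical-like basin C lies 5 kcal/mol below its escape saddle, and the
#' highest saddle is 9 kcal/mol above A.  For the doubly protonated state
#' `"state_plus"` the canonical-like basin C' is global, the broad
#' intermediate basin I' is 4 kcal/mol deep, the alternative-like basin A'
#' is 6 kcal/mol deep, and the highest saddle is 7 kcal/mol.  Basin
#' positions are placed at the reported (RMSD_C, RMSD_A) coordinates of
#' the respective regions.
#'
#' The returned object carries attributes `wells` (named position matrix),
#' `mainSaddle` (kcal/mol) and `globalWell`.
#'
#' @param name `"state_e"` or `"state_plus"`.
#' @param kperp,wall channel confinement, see [channelPotential2D()].
#' @export
potentialPreset <- function(name = c("state_e", "state_plus"),
                            kperp = 250, wall = 60) {
  name <- match.arg(name)
  if (name == "state_e") {
    p0 <- c(8.75, 4.25)   # A: alternative-like, global minimum
    p1 <- c(3.50, 8.00)   # C: canonical-like, 5 kcal/mol deep
    i  <- c(7.25, 6.50)   # I: weak intermediate near A (projected onto
                          #    the channel line below)
    d  <- sqrt(sum((p1 - p0)^2))
    u  <- (p1 - p0) / d
    ti <- sum((i - p0) * u)
    st <- rbind(c(0, 0), c(ti / 2, 5), c(ti, 4), c(5.23, 9), c(d, 4))
    wells <- rbind(A = p0, I = p0 + ti * u, C = p1)
    saddle <- 9
  } else {
    p0 <- c(3.50, 8.50)   # C': canonical-like, global minimum
    p1 <- c(9.75, 3.50)   # A': alternative-like, 6 kcal/mol deep
    i  <- c(5.25, 7.00)   # I': intermediate, a broad basin whose floor
                          #    extends along the channel (the reported
                          #    region spans RMSD_C 4.5-6.0)
    d  <- sqrt(sum((p1 - p0)^2))
    u  <- (p1 - p0) / d
    ti <- sum((i - p0) * u)
    st <- rbind(c(0, 0), c(0.70, 6), c(ti, 2), c(3.50, 2),
                c(7.25, 7), c(d, 1))
    wells <- rbind(Cp = p0, Ip = p0 + ti * u, Ap = p1)
    saddle <- 7
  }
  p <- channelPotential2D(p0, p1, st, kperp = kperp, wall = wall)
  p@name <- name
  attr(p, "wells") <- wells
  attr(p, "mainSaddle") <- saddle
  attr(p, "globalWell") <- rownames(wells)[1]
  p
}

#' Langevin dynamics parameters
#'
#' Overdamped (Brownian) dynamics in reduced time units with friction
#' `gamma`: the Euler--Maruyama update is
#' \deqn{x \leftarrow x + (F/\gamma)\,dt + \sqrt{2 k_B T\, dt/\gamma}\,\xi.}
#'
#' @slot timestep integration step, reduced time units.
#' @slot friction friction coefficient (1/time); the default 1 sets the
#'   time unit.
#' @slot temperature Kelvin.
#' @slot seed integer RNG seed.
#' @slot initialPosition starting point in CV space.
#' @export
setClass("LangevinParams",
  representation(timestep = "numeric", friction = "numeric",
                 temperature = "numeric", seed = "integer",
                 initialPosition = "numeric"),
  validity = function(object) {
    if (object@timestep <= 0) return("timestep must be > 0")
    if (object@friction <= 0) return("friction must be > 0")
    if (object@temperature <= 0) return("temperature must be > 0")
    TRUE
  })

#' @rdname LangevinParams-class
#' @param timestep,friction,temperature,seed,initialPosition see slots.
#' @export
langevinParams <- function(timestep = 0.005, friction = 1,
                           temperature = 298, seed = 1L,
                           initialPosition = 0) {
  new("LangevinParams", timestep = timestep, friction = friction,
      temperature = temperature, seed = as.integer(seed),
      initialPosition = as.numeric(initialPosition))
}

setMethod("show", "LangevinParams", function(object) {
  cat(sprintf(paste0("LangevinParams: dt=%g, gamma=%g, T=%g K, seed=%d, ",
                     "x0=(%s)\n"),
              object@timestep, object@friction, object@temperature,
              object@seed,
              paste(signif(object@initialPosition, 6), collapse = ", ")))
})

#' Sampled trajectory in CV space
#'
#' @slot positions steps x dim matrix of visited positions.
#' @slot forces steps x dim matrix of the systematic CV force
#'   \eqn{-\nabla U} recorded at each visited position (thermal noise and
#'   any external bias are excluded; this is the quantity an ABF estimator
#'   bins).
#' @export
setClass("Trajectory",
  representation(positions = "matrix", forces = "matrix"),
  validity = function(object) {
    if (!all(dim(object@positions) == dim(object@forces)))
      return("positions and forces must have identical dimensions")
    TRUE
  })

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d steps, %dD\n",
              nrow(object@positions), ncol(object@positions)))
})

#' @rdname Trajectory-class
#' @param traj a `Trajectory`.
#' @export
trajectoryPositions <- function(traj) traj@positions

#' @rdname Trajectory-class
#' @export
trajectoryForces <- function(traj) traj@forces

#' Single overdamped Langevin step
#'
#' One Euler--Maruyama update under the systematic force \eqn{-\nabla U}
#' plus an arbitrary external force.  Draws `dim` standard normals from R's
#' RNG stream, so results are reproducible under [set.seed()] and identical
#' to the compiled sampler's updates.
#'
#' @param state current position.
#' @param p an [AnalyticPotential-class].
#' @param externalForce added force vector (kcal/mol/Angstrom).
#' @param lp a [LangevinParams-class].
#' @return the new position.
#' @export
langevinStep <- function(state, p, externalForce = NULL, lp = langevinParams()) {
  state <- as.numeric(state)
  if (is.null(externalForce)) externalForce <- numeric(p@dim)
  f <- -p@gradient(state) + externalForce
  kT <- .kB * lp@temperature
  xi <- rnorm(p@dim)
  out <- state + f * lp@timestep / lp@friction +
    sqrt(2 * kT * lp@timestep / lp@friction) * xi
  if (any(!is.finite(out)))
    stop("non-finite Langevin update; the timestep is too large for this ",
         "potential")
  out
}

#' Run unbiased overdamped Langevin dynamics
#'
#' Samples `nSteps` updates from the compiled inner loop (or via R callback
#' for potentials without a compiled specification).  Deterministic given
#' `lp@seed`.
#'
#' @param p an [AnalyticPotential-class].
#' @param lp a [LangevinParams-class]; `initialPosition` must have length
#'   `dim(p)`.
#' @param nSteps number of steps.
#' @return a [Trajectory-class] of the visited positions (after each step)
#'   and the systematic forces recorded before each step.
#' @export
runLangevin <- function(p, lp, nSteps) {
  stopifnot(is(p, "AnalyticPotential"), is(lp, "LangevinParams"), nSteps >= 1)
  x0 <- lp@initialPosition
  if (length(x0) != p@dim) stop("initialPosition must have length ", p@dim)
  set.seed(lp@seed)
  res <- run_dynamics_cpp(
    spec = p@cppSpec, grad_fun = p@gradient, x0 = as.numeric(x0),
    n_steps = as.integer(nSteps), dt = lp@timestep, gamma = lp@friction,
    kT = .kB * lp@temperature,
    abf = list(enabled = FALSE), record = TRUE)
  new("Trajectory", positions = res$positions, forces = res$forces)
}

#' Build an ideal synthetic alpha-helix structure
#'
#' Generates C-alpha positions on an ideal helix (default rise 1.5
#' Angstrom/residue, 100 degree twist, radius 2.3 Angstrom) plus
#' schematically placed N, C and O backbone atoms, as a
#' [PDBStructure-class].  Useful as a fixture with exactly known geometry.
#'
#' @param nRes number of residues (>= 4).
#' @param rise per-residue rise along the helix axis (Angstrom).
#' @param twist per-residue rotation (degrees).
#' @param radius helix radius (Angstrom).
#' @param chain chain identifier.
#' @param startRes first residue number.
#' @param rotation optional 3 x 3 rotation applied to all coordinates.
#' @param translation optional 3-vector added after rotation.
#' @return a [PDBStructure-class] with N, CA, C, O atoms per residue; the
#'   helix axis of the untransformed structure is +z.
#' @export
makeSyntheticHelix <- function(nRes = 10, rise = 1.5, twist = 100,
                               radius = 2.3, chain = "A", startRes = 1L,
                               rotation = NULL, translation = NULL) {
  stopifnot(nRes >= 4)
  i <- seq_len(nRes) - 1
  th <- i * twist * pi / 180
  ca <- cbind(radius * cos(th), radius * sin(th), i * rise)
  ## schematic backbone: fixed offsets in the local (radial, tangential,
  ## axial) frame so the construct is chiral and selection order is testable
  loc <- function(offsets) {
    radial <- cbind(cos(th), sin(th), 0)
    tangent <- cbind(-sin(th), cos(th), 0)
    axial <- matrix(rep(c(0, 0, 1), each = nRes), ncol = 3)
    ca + offsets[1] * radial + offsets[2] * tangent + offsets[3] * axial
  }
  nn <- loc(c(0.3, -0.8, -0.9))
  cc <- loc(c(0.3, 0.8, 0.9))
  oo <- loc(c(1.0, 1.1, 1.1))
  ## interleave per residue in N, CA, C, O order
  ord <- as.vector(t(matrix(seq_len(4 * nRes), nrow = nRes)))
  xyz <- rbind(nn, ca, cc, oo)[ord, , drop = FALSE]
  if (!is.null(rotation)) xyz <- xyz %*% t(rotation)
  if (!is.null(translation)) xyz <- sweep(xyz, 2, as.numeric(translation), "+")
  n <- nRes * 4
  atoms <- data.frame(
    serial = seq_len(n),
    name = rep(c("N", "CA", "C", "O"), nRes),
    altloc = "",
    res_name = "ALA",
    chain_id = chain,
    res_seq = rep(startRes + i, each = 4),
    i_code = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b_factor = 0,
    element = rep(c("N", "C", "C", "O"), nRes),
    is_hetero = FALSE,
    stringsAsFactors = FALSE)
  newStructure(atoms, pdbID = "SYNTH")
}

#' Rotation matrix from axis and angle
#'
#' @param axis 3-vector (normalised internally).
#' @param angleDeg rotation angle in degrees.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotationMatrix <- function(axis, angleDeg) {
  a <- as.numeric(axis); a <- a / sqrt(sum(a^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
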