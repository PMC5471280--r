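## landscape: replica merging, least-squares integration of the binned
## mean-force field, basin detection, minimum free-energy (minimax) paths,
## barriers and path profiles.

#' Gridded free-energy surface
#'
#' \eqn{\Delta G} over the collective-variable grid, defined only on
#' sampled bins and anchored so the lowest sampled value is 0.  When the
#' sampled mask splits into several connected components each component is
#' anchored to its own minimum and `nComponents > 1` flags that
#' cross-component differences are meaningless.
#'
#' @slot axes per-axis descriptors as in [BinGrid-class].
#' @slot gValues numeric array of \eqn{\Delta G} (kcal/mol), `NA` on
#'   unsampled bins.
#' @slot sampledMask logical array, `TRUE` where the estimate exists.
#' @slot component integer array: connected-component id (8-neighbour) of
#'   each sampled bin, `NA` elsewhere.
#' @slot nComponents number of connected components.
#' @export
setClass("FreeEnergyLandscape",
  representation(axes = "list", gValues = "array", sampledMask = "array",
                 component = "array", nComponents = "integer"),
  validity = function(object) {
    if (!identical(dim(object@gValues), dim(object@sampledMask)))
      return("gValues and sampledMask shape mismatch")
    g <- object@gValues[object@sampledMask]
    if (length(g) && abs(min(g)) > 1e-8)
      return("sampled minimum must be anchored at 0")
    if (any(is.finite(object@gValues[!object@sampledMask])))
      return("unsampled bins must carry no value")
    TRUE
  })

setMethod("show", "FreeEnergyLandscape", function(object) {
  nb <- dim(object@gValues)
  cat(sprintf(paste0("FreeEnergyLandscape %s: %d sampled bins, ",
                     "%d component(s), max G %.2f kcal/mol\n"),
              paste(nb, collapse = " x "), sum(object@sampledMask),
              object@nComponents,
              suppressWarnings(max(object@gValues, na.rm = TRUE))))
})

#' @rdname FreeEnergyLandscape-class
#' @param l a `FreeEnergyLandscape`.
#' @export
gValues <- function(l) l@gValues

#' @rdname FreeEnergyLandscape-class
#' @export
sampledMask <- function(l) l@sampledMask

#' Merge replica bin grids by pooling
#'
#' Counts and force sums are summed bin-wise, so the pooled mean force is
#' the sample-count-weighted average of the per-replica mean forces.  The
#' operation is associative and order-independent.
#'
#' @param grids list of [BinGrid-class] objects on identical axes.
#' @return the pooled [BinGrid-class].
#' @export
mergeRuns <- function(grids) {
  if (is(grids, "BinGrid")) grids <- list(grids)
  stopifnot(length(grids) >= 1)
  ref <- grids[[1]]
  for (g in grids[-1]) {
    if (!isTRUE(all.equal(g@axes, ref@axes)))
      stop("cannot merge grids with different axes")
    ref@counts <- ref@counts + g@counts
    ref@forceSums <- ref@forceSums + g@forceSums
  }
  ref
}

## 8-neighbour connected components of a logical mask (1D: 2-neighbour);
## returns integer array with NA off-mask.
.maskComponents <- function(mask) {
  dm <- dim(mask)
  if (length(dm) == 1L || is.null(dm)) dm <- c(length(mask), 1L)
  nx <- dm[1]; ny <- if (length(dm) > 1) dm[2] else 1L
  comp <- array(NA_integer_, dim = dim(mask))
  nc <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (!is.na(comp[s])) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      ux <- (u - 1L) %% nx + 1L; uy <- (u - 1L) %/% nx + 1L
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0L && dy == 0L) next
        vx <- ux + dx; vy <- uy + dy
        if (vx < 1L || vx > nx || vy < 1L || vy > ny) next
        v <- vx + nx * (vy - 1L)
        if (mask[v] && is.na(comp[v])) {
          comp[v] <- nc
          queue <- c(queue, v)
        }
      }
    }
  }
  list(component = comp, n = nc)
}

#' Integrate the mean-force field into a free-energy surface
#'
#' The free-energy gradient of a sampled bin is minus its mean force.  The
#' surface is recovered as the least-squares solution of the finite
#' difference equations written on every pair of adjacent sampled bins
#' (axis neighbours and, in 2D, diagonal neighbours, which stitches the
#' surface across single-bin staircase corridors).  Each connected
#' component of the sampled mask is solved separately with its own gauge;
#' the result is anchored so the sampled minimum is 0.
#'
#' @param g a [BinGrid-class].
#' @param minCount bins with fewer samples are treated as unsampled.
#' @return a [FreeEnergyLandscape-class]; `nComponents > 1` flags a
#'   disconnected mask.
#' @export
integrateGradient <- function(g, minCount = 1L) {
  nb <- vapply(g@axes, function(a) a$n, integer(1))
  d <- length(nb)
  counts <- as.vector(g@counts)
  mask <- counts >= minCount
  if (!any(mask)) stop("no bin reaches minCount = ", minCount)
  mf <- g@forceSums / pmax(counts, 1L)    # mean force; -dG per axis
  grad <- -mf                             # dG estimates

  nx <- nb[1]; ny <- if (d == 2L) nb[2] else 1L
  w <- vapply(g@axes, function(a) a$width, numeric(1))
  maskArr <- array(mask, dim = if (d == 2L) nb else c(nb, 1L))
  cmp <- .maskComponents(maskArr)

  ## difference equations between adjacent sampled bins
  steps <- if (d == 2L) list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
           else list(c(1L, 0L))
  sampled <- which(mask)
  gi <- match(seq_len(nx * ny), sampled)  # linear index -> unknown id
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  rhs <- numeric(0)
  neq <- 0L
  for (st in steps) {
    ux <- (sampled - 1L) %% nx + 1L
    uy <- (sampled - 1L) %/% nx + 1L
    vx <- ux + st[1]; vy <- uy + st[2]
    ok <- vx >= 1L & vx <= nx & vy >= 1L & vy <= ny
    v <- vx + nx * (vy - 1L)
    ok[ok] <- mask[v[ok]]
    uu <- sampled[ok]; vv <- v[ok]
    if (!length(uu)) next
    dg <- 0.5 * (grad[uu, 1] + grad[vv, 1]) * st[1] * w[1]
    if (d == 2L) dg <- dg + 0.5 * (grad[uu, 2] + grad[vv, 2]) * st[2] * w[2]
    eq <- neq + seq_along(uu)
    rows <- c(rows, eq, eq)
    cols <- c(cols, gi[uu], gi[vv])
    vals <- c(vals, rep(-1, length(uu)), rep(1, length(uu)))
    rhs <- c(rhs, dg)
    neq <- neq + length(uu)
  }

  gvec <- rep(NA_real_, nx * ny)
  if (neq == 0L) {
    gvec[sampled] <- 0       # isolated bins only
  } else {
    A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                              dims = c(neq, length(sampled)))
    ## per-component gauge: augment with one row fixing the first bin of
    ## each component to 0, then solve the normal equations
    compOf <- cmp$component[sampled]
    anchors <- match(seq_len(cmp$n), compOf)
    Aaug <- rbind(A, Matrix::sparseMatrix(i = seq_along(anchors),
                                          j = anchors, x = 1,
                                          dims = c(length(anchors),
                                                   length(sampled))))
    b <- c(rhs, numeric(length(anchors)))
    sol <- Matrix::solve(Matrix::crossprod(Aaug),
                         Matrix::crossprod(Aaug, b))
    gvec[sampled] <- as.numeric(sol)
    ## anchor each component at its own minimum
    for (k in seq_len(cmp$n)) {
      sel <- sampled[compOf == k]
      gvec[sel] <- gvec[sel] - min(gvec[sel])
    }
  }

  new("FreeEnergyLandscape",
      axes = g@axes,
      gValues = array(gvec, dim = nb),
      sampledMask = array(mask, dim = nb),
      component = array(as.vector(cmp$component), dim = nb),
      nComponents = cmp$n)
}

#' Free-energy basin
#'
#' @slot label basin name (assigned in order of increasing minimum).
#' @slot minimumBin per-axis indices of the basin minimum.
#' @slot memberBins linear indices of member bins.
#' @slot gMin basin minimum (kcal/mol).
#' @export
setClass("Basin",
  representation(label = "character", minimumBin = "integer",
                 memberBins = "integer", gMin = "numeric"))

setMethod("show", "Basin", function(object) {
  cat(sprintf("Basin %s: G_min = %.3f kcal/mol at bin (%s), %d bins\n",
              object@label, object@gMin,
              paste(object@minimumBin, collapse = ", "),
              length(object@memberBins)))
})

#' @rdname Basin-class
#' @param b a `Basin`.
#' @export
basinMinimum <- function(b) b@minimumBin

#' @rdname Basin-class
#' @export
basinG <- function(b) b@gMin

## steepest-descent label of every sampled bin (8-neighbour)
.descentLabels <- function(gArr, mask) {
  nb <- dim(gArr)
  nx <- nb[1]; ny <- if (length(nb) > 1) nb[2] else 1L
  n <- nx * ny
  target <- rep(NA_integer_, n)
  for (u in which(as.vector(mask))) {
    ux <- (u - 1L) %% nx + 1L; uy <- (u - 1L) %/% nx + 1L
    best <- u; bestg <- gArr[u]
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0L && dy == 0L) next
      vx <- ux + dx; vy <- uy + dy
      if (vx < 1L || vx > nx || vy < 1L || vy > ny) next
      v <- vx + nx * (vy - 1L)
      if (!mask[v]) next
      if (gArr[v] < bestg - 1e-12 ||
          (abs(gArr[v] - bestg) <= 1e-12 && v < best)) {
        best <- v; bestg <- gArr[v]
      }
    }
    target[u] <- best
  }
  ## follow descent chains to their fixed points
  lab <- target
  sampled <- which(!is.na(lab))
  repeat {
    nxt <- lab
    nxt[sampled] <- target[lab[sampled]]
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  lab
}

## lowest crossing between basin pairs: min over adjacent cross-basin bin
## pairs of max(G_u, G_v)
.basinSaddles <- function(gArr, mask, lab) {
  nb <- dim(gArr)
  nx <- nb[1]; ny <- if (length(nb) > 1) nb[2] else 1L
  saddles <- list()
  key <- function(a, b) paste(sort(c(a, b)), collapse = "-")
  for (u in which(as.vector(mask))) {
    ux <- (u - 1L) %% nx + 1L; uy <- (u - 1L) %/% nx + 1L
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0L && dy == 0L) next
      vx <- ux + dx; vy <- uy + dy
      if (vx < 1L || vx > nx || vy < 1L || vy > ny) next
      v <- vx + nx * (vy - 1L)
      if (!mask[v] || lab[u] == lab[v]) next
      k <- key(lab[u], lab[v])
      h <- max(gArr[u], gArr[v])
      if (is.null(saddles[[k]]) || h < saddles[[k]]) saddles[[k]] <- h
    }
  }
  saddles
}

#' Detect free-energy basins
#'
#' Every sampled bin is assigned to a local minimum by steepest descent
#' over its 8-neighbours; basins whose minimum lies less than `minDepth`
#' below their lowest escape saddle are merged into the neighbouring basin
#' across that saddle, iteratively, so only features deeper than `minDepth`
#' survive.  Basins are labelled `B1`, `B2`, ... in order of increasing
#' minimum.
#'
#' When the sampled mask is disconnected, only the largest connected
#' component is analysed (`mainComponentOnly = TRUE`): satellite
#' components are anchored to their own gauge, so their free energies are
#' not comparable and stray sampled bins would otherwise masquerade as
#' spurious zero-level basins.
#'
#' @param l a [FreeEnergyLandscape-class].
#' @param minDepth minimum basin depth (kcal/mol) for a basin to survive;
#'   the default 2 suppresses shallow features of order a few k_B T.
#' @param mainComponentOnly restrict the analysis to the largest connected
#'   component of the sampled mask.
#' @return list of [Basin-class] objects sorted by `gMin`.
#' @export
findBasins <- function(l, minDepth = 2, mainComponentOnly = TRUE) {
  gArr <- l@gValues
  mask <- l@sampledMask
  if (!any(mask)) stop("landscape has no sampled bins")
  if (mainComponentOnly && l@nComponents > 1L) {
    sizes <- tabulate(l@component[mask], nbins = l@nComponents)
    mask <- mask & !is.na(l@component) &
      l@component == which.max(sizes)
  }
  gv <- as.vector(gArr)
  lab <- .descentLabels(gArr, as.vector(mask))
  repeat {
    mins <- sort(unique(lab[!is.na(lab)]))
    if (length(mins) <= 1L) break
    saddles <- .basinSaddles(gArr, as.vector(mask), lab)
    ## depth of each basin = lowest escape saddle - minimum
    worst <- NULL; worstDepth <- Inf; worstTo <- NULL
    for (m in mins) {
      esc <- Inf; to <- NULL
      for (m2 in mins[mins != m]) {
        k <- paste(sort(c(m, m2)), collapse = "-")
        s <- saddles[[k]]
        if (!is.null(s) && s < esc) { esc <- s; to <- m2 }
      }
      if (is.finite(esc)) {
        depth <- esc - gv[m]
        if (depth < worstDepth) { worstDepth <- depth; worst <- m; worstTo <- to }
      }
    }
    if (is.null(worst) || worstDepth >= minDepth) break
    lab[which(lab == worst)] <- worstTo
  }
  mins <- sort(unique(lab[!is.na(lab)]))
  mins <- mins[order(gv[mins])]
  nb <- dim(gArr)
  nx <- nb[1]
  lapply(seq_along(mins), function(i) {
    m <- mins[i]
    members <- which(lab == m)
    mb <- if (length(nb) > 1)
      c((m - 1L) %% nx + 1L, (m - 1L) %/% nx + 1L) else m
    new("Basin", label = paste0("B", i), minimumBin = as.integer(mb),
        memberBins = as.integer(members), gMin = gv[m])
  })
}

#' Minimum free-energy path
#'
#' @slot bins path bins, steps x d matrix of per-axis indices.
#' @slot arcLength cumulative Euclidean arc length over bin centres
#'   (Angstrom), starting at 0.
#' @slot gProfile free energy along the path (kcal/mol).
#' @slot rcNormalized arc length rescaled to `[0, 1]` (the generalized
#'   reaction coordinate).
#' @export
setClass("FEPath",
  representation(bins = "matrix", arcLength = "numeric",
                 gProfile = "numeric", rcNormalized = "numeric"),
  validity = function(object) {
    n <- nrow(object@bins)
    if (length(object@arcLength) != n || length(object@gProfile) != n ||
        length(object@rcNormalized) != n)
      return("profile lengths must match the number of path bins")
    if (n > 1 && (is.unsorted(object@rcNormalized) ||
                  abs(object@rcNormalized[1]) > 1e-12 ||
                  abs(object@rcNormalized[n] - 1) > 1e-12))
      return("rcNormalized must increase from 0 to 1")
    TRUE
  })

setMethod("show", "FEPath", function(object) {
  cat(sprintf(paste0("FEPath: %d bins, length %.2f A, ",
                     "barrier %.2f kcal/mol\n"),
              nrow(object@bins), max(object@arcLength),
              barrierHeight(object)))
})

#' @rdname FEPath-class
#' @param p an `FEPath`.
#' @export
pathProfile <- function(p) {
  data.frame(rc = p@rcNormalized, arc_length = p@arcLength, G = p@gProfile)
}

#' Minimum free-energy (minimax) path between two basins
#'
#' Finds the 8-connected path over sampled bins that minimises the highest
#' free energy crossed (ties broken by minimal summed G, then
#' lexicographically, making the result deterministic).  This is the path
#' whose peak defines the barrier between the basins.
#'
#' @param l a [FreeEnergyLandscape-class].
#' @param from,to [Basin-class] objects (or per-axis bin indices).
#' @return an [FEPath-class] from `from`'s minimum to `to`'s minimum.
#' @export
minFreeEnergyPath <- function(l, from, to) {
  nb <- dim(l@gValues)
  d <- length(nb)
  asBin <- function(x)
    if (is(x, "Basin")) x@minimumBin else as.integer(x)
  b1 <- asBin(from); b2 <- asBin(to)
  nx <- nb[1]; ny <- if (d == 2L) nb[2] else 1L
  lin <- function(b) if (d == 2L) b[1] + nx * (b[2] - 1L) else b[1]
  g <- as.vector(l@gValues)
  if (l@nComponents > 1L) {
    c1 <- l@component[lin(b1)]; c2 <- l@component[lin(b2)]
    if (!identical(c1, c2))
      stop("basins lie in different connected components of the sampled ",
           "mask; no path exists")
  }
  res <- minimax_path_cpp(g, nx, ny, lin(b1) - 1L, lin(b2) - 1L)
  path <- res$path + 1L
  bins <- if (d == 2L)
    cbind((path - 1L) %% nx + 1L, (path - 1L) %/% nx + 1L)
  else matrix(path, ncol = 1)
  ctr <- binCenters(l)
  xy <- sapply(seq_len(d), function(i) ctr[[i]][bins[, i]])
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = d)
  seg <- sqrt(rowSums((xy[-1, , drop = FALSE] -
                         xy[-nrow(xy), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  rc <- if (max(arc) > 0) arc / max(arc) else
    seq(0, 1, length.out = length(arc))
  if (length(arc) == 1L) rc <- 0
  new("FEPath", bins = bins, arcLength = arc, gProfile = g[path],
      rcNormalized = rc)
}

#' Barrier height of a path
#'
#' `max(G) - G[start]`: the highest free energy along the path measured
#' from its starting basin.
#'
#' @param p an [FEPath-class] (or numeric G profile).
#' @export
barrierHeight <- function(p) {
  g <- if (is(p, "FEPath")) p@gProfile else as.numeric(p)
  max(g) - g[1]
}

#' Escape depth of a basin along a path
#'
#' The relative depth of basin `b`: the highest free energy along `p`
#' minus the basin minimum.  `p` must start or end at `b`'s minimum.
#'
#' @param l a [FreeEnergyLandscape-class] (used only for validation).
#' @param b a [Basin-class].
#' @param p an [FEPath-class] incident to `b`.
#' @export
basinRelativeDepth <- function(l, b, p) {
  ends <- rbind(p@bins[1, ], p@bins[nrow(p@bins), ])
  if (!any(apply(ends, 1, function(e) all(e == b@minimumBin))))
    stop("path is not incident to basin ", b@label)
  max(p@gProfile) - b@gMin
}

#' Write a landscape as a tidy TSV and a contour-ready matrix
#'
#' @param l a [FreeEnergyLandscape-class].
#' @param file tidy TSV path (columns: per-axis centres, G, count mask).
#' @param matrixFile optional path for a plain G matrix (rows = axis 1).
#' @param digits significant digits for the tidy table.
#' @export
writeLandscape <- function(l, file, matrixFile = NULL, digits = 6) {
  ctr <- binCenters(l)
  nb <- dim(l@gValues)
  d <- length(nb)
  if (d == 2L) {
    df <- expand.grid(x = ctr[[1]], y = ctr[[2]])
    df$G <- as.vector(l@gValues)
    df$sampled <- as.integer(as.vector(l@sampledMask))
  } else {
    df <- data.frame(x = ctr[[1]], G = as.vector(l@gValues),
                     sampled = as.integer(as.vector(l@sampledMask)))
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(matrixFile))
    write.table(signif(l@gValues, digits), matrixFile, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write a path profile TSV (rc, coordinates, G)
#'
#' @param p an [FEPath-class].
#' @param l the landscape the path was computed on (for bin centres).
#' @param file output path.
#' @param digits significant digits.
#' @export
writePath <- function(p, l, file, digits = 6) {
  ctr <- binCenters(l)
  d <- ncol(p@bins)
  xy <- sapply(seq_len(d), function(i) ctr[[i]][p@bins[, i]])
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = d)
  df <- data.frame(rc = p@rcNormalized)
  for (i in seq_len(d)) df[[paste0("x", i)]] <- xy[, i]
  df$G <- p@gProfile
  df[] <- lapply(df, function(v) signif(v, digits))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Summarise basins as JSON
#'
#' @param basins list of [Basin-class].
#' @param l the landscape.
#' @param file output JSON path.
#' @export
writeBasinSummary <- function(basins, l, file) {
  ctr <- binCenters(l)
  d <- length(ctr)
  out <- lapply(basins, function(b) {
    pos <- vapply(seq_len(d), function(i) ctr[[i]][b@minimumBin[i]],
                  numeric(1))
    list(label = b@label, g_min = b@gMin, minimum = pos,
         n_bins = length(b@memberBins))
  })
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
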