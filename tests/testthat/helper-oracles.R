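# Independent oracles used across test files.

# Best RMSD over a dense sample of proper rotations (Euler grid plus
# random rotations), allowing optimal translation.
bruteForceRmsd <- function(X, Y, gridStep = 15, nRandom = 4000) {
  X0 <- sweep(X, 2, colMeans(X))
  Y0 <- sweep(Y, 2, colMeans(Y))
  best <- Inf
  angs <- seq(0, 360 - gridStep, by = gridStep)
  tilts <- seq(0, 180, by = gridStep)
  for (a in angs) for (b in tilts) for (c in angs) {
    R <- rotationMatrix(c(0, 0, 1), a) %*%
      rotationMatrix(c(0, 1, 0), b) %*% rotationMatrix(c(0, 0, 1), c)
    d <- sqrt(mean(rowSums((X0 %*% t(R) - Y0)^2)))
    if (d < best) best <- d
  }
  for (i in seq_len(nRandom)) {
    ax <- rnorm(3)
    R <- rotationMatrix(ax, runif(1, 0, 360))
    d <- sqrt(mean(rowSums((X0 %*% t(R) - Y0)^2)))
    if (d < best) best <- d
  }
  best
}

# Exact-gradient grid for a potential: every bin pretends to hold `n`
# samples of the analytic force at its centre.
exactGrid <- function(p, params, n = 5000L) {
  g <- binGrid(params)
  ctr <- binCenters(g)
  nb <- vapply(gridAxes(g), function(a) a$n, integer(1))
  d <- length(nb)
  total <- prod(nb)
  fs <- matrix(0, total, d)
  for (li in seq_len(total)) {
    ij <- if (d == 2L) c((li - 1L) %% nb[1] + 1L, (li - 1L) %/% nb[1] + 1L)
          else li
    x <- vapply(seq_len(d), function(k) ctr[[k]][ij[k]], numeric(1))
    fs[li, ] <- -p@gradient(x) * n
  }
  g@counts <- array(as.integer(n), dim = nb)
  g@forceSums <- fs
  g
}

analyticSurface <- function(p, l) {
  ctr <- binCenters(l)
  nb <- dim(gValues(l))
  if (length(nb) == 1L || is.na(nb[2])) {
    vapply(ctr[[1]], function(x) p@energy(x), numeric(1))
  } else {
    outer(seq_len(nb[1]), seq_len(nb[2]),
          Vectorize(function(i, j) p@energy(c(ctr[[1]][i], ctr[[2]][j]))))
  }
}

# Independent minimax oracle: the barrier equals the smallest threshold at
# which start and goal are 8-connected through cells with G <= threshold.
thresholdOracle <- function(G, start, goal) {
  vals <- sort(unique(as.vector(G[!is.na(G)])))
  nx <- nrow(G); ny <- ncol(G)
  conn <- function(th) {
    ok <- !is.na(G) & G <= th
    if (!ok[start[1], start[2]] || !ok[goal[1], goal[2]]) return(FALSE)
    seen <- matrix(FALSE, nx, ny)
    q <- list(start)
    seen[start[1], start[2]] <- TRUE
    while (length(q)) {
      u <- q[[1]]; q <- q[-1]
      for (dx in -1:1) for (dy in -1:1) {
        v <- u + c(dx, dy)
        if (any(v < 1) || v[1] > nx || v[2] > ny) next
        if (ok[v[1], v[2]] && !seen[v[1], v[2]]) {
          seen[v[1], v[2]] <- TRUE
          q <- c(q, list(v))
        }
      }
    }
    seen[goal[1], goal[2]]
  }
  lo <- 1L; hi <- length(vals)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (conn(vals[mid])) hi <- mid else lo <- mid + 1L
  }
  vals[lo]
}
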