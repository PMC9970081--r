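# Independent oracles and small fixture builders used across the suite.

# Exhaustive discrete Frechet distance: explicit search over all monotone
# couplings (steps right/up/diagonal on the index lattice), pruned by the best
# max-distance found so far. Independent of the package's DP implementation.
bruteFrechet <- function(x1, y1, x2, y2) {
  n <- length(x1)
  m <- length(x2)
  d <- sqrt(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2)
  best <- Inf
  rec <- function(i, j, cur) {
    cur <- max(cur, d[i, j])
    if (cur >= best) return(invisible())
    if (i == n && j == m) {
      best <<- cur
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, cur)
    if (i < n) rec(i + 1L, j, cur)
    if (j < m) rec(i, j + 1L, cur)
    invisible()
  }
  rec(1L, 1L, 0)
  best
}

# direct evaluation of the single-fiber hyperbola, written out longhand
hyperbolaRate <- function(speed, M, D) M * D * speed / (1 + D * speed)

# random nonnegative profile on a shared uniform grid
randomProfile <- function(n = 101L, phaseKind = "stance", controller = "FS") {
  ph <- seq(0, 100, length.out = n)
  center <- runif(1, 20, 80)
  width <- runif(1, 10, 40)
  v <- pmax(0, runif(1, 0.2, 1.5) * (1 - ((ph - center) / width)^2))
  v <- v + runif(1, 0, 0.05)  # small positive floor so norms never vanish
  TorqueProfile(GaitCurve(ph, v, phaseKind, "assistive_torque"),
                controller = controller)
}

# write a small curve table csv and return its path
writeCsvFixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# count separate above-zero lobes of a profile (runs of values > tol)
countLobes <- function(profile, tol = 1e-9) {
  on <- curveValues(profile) > tol
  sum(diff(c(FALSE, on)) == 1L)
}
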