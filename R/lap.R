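# Dense linear-assignment solver: Jonker-Volgenant style shortest
# augmenting path with dual potentials, O(n^3). Written for the square
# link/birth/death matrices this package builds (forbidden entries are a
# large finite cost, so every instance is feasible). Deterministic: ties
# are resolved by the fixed column scan order.

# Returns the minimizing assignment of rows to columns of square matrix
# `cost` as an integer vector `col_of_row`.
lap_solve_dense <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost), all(is.finite(cost)))
  n <- nrow(cost)
  if (n == 0) {
    return(integer(0))
  }
  inf <- Inf
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1) # p[j + 1]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  col_of_row <- integer(n)
  for (j in seq_len(n)) {
    if (p[j + 1] > 0L) col_of_row[p[j + 1]] <- j
  }
  col_of_row
}
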