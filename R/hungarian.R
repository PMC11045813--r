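# Kuhn-Munkres assignment with potentials, O(n^3). Written here because the
# IoU-optimal detection-to-track matching is the heart of the tracker; the
# deterministic row/column iteration order fixes tie resolution.

# Minimum-cost complete assignment of rows to columns.
# cost: n x m matrix with n <= m, all entries finite.
# Returns an integer vector of length n: column assigned to each row.
hungarian_min <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  if (n == 0L) return(integer(0))
  # Columns are indexed 1..m+1 where index jj corresponds to real column
  # jj - 1 and index 1 is the virtual start column.
  u <- numeric(n)
  v <- numeric(m + 1)
  p <- integer(m + 1)       # row matched to each column (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1)
    used <- logical(m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (jj in 2:(m + 1)) {
        if (!used[jj]) {
          cur <- cost[i0, jj - 1L] - u[i0] - v[jj]
          if (cur < minv[jj]) {
            minv[jj] <- cur
            way[jj] <- j0
          }
          if (minv[jj] < delta) {
            delta <- minv[jj]
            j1 <- jj
          }
        }
      }
      for (jj in 1:(m + 1)) {
        if (used[jj]) {
          if (p[jj] > 0L) u[p[jj]] <- u[p[jj]] + delta
          v[jj] <- v[jj] - delta
        } else {
          minv[jj] <- minv[jj] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  out <- integer(n)
  for (jj in 2:(m + 1)) if (p[jj] > 0L) out[p[jj]] <- jj - 1L
  out
}

# Maximum-total-score complete assignment; returns column per row (every row
# assigned when nrow <= ncol, otherwise every column assigned via transpose).
# Output: integer matrix with columns (row, col) over all assigned pairs.
max_score_assignment <- function(score) {
  n <- nrow(score); m <- ncol(score)
  if (n == 0L || m == 0L) return(matrix(integer(0), 0, 2))
  if (n <= m) {
    cols <- hungarian_min(max(score) - score)
    cbind(seq_len(n), cols)
  } else {
    rows <- hungarian_min(t(max(score) - score))
    cbind(rows, seq_len(m))
  }
}
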