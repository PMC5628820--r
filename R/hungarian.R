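# O(n^3) Hungarian algorithm (potentials / augmenting-path formulation) for
# the linear assignment problem, used to map clusters onto label classes.
# Written here because no assignment solver is among the package's
# dependencies; validated in the tests against exhaustive permutation search.

# Maximize the sum of selected entries of `score`, at most one per row and
# column.  Rectangular inputs are padded to square with zeros (unmatched
# rows/columns contribute nothing).  Returns the achieved maximum total.
.assignmentMax <- function(score) {
  n <- max(dim(score))
  A <- matrix(0, n, n)
  A[seq_len(nrow(score)), seq_len(ncol(score))] <- score
  cost <- max(A) - A  # minimization form
  INF <- .Machine$double.xmax / 4
  # index 1 plays the classic "column 0" role; real columns are 2..(n+1)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)    # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in seq.int(2L, n + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j] + 1L] <- u[p[j] + 1L] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
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
  total <- 0
  for (j in seq.int(2L, n + 1L)) total <- total + A[p[j], j - 1L]
  total
}
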