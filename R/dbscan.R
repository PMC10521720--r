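# Density-based clustering (DBSCAN) on a precomputed distance matrix.
# Returns integer labels; -1 marks noise. The O(n^2) formulation is ample
# for contig sets of a few thousand records.
dbscan_impl <- function(d, eps, min_pts = 5) {
  n <- nrow(d)
  neighbours <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neighbours, length, integer(1)) >= min_pts
  labels <- rep(-1L, n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    queue <- setdiff(neighbours[[i]], i)
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == -1L) {
        labels[j] <- cluster
        if (core[j]) queue <- union(queue, setdiff(neighbours[[j]], j))
      }
    }
  }
  labels
}
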