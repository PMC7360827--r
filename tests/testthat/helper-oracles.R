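# Independent brute-force oracles the implementation is checked against.

# Enumerates the nine class boundaries and bins one value at a time with
# literal interval comparisons (class 1 strictly below X - 2s, class 10
# strictly above X + 2s, interior classes [lower, upper), top boundary
# value in class 9).
oracle_bin <- function(values) {
  m <- mean(values)
  s <- sd(values)
  if (s == 0) return(rep(6L, length(values)))
  b <- m - 2 * s + (1:9 - 1) * 0.5 * s
  vapply(values, function(x) {
    if (x < b[1]) return(1L)
    for (j in 2:9) {
      if (x >= b[j - 1] && x < b[j]) return(j)
    }
    if (x == b[9]) return(9L)
    10L
  }, integer(1))
}

# Naive O(n^3) UPGMA: clusters kept as index sets, every pairwise average
# inter-cluster distance recomputed from the original matrix at each step.
# Returns the n - 1 merge heights in merge order.
oracle_upgma_heights <- function(dmat) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- Inf
    best_pair <- c(NA, NA)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        d <- mean(dmat[clusters[[i]], clusters[[j]]])
        if (d < best) {
          best <- d
          best_pair <- c(i, j)
        }
      }
    }
    merged <- c(clusters[[best_pair[1]]], clusters[[best_pair[2]]])
    clusters <- clusters[-best_pair]
    clusters[[length(clusters) + 1]] <- merged
    heights <- c(heights, best)
  }
  heights
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small hand-built collection used across io/diversity tests
tiny_collection <- function() {
  as_collection(tibble::tibble(
    id = c("a1", "a2", "a3", "a4"),
    region = c("I", "I", "II", "II"),
    county = c("x", "x", "y", "y"),
    HSW = c(40, 42, 21, 23),
    PH = c(50, 60, 160, 180),
    GH = c(1L, 1L, 2L, 2L),
    SSC = c(1L, 2L, 0L, 0L)))
}

# archetypes cached once per test run (YAML parse is not free)
cached_archetypes <- local({
  arch <- NULL
  function() {
    if (is.null(arch)) arch <<- default_archetypes()
    arch
  }
})
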