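# Independent brute-force oracles used across the suite.

# Maximum-cardinality opposite-strand matching among SSBs within distance d,
# by exhaustive recursion (feasible for <= ~10 SSBs).
max_matching_count <- function(pos, strand, d) {
  n <- nrow(pos)
  pairs <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (strand[i] != strand[j] &&
        sqrt(sum((pos[i, ] - pos[j, ])^2)) <= d)
      pairs[[length(pairs) + 1]] <- c(i, j)
  }
  if (length(pairs) == 0) return(0L)
  best <- 0L
  recurse <- function(used, k, count) {
    if (count + (length(pairs) - k + 1) <= best) return()
    if (k > length(pairs)) {
      best <<- max(best, count)
      return()
    }
    p <- pairs[[k]]
    if (!used[p[1]] && !used[p[2]]) {
      used2 <- used
      used2[p[1]] <- used2[p[2]] <- TRUE
      recurse(used2, k + 1L, count + 1L)
    }
    recurse(used, k + 1L, count)
    best
  }
  recurse(rep(FALSE, n), 1L, 0L)
  best
}

# Expected number of correctly repaired breaks for k coincident DSBs (all
# pair rates equal): exhaustive recursion over sequential uniform pairings.
# State: k intact breaks (both ends free) and m orphan free ends.
expected_correct_coincident <- function(k, m = 0) {
  key <- paste(k, m)
  cache <- new.env(parent = emptyenv())
  rec <- function(k, m) {
    N <- 2 * k + m
    if (N < 2) return(0)
    key <- paste(k, m)
    if (!is.null(cache[[key]])) return(cache[[key]])
    total <- N * (N - 1) / 2
    val <- 0
    if (k > 0)  # correct joins
      val <- val + (k / total) * (1 + rec(k - 1, m))
    if (m > 1)  # orphan-orphan join
      val <- val + (m * (m - 1) / 2 / total) * rec(k, m - 2)
    if (k > 0 && m > 0)  # orphan joins one end of an intact break
      val <- val + (2 * k * m / total) * rec(k - 1, m + 1)
    if (k > 1)  # ends of two different intact breaks join
      val <- val + (2 * k * (k - 1) / total) * rec(k - 2, m + 2)
    cache[[key]] <- val
    val
  }
  rec(k, m)
}

# convenience: generate split-dose records for one preset and split by
# condition code ("xx", "aa", "xa", "ax")
gen_conditions <- function(truth, seed, noise = TRUE) {
  d <- gen_survival_dataset(truth, seed = seed, noise = noise)
  two <- d[d$dose_2_Gy > 0, ]
  cond <- paste0(substr(two$modality_1, 1, 1), substr(two$modality_2, 1, 1))
  split(two, cond)
}
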