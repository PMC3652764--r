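# Shared fixtures: the canonical worked-example string, a random-string
# generator, and independent brute-force oracles used against the
# implementation.

TOY <- "CCHHHHEEEEECCCCCHHH"

random_ss <- function(n) {
  paste(sample(c("H", "E", "C"), n, replace = TRUE), collapse = "")
}

# Truncated moments computed directly on the distance multiset, without
# going through the package's distribution table.
semi_oracle <- function(dists, k = Inf) {
  kept <- dists[dists <= k]
  e <- sum(kept) / length(dists)
  d <- sum(kept^2) / length(dists) - e^2
  list(E = e, D = d)
}

# Exhaustive 3-window scan, position by position.
three_pattern_oracle <- function(seq) {
  x <- strsplit(seq, "")[[1]]
  counts <- matrix(0, 3, 4, dimnames = list(c("H", "E", "C"), 1:4))
  n <- length(x)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      e <- x[i]
      m <- if (x[i - 1] == e && x[i + 1] == e) 1
      else if (x[i - 1] == e) 2
      else if (x[i + 1] == e) 3
      else 4
      counts[e, m] <- counts[e, m] + 1
    }
  }
  counts
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
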