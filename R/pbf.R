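#' Occurrence positions of an element
#'
#' The 1-based indices at which the element occurs, in ascending order
#' (the position sequence `Po(delta)` obtained by dropping the zeros of
#' the occurrence indicator).
#'
#' @param seq H/E/C string.
#' @param element One of `"H"`, `"E"`, `"C"`.
#' @return Integer vector, possibly empty.
#' @examples
#' ss_positions("CCHHHHEEEEECCCCCHHH", "C")  # 1 2 12 13 14 15 16
#' @export
ss_positions <- function(seq, element) {
  element <- match.arg(element, SS_ALPHABET)
  which(ss_chars(seq) == element)
}

#' Interval distances between successive occurrences
#'
#' Successive differences of a position sequence. A distance of 1 means
#' the two occurrences lie in the same segment; a larger distance means
#' they belong to different segments, so the distance multiset carries
#' both content and arrangement information.
#'
#' @param po Strictly increasing integer vector of positions.
#' @return Integer vector of length `length(po) - 1` (empty when `po` has
#'   fewer than two entries); every entry is at least 1 and the entries
#'   sum to `max(po) - min(po)`.
#' @examples
#' interval_distances(c(1, 2, 12, 13, 14, 15, 16))  # 1 10 1 1 1 1
#' @export
interval_distances <- function(po) {
  po <- as.integer(po)
  if (length(po) >= 2L && any(diff(po) <= 0L))
    stop("positions must be strictly increasing", call. = FALSE)
  diff(po)
}

#' Empirical distribution of interval distances
#'
#' Relative frequency of each distinct interval distance, the probability
#' table `P(Dis(delta) = n)` over positive integers `n`.
#'
#' @param nd Integer vector of interval distances.
#' @return Named numeric vector: names are the distinct distances in
#'   increasing order, values their relative frequencies (summing to 1);
#'   empty when `nd` is empty.
#' @export
distance_distribution <- function(nd) {
  if (length(nd) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (any(nd < 1L))
    stop("interval distances must be positive integers", call. = FALSE)
  tab <- table(nd)
  stats::setNames(as.numeric(tab) / length(nd), names(tab))
}

dist_support <- function(d) as.numeric(names(d))

#' Truncated (semi-) moments of a distance distribution
#'
#' `semi_mean()` is `sum_{n <= k} n P(n)` and `semi_variance()` is
#' `sum_{n <= k} n^2 P(n) - semi_mean^2`. The truncated probabilities are
#' deliberately *not* renormalised, so these are not the mean and variance
#' of a conditional distribution — only the leading terms of the full
#' moments. With `k = Inf` they are the ordinary mean and variance.
#'
#' @param d Distribution from [distance_distribution()].
#' @param k Truncation bound (positive integer) or `Inf` for the full sum.
#' @return Scalar; 0 (mean) for an empty distribution.
#' @examples
#' d <- distance_distribution(c(1, 10, 1, 1, 1, 1))
#' semi_mean(d, 5)       # 5/6
#' semi_variance(d, 5)   # 5/36
#' @export
semi_mean <- function(d, k = Inf) {
  check_k(k)
  n <- dist_support(d)
  keep <- n <= k
  sum(n[keep] * d[keep])
}

#' @rdname semi_mean
#' @export
semi_variance <- function(d, k = Inf) {
  check_k(k)
  n <- dist_support(d)
  keep <- n <= k
  sum(n[keep]^2 * d[keep]) - sum(n[keep] * d[keep])^2
}

check_k <- function(k) {
  if (!(is.infinite(k) || (is.numeric(k) && length(k) == 1L && k >= 1)))
    stop("`k` must be a positive integer or Inf", call. = FALSE)
  invisible(k)
}

#' Reciprocal coefficient of variation of the interval distances
#'
#' The position-based feature for one element: the truncated mean over the
#' truncated standard deviation,
#' \deqn{C_k = \mathrm{SemiE}_k / \sqrt{\mathrm{SemiD}_k}.}
#' With `k = Inf` this is the reciprocal coefficient of variation of the
#' full interval-distance distribution (written `C_F`). When the
#' distribution is empty (fewer than two occurrences of the element) or
#' the truncated variance is not positive (e.g. all distances equal), the
#' statistic is undefined and `degenerate` is returned instead — 0 by
#' default, distinguishable from genuine values, which are positive.
#'
#' `variant = "variance-ratio"` computes mean over variance (no square
#' root) instead, provided for comparison.
#'
#' @param d Distribution from [distance_distribution()].
#' @param k Truncation bound or `Inf`.
#' @param degenerate Value returned when the statistic is undefined.
#' @param variant `"cv"` (default, mean / sd) or `"variance-ratio"`
#'   (mean / variance).
#' @return Scalar.
#' @examples
#' d <- distance_distribution(c(1, 10, 1, 1, 1, 1))
#' c_k(d, k = 5)    # sqrt(5)
#' c_k(d, k = Inf)  # 2.5 / sqrt(11.25)
#' @export
c_k <- function(d, k = Inf, degenerate = 0,
                variant = c("cv", "variance-ratio")) {
  variant <- match.arg(variant)
  check_k(k)
  if (length(d) == 0L) return(degenerate)
  se <- semi_mean(d, k)
  sd_ <- semi_variance(d, k)
  if (sd_ <= 0) return(degenerate)
  if (variant == "cv") se / sqrt(sd_) else se / sd_
}

#' Position-based feature vector for one sequence
#'
#' Applies [c_k()] to the interval-distance distribution of each element,
#' in the fixed order C, H, E. Column names encode the truncation bound:
#' `C5_C` for `k = 5`, `CF_C` for the untruncated statistic.
#'
#' @param seq H/E/C string.
#' @param k Truncation bound or `Inf` (untruncated, the default).
#' @param degenerate Value used when the statistic is undefined for an
#'   element.
#' @param variant Passed to [c_k()].
#' @return Named numeric vector of 3 values.
#' @export
pbf_vector <- function(seq, k = Inf, degenerate = 0,
                       variant = c("cv", "variance-ratio")) {
  variant <- match.arg(variant)
  seq <- ss_validate(seq)
  tag <- if (is.infinite(k)) "CF" else paste0("C", format(k))
  els <- c("C", "H", "E")
  out <- vapply(els, function(e) {
    d <- distance_distribution(interval_distances(ss_positions(seq, e)))
    c_k(d, k = k, degenerate = degenerate, variant = variant)
  }, numeric(1L))
  stats::setNames(out, paste0(tag, "_", els))
}
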