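#' Element content of a secondary-structure sequence
#'
#' Fraction of positions carrying each element: `Count_SE / N`. The three
#' fractions sum to 1.
#'
#' @param seq H/E/C string.
#' @return Named numeric vector `c(H=, E=, C=)`.
#' @examples
#' ss_content("CCHHHHEEEEECCCCCHHH")  # H 7/19, E 5/19, C 7/19
#' @export
ss_content <- function(seq) {
  x <- ss_chars(seq)
  counts <- vapply(SS_ALPHABET, function(e) sum(x == e), numeric(1L))
  counts / length(x)
}

#' Composition moment vector
#'
#' Order-`k` composition moment of one element:
#' \deqn{CMV_k(SE) = \frac{\sum_j PO_{SE,j}^k}{\prod_{d=1}^{k} (N-d)}}
#' where `PO_SE,j` is the 1-based position of the j-th occurrence of the
#' element and `N` the sequence length. Orders 1 and 2 are the feature set
#' used for class prediction. An absent element contributes an empty sum,
#' hence 0.
#'
#' @param seq H/E/C string.
#' @param element One of `"H"`, `"E"`, `"C"`.
#' @param k Moment order, 1 or 2.
#' @return Non-negative scalar.
#' @examples
#' cmv("CCHHHHEEEEECCCCCHHH", "E", k = 1)  # (7+...+11)/18 = 2.5
#' @export
cmv <- function(seq, element, k = 1L) {
  element <- match.arg(element, SS_ALPHABET)
  if (!k %in% c(1L, 2L))
    stop("`k` must be 1 or 2", call. = FALSE)
  x <- ss_chars(seq)
  n <- length(x)
  if (n <= k)
    stop("composition moment of order ", k,
         " is undefined for a sequence of length ", n, call. = FALSE)
  pos <- which(x == element)
  sum(as.numeric(pos)^k) / prod(n - seq_len(k))
}

#' Longest and average segment lengths
#'
#' `max_seg()` is the length of the longest maximal run of the element
#' (`MaxSeg`), `avg_seg()` the mean length of its runs (`AvgSeg`); both are
#' 0 when the element is absent so feature rows stay complete. The
#' normalised forms divide by the sequence length `N`.
#'
#' @param x H/E/C string or a segment data frame from [segment_decompose()].
#' @param element One of `"H"`, `"E"`, `"C"`.
#' @param n Sequence length `N`, required for the normalised forms when `x`
#'   is already a segment data frame (inferred otherwise).
#' @return Non-negative scalar.
#' @export
max_seg <- function(x, element) {
  element <- match.arg(element, SS_ALPHABET)
  sl <- if (is.data.frame(x)) x else segment_decompose(x)
  lens <- sl$len[sl$element == element]
  if (length(lens) == 0L) 0 else max(lens)
}

#' @rdname max_seg
#' @export
avg_seg <- function(x, element) {
  element <- match.arg(element, SS_ALPHABET)
  sl <- if (is.data.frame(x)) x else segment_decompose(x)
  lens <- sl$len[sl$element == element]
  if (length(lens) == 0L) 0 else mean(lens)
}

seg_n <- function(x, n) {
  if (!is.null(n)) return(n)
  sl <- if (is.data.frame(x)) x else segment_decompose(x)
  sum(sl$len)
}

#' @rdname max_seg
#' @export
nmax_seg <- function(x, element, n = NULL) {
  max_seg(x, element) / seg_n(x, n)
}

#' @rdname max_seg
#' @export
navg_seg <- function(x, element, n = NULL) {
  avg_seg(x, element) / seg_n(x, n)
}

#' 3PATTERN window fractions
#'
#' Each interior position `i` (2..N-1) with central element `e` is
#' classified by whether its neighbours match `e`: pattern `m = 1` is
#' `eee`, `m = 2` is `eex`, `m = 3` is `xee`, `m = 4` is `xex`, with `x`
#' any element other than `e`. The pattern encodes whether the central
#' residue sits inside a segment or at a segment interface. Counts are
#' divided by the number of windows, `N - 2`, so the 12 fractions sum to 1;
#' set `normalize = FALSE` for raw counts. Sequences shorter than 3 have no
#' window, giving all zeros.
#'
#' @param seq H/E/C string.
#' @param normalize Divide counts by `N - 2` (default) or return raw counts.
#' @return Named numeric vector of 12 values, elements in order H, E, C and
#'   `m` ascending within each element (`p3_H_m1`, ..., `p3_C_m4`).
#' @export
three_pattern <- function(seq, normalize = TRUE) {
  x <- ss_chars(seq)
  n <- length(x)
  counts <- matrix(0, nrow = 3L, ncol = 4L,
                   dimnames = list(SS_ALPHABET, paste0("m", 1:4)))
  if (n >= 3L) {
    centre <- x[2:(n - 1L)]
    left_ok <- x[1:(n - 2L)] == centre
    right_ok <- x[3:n] == centre
    m <- ifelse(left_ok & right_ok, 1L,
                ifelse(left_ok, 2L, ifelse(right_ok, 3L, 4L)))
    for (i in seq_along(centre))
      counts[centre[i], m[i]] <- counts[centre[i], m[i]] + 1
    if (normalize) counts <- counts / (n - 2L)
  }
  out <- as.vector(t(counts))
  names(out) <- paste0("p3_", rep(SS_ALPHABET, each = 4L), "_m", 1:4)
  out
}

#' Normalised helix/strand alternation frequency
#'
#' Number of adjacent pairs in the coil-free segment sequence whose states
#' differ (helix-to-strand or strand-to-helix switches), divided by the
#' sequence length `N`. Helices and strands alternate more frequently in
#' alpha/beta proteins than in alpha+beta proteins, which is what this
#' feature captures.
#'
#' @param seq H/E/C string.
#' @return Scalar in `[0, 1)`.
#' @examples
#' nalt("CCHHHHEEEEECCCCCHHH")  # reduced (a,b,a): 2 alternations / 19
#' @export
nalt <- function(seq) {
  seq <- ss_validate(seq)
  red <- reduced_segments(seq)
  if (length(red) < 2L) return(0)
  sum(red[-1L] != red[-length(red)]) / nchar(seq)
}

#' Transition probability matrix of the coil-free segment sequence
#'
#' Over adjacent pairs of the reduced segment sequence (states `a` = helix
#' segment, `b` = strand segment), the transition probability from state
#' `i` to state `j` is the pair count divided by the total count of pairs
#' leaving `i`; a row whose denominator is 0 is left entirely 0 rather
#' than renormalised.
#'
#' @param seq H/E/C string.
#' @return Named numeric vector `c(tpm_aa=, tpm_ab=, tpm_ba=, tpm_bb=)`;
#'   each row of the underlying 2x2 matrix sums to 1 or is all zero.
#' @export
tpm <- function(seq) {
  red <- reduced_segments(seq)
  counts <- matrix(0, 2L, 2L, dimnames = list(c("a", "b"), c("a", "b")))
  if (length(red) >= 2L) {
    from <- red[-length(red)]
    to <- red[-1L]
    for (i in seq_along(from))
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  probs <- counts
  for (r in 1:2) {
    tot <- sum(counts[r, ])
    probs[r, ] <- if (tot > 0) counts[r, ] / tot else c(0, 0)
  }
  c(tpm_aa = probs["a", "a"], tpm_ab = probs["a", "b"],
    tpm_ba = probs["b", "a"], tpm_bb = probs["b", "b"])
}

CBF_FAMILIES <- c("content", "cmv", "maxseg", "nmaxseg", "avgseg",
                  "navgseg", "p3", "nalt", "tpm")

#' Content-based feature recipe
#'
#' Selects which content-based feature families to emit, for which
#' elements, and which composition-moment orders. Defaults emit every
#' family for all three elements.
#'
#' @param families Subset of `content`, `cmv`, `maxseg`, `nmaxseg`,
#'   `avgseg`, `navgseg`, `p3`, `nalt`, `tpm`.
#' @param elements Elements to emit per-element families for.
#' @param cmv_orders Composition-moment orders, subset of `1:2`.
#' @param p3_normalize Normalise 3PATTERN counts by the window count.
#' @return An object of class `cbf_recipe`.
#' @export
cbf_recipe <- function(families = CBF_FAMILIES,
                       elements = SS_ALPHABET,
                       cmv_orders = 1:2,
                       p3_normalize = TRUE) {
  if (length(families) == 0L)
    stop("recipe selects no feature family", call. = FALSE)
  families <- match.arg(families, CBF_FAMILIES, several.ok = TRUE)
  elements <- match.arg(elements, SS_ALPHABET, several.ok = TRUE)
  if (!all(cmv_orders %in% 1:2))
    stop("`cmv_orders` must be a subset of 1:2", call. = FALSE)
  structure(list(families = families,
                 elements = SS_ALPHABET[SS_ALPHABET %in% elements],
                 cmv_orders = sort(unique(as.integer(cmv_orders))),
                 p3_normalize = isTRUE(p3_normalize)),
            class = "cbf_recipe")
}

#' Content-based feature vector for one sequence
#'
#' Assembles the selected families into a named numeric row with a fixed,
#' documented column order: families in the order content, cmv, maxseg,
#' nmaxseg, avgseg, navgseg, p3, nalt, tpm; elements in the order H, E, C
#' within per-element families; composition-moment order 1 before 2;
#' 3PATTERN `m` ascending.
#'
#' @param seq H/E/C string.
#' @param recipe A [cbf_recipe()].
#' @return Named numeric vector.
#' @export
cbf_vector <- function(seq, recipe = cbf_recipe()) {
  stopifnot(inherits(recipe, "cbf_recipe"))
  seq <- ss_validate(seq)
  sl <- segment_decompose(seq)
  n <- nchar(seq)
  el <- recipe$elements
  out <- numeric(0)
  for (fam in CBF_FAMILIES) {
    if (!fam %in% recipe$families) next
    part <- switch(fam,
      content = stats::setNames(ss_content(seq)[el],
                                paste0("content_", el)),
      cmv = {
        v <- unlist(lapply(recipe$cmv_orders, function(k)
          stats::setNames(vapply(el, function(e) cmv(seq, e, k), numeric(1L)),
                          paste0("cmv", k, "_", el))))
        v
      },
      maxseg = stats::setNames(
        vapply(el, function(e) max_seg(sl, e), numeric(1L)),
        paste0("maxseg_", el)),
      nmaxseg = stats::setNames(
        vapply(el, function(e) nmax_seg(sl, e, n), numeric(1L)),
        paste0("nmaxseg_", el)),
      avgseg = stats::setNames(
        vapply(el, function(e) avg_seg(sl, e), numeric(1L)),
        paste0("avgseg_", el)),
      navgseg = stats::setNames(
        vapply(el, function(e) navg_seg(sl, e, n), numeric(1L)),
        paste0("navgseg_", el)),
      p3 = {
        v <- three_pattern(seq, normalize = recipe$p3_normalize)
        v[grepl(paste0("^p3_(", paste(el, collapse = "|"), ")_"), names(v))]
      },
      nalt = c(nalt = nalt(seq)),
      tpm = tpm(seq))
    out <- c(out, part)
  }
  out
}
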