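#' Decompose a secondary-structure string into maximal segments
#'
#' A segment is a maximal run of one element. Segments are returned in
#' sequence order with 1-based inclusive start coordinates, so they tile
#' positions `1..N` and adjacent segments always carry different elements.
#' Every segment-based feature (longest/average segment length, the
#' coil-free segment sequence, the transition matrix) is computed from this
#' decomposition.
#'
#' @param seq H/E/C string (validated through [ss_validate()]).
#' @return Data frame with columns `element` (character), `start`
#'   (integer, 1-based) and `len` (integer).
#' @examples
#' segment_decompose("CCHHHHEEEEECCCCCHHH")
#' @export
segment_decompose <- function(seq) {
  x <- ss_chars(seq)
  r <- rle(x)
  len <- r$lengths
  data.frame(element = r$values,
             start = cumsum(c(1L, len[-length(len)])),
             len = len,
             stringsAsFactors = FALSE)
}

# Inverse of segment_decompose; used by property tests and the generator.
segments_expand <- function(sl) {
  paste(rep(sl$element, sl$len), collapse = "")
}

#' Coil-free (reduced) segment sequence
#'
#' Drops coil segments and maps helix segments to state `a` and strand
#' segments to state `b`, preserving order. Because coil removal can
#' juxtapose two segments of the same type, consecutive equal states are
#' retained. This is the substrate for the helix/strand alternation
#' frequency and the transition probability matrix.
#'
#' @param x H/E/C string or a segment data frame from [segment_decompose()].
#' @return Character vector over `{"a","b"}` (possibly empty).
#' @examples
#' reduced_segments("CCHHHHEEEEECCCCCHHH")  # "a" "b" "a"
#' @export
reduced_segments <- function(x) {
  sl <- if (is.data.frame(x)) x else segment_decompose(x)
  el <- sl$element[sl$element != "C"]
  unname(c(H = "a", E = "b")[el])
}
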