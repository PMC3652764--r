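#' Class presets for the synthetic secondary-structure generator
#'
#' The generator works at the segment level: a Markov chain over segment
#' types (H, E, C) with geometrically distributed segment lengths
#' (minimum 1), because every feature in the package is a function of
#' segments and gaps. Each preset caricatures one structural class:
#'
#' * `all-alpha`: helix/coil alternation with long helices; no strands.
#' * `all-beta`: strand/coil alternation with long strands; no helices.
#' * `alpha/beta`: helices and strands interleaved with short coils, so
#'   helix/strand alternation is frequent.
#' * `alpha+beta`: a helix/coil block followed by a strand/coil block —
#'   both elements present but segregated, so alternation is rare.
#'
#' The numeric parameters (mean segment lengths, transition weights,
#' sequence lengths uniform on 80..300 residues) are arbitrary defaults in
#' the range typical of protein domains, not estimates from any corpus.
#'
#' A preset is a list with fields `class` and `phases` (each phase a list
#' with `frac` of the target length, `start` weights over H/E/C and a 3x3
#' `trans` weight matrix with zero diagonal) plus `mean_len` per type and
#' the `len_range` of total sequence length.
#'
#' @return Named list of four presets, one per structural class.
#' @export
default_presets <- function() {
  tr <- function(...) {
    m <- matrix(c(...), nrow = 3L, byrow = TRUE,
                dimnames = list(SS_ALPHABET, SS_ALPHABET))
    stopifnot(all(diag(m) == 0), all(m >= 0))
    m
  }
  phase <- function(start, trans, frac = 1) {
    list(frac = frac, start = start, trans = trans)
  }
  w <- function(H = 0, E = 0, C = 0) c(H = H, E = E, C = C)
  list(
    "all-alpha" = list(
      class = "all-alpha",
      phases = list(phase(w(H = 0.5, C = 0.5),
                          tr(0, 0, 1,   0, 0, 1,   1, 0, 0))),
      mean_len = c(H = 10, E = 4, C = 4),
      len_range = c(80L, 300L)),
    "all-beta" = list(
      class = "all-beta",
      phases = list(phase(w(E = 0.5, C = 0.5),
                          tr(0, 0, 1,   0, 0, 1,   0, 1, 0))),
      mean_len = c(H = 6, E = 6, C = 4),
      len_range = c(80L, 300L)),
    "alpha/beta" = list(
      class = "alpha/beta",
      phases = list(phase(w(H = 0.4, E = 0.4, C = 0.2),
                          tr(0, 0.7, 0.3,   0.7, 0, 0.3,   0.5, 0.5, 0))),
      mean_len = c(H = 8, E = 5, C = 2),
      len_range = c(80L, 300L)),
    "alpha+beta" = list(
      class = "alpha+beta",
      phases = list(
        phase(w(H = 0.5, C = 0.5),
              tr(0, 0, 1,   0, 0, 1,   1, 0, 0), frac = 0.5),
        phase(w(E = 0.5, C = 0.5),
              tr(0, 0, 1,   0, 0, 1,   0, 1, 0), frac = 0.5)),
      mean_len = c(H = 9, E = 5, C = 4),
      len_range = c(80L, 300L))
  )
}

sample_state <- function(weights) {
  weights <- weights[weights > 0]
  if (length(weights) == 1L) return(names(weights))
  sample(names(weights), 1L, prob = weights)
}

# Geometric segment length with minimum 1 and the given mean (>= 1).
rseg_len <- function(mean_len) {
  1L + stats::rgeom(1L, prob = 1 / mean_len)
}

#' Generate one synthetic secondary-structure sequence
#'
#' Draws a target length uniformly from the preset's range, then emits
#' segments from the preset's type chain with geometric lengths until the
#' target is reached, truncating the final segment. Multi-phase presets
#' (alpha+beta) split the target across phases.
#'
#' @param preset One preset from [default_presets()].
#' @param seed Optional integer seed; when given, the draw is reproducible.
#' @return An H/E/C string.
#' @export
generate_sequence <- function(preset, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  target <- sample(seq.int(preset$len_range[1L], preset$len_range[2L]), 1L)
  fr <- vapply(preset$phases, `[[`, numeric(1L), "frac")
  phase_len <- diff(round(cumsum(c(0, fr)) / sum(fr) * target))
  out <- character(0)
  for (p in seq_along(preset$phases)) {
    ph <- preset$phases[[p]]
    emitted <- 0L
    state <- sample_state(ph$start)
    while (emitted < phase_len[p]) {
      len <- min(rseg_len(preset$mean_len[[state]]),
                 phase_len[p] - emitted)
      out <- c(out, strrep(state, len))
      emitted <- emitted + len
      state <- sample_state(ph$trans[state, ])
    }
  }
  paste(out, collapse = "")
}

#' Generate a balanced labelled synthetic dataset
#'
#' `n` sequences per structural class. Per-sequence seeds are derived from
#' the master seed by a counter scheme (`seed + 1000003 * counter`, reduced
#' modulo 2^31 - 1), so regeneration with the same seed is bit-exact and
#' individual sequences can be regenerated in isolation.
#'
#' @param n Sequences per class.
#' @param presets Named list of class presets; defaults to
#'   [default_presets()].
#' @param seed Master integer seed.
#' @return List of class `ss_dataset` with elements `sequences` (named
#'   character vector), `labels` (named character vector of canonical class
#'   labels), `presets` and `seed`.
#' @export
generate_dataset <- function(n = 50L, presets = default_presets(),
                             seed = 1L) {
  stopifnot(n >= 1L, length(presets) >= 1L)
  seqs <- character(0)
  labels <- character(0)
  counter <- 0L
  for (cls in names(presets)) {
    tag <- gsub("[^a-z]+", "", chartr("/+", "sp", cls))
    for (i in seq_len(n)) {
      counter <- counter + 1L
      sub_seed <- (as.numeric(seed) + 1000003 * counter) %% (2^31 - 1)
      id <- sprintf("%s_%03d", tag, i)
      seqs[[id]] <- generate_sequence(presets[[cls]], seed = sub_seed)
      labels[[id]] <- normalize_class(presets[[cls]]$class)
    }
  }
  structure(list(sequences = seqs, labels = labels,
                 presets = presets, seed = seed),
            class = "ss_dataset")
}

#' @export
print.ss_dataset <- function(x, ...) {
  cat("Synthetic secondary-structure dataset:",
      length(x$sequences), "sequences\n")
  print(table(class = x$labels))
  cat("master seed:", x$seed, "\n")
  invisible(x)
}
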