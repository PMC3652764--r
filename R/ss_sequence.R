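#' Three-state secondary-structure alphabet
#'
#' The package works on predicted protein secondary structure in the usual
#' 3-state encoding: `H` (alpha-helix), `E` (beta-strand), `C` (coil).
#'
#' @format Character vector of the three state letters, in the order H, E, C.
#' @export
SS_ALPHABET <- c("H", "E", "C")

#' Recognised structural classes
#'
#' Canonical labels for the four major SCOP folding classes.
#'
#' @format Character vector: `all-alpha`, `all-beta`, `alpha/beta`,
#'   `alpha+beta`.
#' @export
SS_CLASSES <- c("all-alpha", "all-beta", "alpha/beta", "alpha+beta")

#' Validate and normalise a secondary-structure string
#'
#' Strips whitespace, upper-cases, and checks that every symbol is one of
#' `H`, `E`, `C`. All feature extractors call this, so they accept
#' lower-case or whitespace-wrapped input transparently.
#'
#' @param seq A single character string over the alphabet `{H,E,C}`
#'   (case-insensitive; whitespace ignored).
#' @param id Optional sequence identifier used in error messages.
#' @return The normalised (upper-case, whitespace-free) string.
#' @examples
#' ss_validate("cchhhhEEEEEcccccHHH")
#' @export
ss_validate <- function(seq, id = NULL) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("`seq` must be a single character string", call. = FALSE)
  seq <- toupper(gsub("[[:space:]]", "", seq))
  if (nchar(seq) < 1L)
    stop(label_id("sequence", id), " is empty", call. = FALSE)
  bad <- regexpr("[^HEC]", seq)
  if (bad > 0L)
    stop(label_id("sequence", id), " contains symbol '",
         substr(seq, bad, bad), "' outside {H,E,C} at position ", bad,
         call. = FALSE)
  seq
}

label_id <- function(what, id) {
  if (is.null(id)) what else paste0(what, " '", id, "'")
}

# Split a validated string into a character vector of single letters.
ss_chars <- function(seq, id = NULL) {
  strsplit(ss_validate(seq, id), "", fixed = TRUE)[[1L]]
}

#' Normalise structural-class labels
#'
#' Accepts the common spellings of the four structural classes
#' (case-insensitive) and maps them onto the canonical labels in
#' [SS_CLASSES]. Recognised aliases include `all-a`/`all-alpha`/`a`,
#' `all-b`/`all-beta`/`b`, `a/b`/`alpha/beta`/`ab`, and
#' `a+b`/`alpha+beta`/`a.b`.
#'
#' @param x Character vector of class labels.
#' @return Character vector of canonical labels.
#' @export
normalize_class <- function(x) {
  key <- tolower(trimws(as.character(x)))
  alias <- c(
    "all-a" = "all-alpha", "all-alpha" = "all-alpha", "alla" = "all-alpha",
    "a" = "all-alpha", "alpha" = "all-alpha", "all-α" = "all-alpha",
    "all-b" = "all-beta", "all-beta" = "all-beta", "allb" = "all-beta",
    "b" = "all-beta", "beta" = "all-beta", "all-β" = "all-beta",
    "a/b" = "alpha/beta", "alpha/beta" = "alpha/beta", "ab" = "alpha/beta",
    "α/β" = "alpha/beta",
    "a+b" = "alpha+beta", "alpha+beta" = "alpha+beta",
    "α+β" = "alpha+beta")
  out <- unname(alias[key])
  if (anyNA(out))
    stop("unknown structural class label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}
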