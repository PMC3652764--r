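# Columns of the default 11-dimension content-based set used in the
# combined "PBF11CBF" recipe. The composition of this set is a documented
# package default spanning the widely used content-based families; it is
# fully overridable via feature_spec(cbf_columns = ...).
PBF11CBF_CBF_COLUMNS <- c("content_H", "content_E", "content_C",
                          "maxseg_H", "maxseg_E",
                          "nmaxseg_H", "nmaxseg_E",
                          "avgseg_H", "avgseg_E",
                          "nalt", "cmv1_H")

FEATURE_PRESETS <- c("content", "cmv", "maxseg", "nmaxseg", "avgseg",
                     "navgseg", "p3", "nalt", "tpm", "cbf", "pbf",
                     "pbf11cbf")

#' Feature-set specification
#'
#' Resolves a preset name or an explicit recipe into the concrete list of
#' feature columns to compute. Presets:
#'
#' * each single content-based family (`"content"`, `"cmv"`, `"maxseg"`,
#'   `"nmaxseg"`, `"avgseg"`, `"navgseg"`, `"p3"`, `"nalt"`, `"tpm"`);
#' * `"cbf"`: all nine content-based families;
#' * `"pbf"`: the 3-dimensional position-based set (one reciprocal-CV
#'   statistic per element);
#' * `"pbf11cbf"`: the position-based set plus an 11-dimension
#'   content-based selection (see `cbf_columns` default) — 14 columns.
#'
#' Any content-based preset can be combined with the position-based set by
#' appending `"+CF"` (or `"+pbf"`), e.g. `"content+CF"`.
#'
#' @param features Preset name (case-insensitive) or a character vector of
#'   content-based family names.
#' @param pbf_k Truncation bound for the position-based statistic; `Inf`
#'   for the untruncated `C_F`.
#' @param pbf_variant Passed to [c_k()].
#' @param cbf_columns Optional explicit column selection applied after
#'   computing the content-based families (used by the `pbf11cbf` preset;
#'   may be given directly to override its default composition).
#' @param p3_normalize Normalise 3PATTERN counts.
#' @return Object of class `feature_spec` with the resolved recipe.
#' @export
feature_spec <- function(features = "pbf11cbf", pbf_k = Inf,
                         pbf_variant = c("cv", "variance-ratio"),
                         cbf_columns = NULL, p3_normalize = TRUE) {
  pbf_variant <- match.arg(pbf_variant)
  check_k(pbf_k)
  feats <- tolower(features)
  with_pbf <- FALSE
  if (length(feats) == 1L && grepl("\\+(cf|pbf)$", feats)) {
    with_pbf <- TRUE
    feats <- sub("\\+(cf|pbf)$", "", feats)
  }
  if (length(feats) == 1L && feats %in% c("pbf", "pbf11cbf")) {
    with_pbf <- TRUE
    cbf_fams <- if (feats == "pbf11cbf") CBF_FAMILIES else character(0)
    if (feats == "pbf11cbf" && is.null(cbf_columns))
      cbf_columns <- PBF11CBF_CBF_COLUMNS
  } else if (length(feats) == 1L && feats == "cbf") {
    cbf_fams <- CBF_FAMILIES
  } else {
    bad <- setdiff(feats, CBF_FAMILIES)
    if (length(bad) > 0L)
      stop("unknown feature preset/family: ", paste(bad, collapse = ", "),
           "; expected one of ", paste(FEATURE_PRESETS, collapse = ", "),
           " or a '<family>+CF' combination", call. = FALSE)
    cbf_fams <- feats
  }
  if (length(cbf_fams) == 0L && !with_pbf)
    stop("feature specification selects nothing", call. = FALSE)
  recipe <- if (length(cbf_fams) > 0L)
    cbf_recipe(families = cbf_fams, p3_normalize = p3_normalize)
  else NULL
  structure(list(name = paste(features, collapse = "+"),
                 cbf = recipe, cbf_columns = cbf_columns,
                 pbf = if (with_pbf)
                   list(k = pbf_k, variant = pbf_variant, degenerate = 0)
                 else NULL),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("Feature specification '", x$name, "'\n", sep = "")
  if (!is.null(x$cbf))
    cat("  content-based families:",
        paste(x$cbf$families, collapse = ", "), "\n")
  if (!is.null(x$cbf_columns))
    cat("  content-based columns:",
        paste(x$cbf_columns, collapse = ", "), "\n")
  if (!is.null(x$pbf))
    cat("  position-based: k =",
        if (is.infinite(x$pbf$k)) "full" else x$pbf$k,
        "(", x$pbf$variant, ")\n")
  invisible(x)
}

feature_row <- function(seq, spec) {
  row <- numeric(0)
  if (!is.null(spec$cbf)) {
    v <- cbf_vector(seq, spec$cbf)
    if (!is.null(spec$cbf_columns)) {
      missing_cols <- setdiff(spec$cbf_columns, names(v))
      if (length(missing_cols) > 0L)
        stop("requested content-based column(s) not produced: ",
             paste(missing_cols, collapse = ", "), call. = FALSE)
      v <- v[spec$cbf_columns]
    }
    row <- c(row, v)
  }
  if (!is.null(spec$pbf))
    row <- c(row, pbf_vector(seq, k = spec$pbf$k,
                             degenerate = spec$pbf$degenerate,
                             variant = spec$pbf$variant))
  row
}

#' Assemble a feature matrix for a set of sequences
#'
#' Computes the feature row of every sequence under one specification,
#' producing a rectangular matrix with deterministic column order and no
#' missing values (degenerate statistics are filled with their documented
#' defaults). Optionally standardises each column to zero mean and unit
#' variance over the dataset; constant columns are centred but left
#' unscaled. The applied centring/scaling is recorded in the matrix
#' attributes so it can be replayed on new data.
#'
#' @param sequences Named character vector of H/E/C strings, or an
#'   `ss_dataset` from [generate_dataset()].
#' @param spec A [feature_spec()] (or a preset name passed through it).
#' @param scale Standardise columns over the dataset.
#' @return Numeric matrix, rows = sequences, columns = features, with
#'   attributes `spec` and (if scaled) `center` and `scale`.
#' @export
assemble_features <- function(sequences, spec = feature_spec(),
                              scale = FALSE) {
  if (inherits(sequences, "ss_dataset")) sequences <- sequences$sequences
  if (is.character(spec)) spec <- feature_spec(spec)
  stopifnot(inherits(spec, "feature_spec"))
  if (length(sequences) == 0L)
    stop("no sequences to assemble features for", call. = FALSE)
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq_%03d", seq_along(sequences))
  rows <- lapply(sequences, feature_row, spec = spec)
  fm <- do.call(rbind, rows)
  rownames(fm) <- names(sequences)
  attr(fm, "spec") <- spec
  if (scale) {
    ctr <- colMeans(fm)
    scl <- apply(fm, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    fm <- sweep(sweep(fm, 2L, ctr, "-"), 2L, scl, "/")
    attr(fm, "spec") <- spec
    attr(fm, "center") <- ctr
    attr(fm, "scale") <- scl
  }
  fm
}
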