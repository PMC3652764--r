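#' Read secondary-structure sequences from an SS-FASTA file
#'
#' An SS-FASTA file is an ordinary FASTA file whose sequence letters are the
#' 3-state secondary-structure alphabet `{H,E,C}`. Letters are upper-cased
#' and whitespace inside sequence lines is ignored; any other symbol is an
#' error naming the offending record and position.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of validated H/E/C strings; names are
#'   the FASTA record identifiers (first whitespace-delimited token of the
#'   header), in file order.
#' @seealso [write_ss_fasta()], [read_psipred_ss2()]
#' @export
read_ss_fasta <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       set.attributes = FALSE),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(recs) == 0L)
    stop("no FASTA records in '", path, "'", call. = FALSE)
  ids <- names(recs)
  out <- vapply(seq_along(recs),
                function(i) ss_validate(recs[[i]], id = ids[i]),
                character(1L))
  names(out) <- ids
  out
}

#' Write secondary-structure sequences as SS-FASTA
#'
#' @param seqs Named character vector of H/E/C strings.
#' @param path Output file path.
#' @param linewidth Characters per sequence line.
#' @return `path`, invisibly.
#' @export
write_ss_fasta <- function(seqs, path, linewidth = 60L) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("`seqs` must be a named character vector", call. = FALSE)
  seqs <- vapply(names(seqs), function(id) ss_validate(seqs[[id]], id),
                 character(1L))
  seqinr::write.fasta(as.list(seqs), names = names(seqs), file.out = path,
                      as.string = TRUE, nbchar = linewidth)
  invisible(path)
}

#' Read a PSIPRED `.ss2` (VFORMAT) prediction
#'
#' Parses the vertical-format output of PSIPRED: comment (`#`) and blank
#' header lines followed by rows of residue index, amino acid, predicted
#' state letter, and three per-state confidence values. The confidence
#' columns are parsed but discarded: no feature in this package uses them.
#' Only the strict 3-state alphabet is accepted; 8-state DSSP letters are
#' rejected rather than silently reduced.
#'
#' @param path Path to a `.ss2` file.
#' @param id Identifier for the resulting sequence; defaults to the file
#'   stem.
#' @return A named character vector of length 1: the H/E/C string.
#' @export
read_psipred_ss2 <- function(path, id = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (is.null(id))
    id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L)
    stop("no data rows in ss2 file '", path, "'", call. = FALSE)
  tab <- tryCatch(
    utils::read.table(text = lines, header = FALSE,
                      colClasses = c("integer", "character", "character",
                                     "numeric", "numeric", "numeric")),
    error = function(e) stop("malformed ss2 row in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (any(diff(tab[[1L]]) <= 0L))
    stop("residue indices in '", path, "' are not strictly increasing",
         call. = FALSE)
  out <- ss_validate(paste(tab[[3L]], collapse = ""), id = id)
  stats::setNames(out, id)
}

#' Read a structural-class label table
#'
#' Reads a two-column delimited table of sequence id and structural class.
#' The delimiter is taken from the file extension (`.csv` means comma,
#' anything else tab) unless given. Class names are normalised through
#' [normalize_class()], so aliases such as `all-a` or `a+b` are accepted.
#'
#' @param path Path to the table. A header row is detected automatically:
#'   if the second field of the first row is not a recognisable class label
#'   the row is treated as a header.
#' @param sep Field delimiter; `NULL` to infer from the extension.
#' @return Named character vector mapping sequence id to canonical class.
#' @export
read_labels <- function(path, sep = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", strip.white = TRUE)
  if (ncol(tab) < 2L)
    stop("label table '", path, "' needs two columns (id, class)",
         call. = FALSE)
  # header row: second field a header word rather than a class label
  hdr <- tolower(tab[1L, 2L]) %in% c("class", "label", "structural_class") ||
    tolower(tab[1L, 1L]) %in% c("id", "name", "sequence")
  if (hdr) tab <- tab[-1L, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("label table '", path, "' has no data rows", call. = FALSE)
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in label table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  stats::setNames(normalize_class(tab[[2L]]), ids)
}

#' Write a structural-class label table
#'
#' @param labels Named character vector mapping id to class.
#' @param path Output path; comma-delimited if it ends in `.csv`, otherwise
#'   tab-delimited.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(
    data.frame(id = names(labels), class = unname(labels)),
    path, sep = sep, quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a feature matrix as CSV
#'
#' The first column, `id`, holds the row names; remaining columns are the
#' named features. Values are written with full double precision so a
#' read/write round trip is exact to at least 12 significant digits.
#'
#' @param fm Numeric matrix or data frame with row names (sequence ids) and
#'   column names (feature names).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_feature_table()]
#' @export
write_feature_table <- function(fm, path) {
  fm <- as.matrix(fm)
  if (is.null(colnames(fm)))
    stop("feature matrix must have column names", call. = FALSE)
  ids <- rownames(fm)
  if (is.null(ids)) ids <- sprintf("seq_%03d", seq_len(nrow(fm)))
  vals <- array(formatC(fm, digits = 17, format = "g"),
                dim = dim(fm), dimnames = dimnames(fm))
  utils::write.table(cbind(id = ids, vals), path, sep = ",",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_table()]
#'
#' @param path CSV path with an `id` column and numeric feature columns.
#' @return Numeric matrix with row names from the `id` column.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 1L || names(df)[1L] != "id")
    stop("feature table '", path, "' must start with an 'id' column",
         call. = FALSE)
  ids <- df[[1L]]
  vals <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L,
                                    dimnames = list(NULL, names(vals)))
  if (nrow(df) > 0L && anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric value in feature table '", path, "' at row ",
         bad[1L], ", column '", colnames(num)[bad[2L]], "'", call. = FALSE)
  }
  rownames(num) <- ids
  num
}
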