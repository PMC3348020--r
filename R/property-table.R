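#' Amino-acid property tables
#'
#' A property table stores one physicochemical/energetic/conformational
#' scale per row: a numeric value for each of the 20 standard amino acids.
#' Values are kept both on the raw scale and min-max normalized to
#' \[0, 1\]:
#' \deqn{P_{norm}(i) = (P(i) - P_{min}) / (P_{max} - P_{min})}
#' where the minimum and maximum are taken over the 20 standard residues.
#' All downstream feature computation defaults to the normalized scale.
#'
#' @param raw numeric matrix, one row per property, columns named by the
#'   20 one-letter residue codes.
#' @param description character vector of free-text descriptions, one per
#'   property (recycled if length 1).
#' @return An object of class `property_table` with components `property_ids`,
#'   `raw`, `normalized` (both matrices with residue columns in alphabetical
#'   order), `pmin`, `pmax` (named per property) and `description`.
#' @examples
#' m <- matrix(c(0, 1, 2, seq_len(17)), nrow = 1,
#'             dimnames = list("toy", mutprop:::AA_CODES))
#' pt <- property_table(m)
#' range(pt$normalized)
#' @export
property_table <- function(raw, description = "") {
  if (!is.matrix(raw) || !is.numeric(raw)) {
    stop("`raw` must be a numeric matrix (properties x residues)", call. = FALSE)
  }
  missing_res <- setdiff(AA_CODES, colnames(raw))
  if (length(missing_res) > 0) {
    stop("property table is missing residue column(s): ",
         paste(missing_res, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(colnames(raw), AA_CODES)
  if (length(extra) > 0) {
    stop("property table has non-standard residue column(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  ids <- rownames(raw)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("every property needs a non-empty id (rownames of `raw`)", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate property id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, AA_CODES, drop = FALSE]
  if (anyNA(raw)) {
    bad <- which(apply(raw, 1L, anyNA))
    stop("missing/non-numeric value(s) in property row(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  pmin <- apply(raw, 1L, min)
  pmax <- apply(raw, 1L, max)
  degenerate <- pmax <= pmin
  if (any(degenerate)) {
    stop("degenerate property (all 20 values equal, Pmax = Pmin): ",
         paste(ids[degenerate], collapse = ", "), call. = FALSE)
  }
  normalized <- (raw - pmin) / (pmax - pmin)
  structure(
    list(property_ids = ids,
         raw = raw,
         normalized = normalized,
         pmin = setNames(pmin, ids),
         pmax = setNames(pmax, ids),
         description = setNames(rep_len(as.character(description), length(ids)), ids)),
    class = "property_table"
  )
}

#' Load an amino-acid property table from TSV
#'
#' Expects a tab-separated file with header
#' `id<TAB>description<TAB>A<TAB>C<TAB>...` -- one column per one-letter
#' residue code (any column order) and one row per property. Values are
#' validated (all 20 residues present, numeric, no duplicate ids) and
#' min-max normalized on load.
#'
#' @param path path to the TSV file.
#' @return A [property_table].
#' @examples
#' tsv <- system.file("extdata", "aa_properties_synthetic49.tsv",
#'                    package = "mutprop")
#' pt <- load_property_table(tsv)
#' length(pt$property_ids)
#' @export
load_property_table <- function(path) {
  if (!file.exists(path)) stop("property table file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (!all(c("id", "description") %in% colnames(df))) {
    stop("property TSV must have 'id' and 'description' columns", call. = FALSE)
  }
  missing_res <- setdiff(AA_CODES, colnames(df))
  if (length(missing_res) > 0) {
    stop("property TSV is missing residue column(s): ",
         paste(missing_res, collapse = ", "), call. = FALSE)
  }
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup) > 0) {
    stop("duplicate property id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(AA_CODES, function(a) as.numeric(df[[a]]), numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(df$id, AA_CODES))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stop(sprintf("non-numeric cell(s), e.g. property '%s' residue '%s'",
                 rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]]),
         call. = FALSE)
  }
  property_table(vals, description = df$description)
}

#' Min-max normalize one property scale
#'
#' Maps 20 raw residue values onto \[0, 1\] so the minimum becomes 0 and the
#' maximum 1. A constant scale carries no information and is rejected
#' rather than silently zeroed.
#'
#' @param raw_values numeric vector (typically length 20, one value per
#'   residue; names preserved).
#' @return numeric vector of the same length in \[0, 1\].
#' @examples
#' normalize_property(c(2, 7, 12))
#' @export
normalize_property <- function(raw_values) {
  if (!is.numeric(raw_values) || anyNA(raw_values)) {
    stop("raw_values must be numeric with no missing values", call. = FALSE)
  }
  lo <- min(raw_values)
  hi <- max(raw_values)
  if (hi <= lo) {
    stop("degenerate property: all values equal (Pmax = Pmin); cannot normalize",
         call. = FALSE)
  }
  (raw_values - lo) / (hi - lo)
}

#' Look up one property value for one residue
#'
#' @param table a [property_table].
#' @param property_id property identifier (row of the table).
#' @param residue one-letter residue code (standard 20 only).
#' @param scale `"normalized"` (default, used by all feature encodings) or
#'   `"raw"`.
#' @return a single numeric value.
#' @export
get_value <- function(table, property_id, residue,
                      scale = c("normalized", "raw")) {
  stopifnot(inherits(table, "property_table"))
  scale <- match.arg(scale)
  if (!property_id %in% table$property_ids) {
    stop("unknown property id: ", property_id, call. = FALSE)
  }
  check_residue(residue)
  m <- if (scale == "normalized") table$normalized else table$raw
  m[property_id, residue]
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("Amino-acid property table: %d properties x 20 residues\n",
              length(x$property_ids)))
  cat("ids: ", paste(utils::head(x$property_ids, 5), collapse = ", "),
      if (length(x$property_ids) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Write a property table to TSV
#'
#' Inverse of [load_property_table()]: writes the raw scale with the
#' `id`/`description` columns followed by the 20 residue columns.
#'
#' @param table a [property_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_property_table <- function(table, path) {
  stopifnot(inherits(table, "property_table"))
  df <- data.frame(id = table$property_ids,
                   description = unname(table$description),
                   table$raw, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
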