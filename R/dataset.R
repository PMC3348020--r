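#' Site-directed mutant datasets
#'
#' A mutant dataset collects single amino-acid substitutions of one
#' receptor together with an experimental response value per mutant
#' (e.g. change in EC50, cAMP increase, Ca2+ increase). Optionally the
#' receptor sequence (for sequence-window features) and a structure
#' context (for surrounding-residue features) are attached.
#'
#' @param records data.frame with columns `receptor_id`, `position`
#'   (1-based), `wild`, `mutant` (one-letter codes), `response` (numeric)
#'   and optionally `location_class` (`"TM"`, `"loop"` or `"unknown"`).
#' @param sequence optional receptor amino-acid sequence as a single
#'   character string (1-based positions).
#' @param structure optional [structure_context].
#' @param response_label free-text label for what the response measures.
#' @return An object of class `mutant_dataset`.
#' @export
mutant_dataset <- function(records, sequence = NULL, structure = NULL,
                           response_label = "response") {
  required <- c("receptor_id", "position", "wild", "mutant", "response")
  missing_cols <- setdiff(required, colnames(records))
  if (length(missing_cols) > 0) {
    stop("mutant records missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) < 1) stop("a mutant dataset needs at least one record", call. = FALSE)
  if (!"location_class" %in% colnames(records)) records$location_class <- "unknown"
  records$position <- as.integer(records$position)
  if (anyNA(records$position) || any(records$position < 1)) {
    stop("positions must be integers >= 1", call. = FALSE)
  }
  resp <- suppressWarnings(as.numeric(records$response))
  if (anyNA(resp)) {
    stop("non-numeric or missing response value(s) in row(s): ",
         paste(which(is.na(resp)), collapse = ", "), call. = FALSE)
  }
  records$response <- resp
  bad_res <- which(!(records$wild %in% AA_CODES) | !(records$mutant %in% AA_CODES))
  if (length(bad_res) > 0) {
    stop("non-standard residue code(s) in row(s): ",
         paste(bad_res, collapse = ", "), call. = FALSE)
  }
  same <- which(records$wild == records$mutant)
  if (length(same) > 0) {
    stop("wild type equals mutant residue in row(s): ",
         paste(same, collapse = ", "), call. = FALSE)
  }
  if (!records$location_class[1] %in% c("TM", "loop", "unknown") &&
      !all(records$location_class %in% c("TM", "loop", "unknown"))) {
    stop("location_class must be 'TM', 'loop' or 'unknown'", call. = FALSE)
  }
  if (!is.null(sequence)) {
    sequence <- toupper(paste(sequence, collapse = ""))
    seq_chars <- strsplit(sequence, "")[[1]]
    out_of_range <- which(records$position > length(seq_chars))
    if (length(out_of_range) > 0) {
      stop("position beyond sequence length in row(s): ",
           paste(out_of_range, collapse = ", "), call. = FALSE)
    }
    mismatch <- which(seq_chars[records$position] != records$wild)
    if (length(mismatch) > 0) {
      stop("wild-type residue does not match sequence in row(s): ",
           paste(mismatch, collapse = ", "),
           sprintf(" (row %d: sequence has '%s', record says '%s')",
                   mismatch[1], seq_chars[records$position[mismatch[1]]],
                   records$wild[mismatch[1]]),
           call. = FALSE)
    }
  }
  if (!is.null(structure)) stopifnot(inherits(structure, "structure_context"))
  structure(
    list(records = records, sequence = sequence, structure = structure,
         response_label = response_label),
    class = "mutant_dataset"
  )
}

#' @export
print.mutant_dataset <- function(x, ...) {
  cat(sprintf("Mutant dataset: %d mutants of %s (%s)\n",
              nrow(x$records), x$records$receptor_id[1], x$response_label))
  cat(sprintf("  sequence: %s | structure: %s\n",
              if (is.null(x$sequence)) "none" else paste0(nchar(x$sequence), " aa"),
              if (is.null(x$structure)) "none" else paste0(nrow(x$structure$residues), " residues")))
  invisible(x)
}

#' Residue-level structure context
#'
#' Holds one representative coordinate per residue (typically the C-alpha
#' atom), used to define the surrounding-residue neighborhood of a
#' mutation site.
#'
#' @param position integer vector of unique 1-based residue positions.
#' @param residue one-letter residue codes, same length.
#' @param x,y,z coordinates in Angstrom.
#' @return An object of class `structure_context` with a `residues`
#'   data.frame sorted by position.
#' @export
structure_context <- function(position, residue, x, y, z) {
  position <- as.integer(position)
  n <- length(position)
  if (length(residue) != n || length(x) != n || length(y) != n || length(z) != n) {
    stop("position, residue, x, y, z must have equal length", call. = FALSE)
  }
  if (anyDuplicated(position)) stop("residue positions must be unique", call. = FALSE)
  bad <- which(!residue %in% AA_CODES)
  if (length(bad) > 0) {
    stop("non-standard residue code(s) at position(s): ",
         paste(position[bad], collapse = ", "), call. = FALSE)
  }
  ord <- order(position)
  structure(
    list(residues = data.frame(position = position[ord], residue = residue[ord],
                               x = as.numeric(x)[ord], y = as.numeric(y)[ord],
                               z = as.numeric(z)[ord],
                               stringsAsFactors = FALSE)),
    class = "structure_context"
  )
}

#' @export
print.structure_context <- function(x, ...) {
  cat(sprintf("Structure context: %d residues (positions %d..%d)\n",
              nrow(x$residues), min(x$residues$position), max(x$residues$position)))
  invisible(x)
}
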