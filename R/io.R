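#' Read a mutant table from CSV
#'
#' Expects a comma-separated file (UTF-8, '.' decimals) with header
#' columns `receptor_id, position, wild, mutant, response` and optionally
#' `location_class`. Records are validated on load; if a sequence is
#' supplied, the wild-type residue of every record is checked against it
#' and offending rows are listed.
#'
#' @param path CSV path.
#' @param sequence optional receptor sequence (string or FASTA-derived)
#'   to attach and validate against.
#' @param structure optional [structure_context] to attach.
#' @param response_label label describing the response column.
#' @return a [mutant_dataset].
#' @export
read_mutation_table <- function(path, sequence = NULL, structure = NULL,
                                response_label = "response") {
  if (!file.exists(path)) stop("mutation table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mutant_dataset(df, sequence = sequence, structure = structure,
                 response_label = response_label)
}

#' Write a mutant dataset to CSV
#'
#' @param dataset a [mutant_dataset].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "mutant_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a receptor sequence from FASTA
#'
#' Reads the first (or a named) record of a FASTA file and returns the
#' sequence as a plain upper-case string for 1-based position indexing.
#'
#' @param path FASTA path.
#' @param id optional record id; default: first record.
#' @return character string.
#' @export
read_receptor_sequence <- function(path, id = NULL) {
  fa <- bio3d::read.fasta(path, rm.dup = FALSE, to.upper = TRUE)
  ids <- fa$id
  take <- if (is.null(id)) 1L else match(id, ids)
  if (is.na(take)) stop("FASTA record not found: ", id, call. = FALSE)
  seq <- fa$ali[take, ]
  paste(seq[seq != "-"], collapse = "")
}

#' Write a sequence to FASTA
#'
#' @param sequence amino-acid string.
#' @param path output path.
#' @param id record identifier.
#' @return `path`, invisibly.
#' @export
write_sequence_fasta <- function(sequence, path, id = "receptor") {
  bio3d::write.fasta(ids = id,
                     seqs = matrix(strsplit(toupper(sequence), "")[[1]], nrow = 1),
                     file = path)
  invisible(path)
}

#' Read a residue-level structure context from PDB
#'
#' Extracts C-alpha coordinates of one chain (first model, first altloc)
#' as representative residue positions. PDB residue numbers are mapped to
#' 1-based sequence positions via `offset` (sequence position = PDB resno
#' + offset); insertion codes are not supported.
#'
#' @param path PDB path.
#' @param chain chain identifier (default: first chain in the file).
#' @param offset integer added to PDB residue numbers to obtain 1-based
#'   sequence positions.
#' @return a [structure_context].
#' @export
read_structure_pdb <- function(path, chain = NULL, offset = 0L) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  sel <- at$type == "ATOM" & at$elety == "CA" & at$chain %in% chain &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[sel, , drop = FALSE]
  if (nrow(at) == 0) stop("no C-alpha atoms found for chain ", chain, call. = FALSE)
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported", call. = FALSE)
  }
  at <- at[!duplicated(at$resno), , drop = FALSE]
  res1 <- THREE_TO_ONE[at$resid]
  if (anyNA(res1)) {
    stop("non-standard residue(s) in structure: ",
         paste(unique(at$resid[is.na(res1)]), collapse = ", "), call. = FALSE)
  }
  pos <- at$resno + as.integer(offset)
  if (any(pos < 1)) stop("offset maps residue numbers below 1", call. = FALSE)
  structure_context(pos, unname(res1), at$x, at$y, at$z)
}

#' Write a structure context as a C-alpha-only PDB file
#'
#' @param structure a [structure_context].
#' @param path output path.
#' @param chain chain identifier to write.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path, chain = "A") {
  stopifnot(inherits(structure, "structure_context"))
  res <- structure$residues
  xyz <- as.numeric(t(as.matrix(res[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = res$position,
                   resid = unname(ONE_TO_THREE[res$residue]),
                   elety = rep("CA", nrow(res)),
                   chain = rep(chain, nrow(res)))
  invisible(path)
}

#' Write a search report as TSV and JSON
#'
#' The TSV holds one row per ranked combination (rank, columns,
#' coefficients, R, N); the JSON additionally records the search
#' settings and space size.
#'
#' @param report a `search_report` from [exhaustive_subset_search()].
#' @param path_tsv,path_json output paths (either may be `NULL` to skip).
#' @return invisibly, the data.frame written to TSV.
#' @export
write_search_report <- function(report, path_tsv = NULL, path_json = NULL) {
  stopifnot(inherits(report, "search_report"))
  rows <- lapply(seq_along(report$results), function(i) {
    f <- report$results[[i]]
    data.frame(rank = i,
               columns = paste(f$column_ids, collapse = "+"),
               coefficients = paste(sprintf("%.10g", f$coefficients), collapse = ","),
               R = f$R, N = f$N, p = f$p, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(path_tsv)) {
    utils::write.table(df, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(settings = list(sizes = report$sizes, N = report$N, p = report$p,
                           allow_saturated = report$allow_saturated),
           search_space = report$search_space,
           n_fitted = report$n_fitted, n_skipped = report$n_skipped,
           results = lapply(report$results, function(f)
             list(columns = f$column_ids,
                  coefficients = as.list(f$coefficients),
                  R = f$R, N = f$N, p = f$p))),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}

#' Write a classifier evaluation report as TSV and JSON
#'
#' @param report an `evaluation_report` from [evaluate_classifiers()].
#' @param path_tsv,path_json output paths (either may be `NULL` to skip).
#' @return invisibly, the report data.frame.
#' @export
write_evaluation_report <- function(report, path_tsv = NULL, path_json = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  df <- as.data.frame(report)
  if (!is.null(path_tsv)) {
    utils::write.table(df, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(list(best_jackknife_method = attr(report, "best"),
                              results = df),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
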