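#' Mutation-induced property change
#'
#' The basic explanatory variable of the analysis: the difference in a
#' property value between the mutant and the wild-type residue,
#' \deqn{\Delta P = P_{mut} - P_{wild}.}
#'
#' @inheritParams get_value
#' @param wild,mutant one-letter residue codes.
#' @return a single numeric value (antisymmetric in wild/mutant; zero for
#'   an identity substitution).
#' @export
delta_property <- function(table, property_id, wild, mutant,
                           scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  get_value(table, property_id, mutant, scale) -
    get_value(table, property_id, wild, scale)
}

#' Local sequence-window effect of a mutation
#'
#' Sums a property over the wild-type residues in a window of 2k+1
#' positions centred on the mutated site and subtracts the mutant
#' residue's value:
#' \deqn{P_{seq} = \sum_{j = i-k}^{i+k} P_j - P_{mut}.}
#' The sum runs over wild-type residues (including the wild-type residue
#' at the mutated position itself). Windows are truncated at the sequence
#' termini: out-of-range positions contribute nothing. With `k = 0` this
#' reduces to \eqn{P_{wild} - P_{mut}}, the negative of [delta_property()].
#'
#' @inheritParams get_value
#' @param sequence receptor sequence as a single character string.
#' @param position 1-based mutated position; `sequence` must carry the
#'   wild-type residue there.
#' @param mutant one-letter code of the substituted residue.
#' @param k half-window size (window length 2k+1); non-negative integer.
#' @return a single numeric value.
#' @export
local_sequence_effect <- function(table, property_id, sequence, position,
                                  mutant, k,
                                  scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(table, "property_table"))
  if (length(k) != 1L || is.na(k) || k < 0 || k != as.integer(k)) {
    stop("k must be a non-negative integer half-window size", call. = FALSE)
  }
  sequence <- toupper(paste(sequence, collapse = ""))
  n <- nchar(sequence)
  if (position < 1 || position > n) {
    stop(sprintf("position %d outside sequence of length %d", position, n),
         call. = FALSE)
  }
  check_residue(mutant, "mutant residue")
  window <- max(1L, position - as.integer(k)):min(n, position + as.integer(k))
  residues <- strsplit(substr(sequence, window[1], window[length(window)]), "")[[1]]
  vapply(residues, check_residue, character(1), what = "sequence residue")
  m <- if (scale == "normalized") table$normalized else table$raw
  if (!property_id %in% table$property_ids) {
    stop("unknown property id: ", property_id, call. = FALSE)
  }
  sum(m[property_id, residues]) - m[property_id, mutant]
}

#' Residues surrounding a position in space
#'
#' Returns the positions whose representative coordinate lies within
#' `radius` Angstrom (Euclidean) of the given position's coordinate. The
#' residue itself is excluded; sequence-adjacent residues are included if
#' they fall inside the sphere. The 8 Angstrom default is the convention
#' of the surrounding-hydrophobicity literature for C-alpha contact
#' neighborhoods.
#'
#' @param structure a [structure_context].
#' @param position 1-based residue position present in the structure.
#' @param radius contact radius in Angstrom.
#' @return integer vector of neighboring positions (sorted).
#' @export
neighbors_within_radius <- function(structure, position, radius = 8.0) {
  stopifnot(inherits(structure, "structure_context"))
  res <- structure$residues
  idx <- match(position, res$position)
  if (is.na(idx)) {
    stop("position ", position, " absent from structure", call. = FALSE)
  }
  if (radius < 0) stop("radius must be non-negative", call. = FALSE)
  d2 <- (res$x - res$x[idx])^2 + (res$y - res$y[idx])^2 + (res$z - res$z[idx])^2
  keep <- d2 <= radius^2 & res$position != position
  sort(res$position[keep])
}

#' Property sum over surrounding residues
#'
#' The surrounding-residue term
#' \deqn{P_{sur} = \sum_j n_{ij} P_j,}
#' where \eqn{n_{ij}} counts residues of type j within `radius` Angstrom
#' of the mutated site -- equivalently, the sum of the property value over
#' all neighboring residues.
#'
#' @inheritParams neighbors_within_radius
#' @inheritParams get_value
#' @return a single numeric value (0 if the site has no neighbors).
#' @export
surrounding_property_sum <- function(table, property_id, structure, position,
                                     radius = 8.0,
                                     scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(table, "property_table"))
  if (!property_id %in% table$property_ids) {
    stop("unknown property id: ", property_id, call. = FALSE)
  }
  nb <- neighbors_within_radius(structure, position, radius)
  if (length(nb) == 0) return(0.0)
  res <- structure$residues
  types <- res$residue[match(nb, res$position)]
  m <- if (scale == "normalized") table$normalized else table$raw
  sum(m[property_id, types])
}

#' Structural effect of a mutation
#'
#' Combines the surrounding-residue environment with the substituted
#' residue:
#' \deqn{P_{str} = P_{sur} - P_{mut}.}
#' Note that an identity substitution does not in general give zero:
#' \eqn{P_{str}} compares the local environment with the (new) residue at
#' the site, not the wild type with the mutant.
#'
#' @inheritParams surrounding_property_sum
#' @param mutant one-letter code of the substituted residue.
#' @return a single numeric value.
#' @export
structural_effect <- function(table, property_id, structure, position, mutant,
                              radius = 8.0,
                              scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  check_residue(mutant, "mutant residue")
  psur <- surrounding_property_sum(table, property_id, structure, position,
                                   radius, scale)
  m <- if (scale == "normalized") table$normalized else table$raw
  psur - m[property_id, mutant]
}

#' Build a per-mutant feature matrix
#'
#' Constructs one column per (encoding, property) pair for every mutant in
#' the dataset. Available encodings:
#' \describe{
#'   \item{`delta`}{mutation-induced property change \eqn{\Delta P}}
#'   \item{`seq_window`}{local sequence-window effect \eqn{P_{seq}}
#'     (requires an attached sequence; half-window `k`)}
#'   \item{`structural`}{surrounding-residue effect \eqn{P_{str}}
#'     (requires an attached structure; contact `radius`)}
#' }
#' Columns are ordered deterministically: encodings in the order above,
#' properties in table order. Column metadata (encoding, property) is kept
#' in the `"encoding"` and `"property"` attributes.
#'
#' @param dataset a [mutant_dataset].
#' @param table a [property_table].
#' @param encodings character vector, subset of
#'   `c("delta", "seq_window", "structural")`.
#' @param property_ids properties to encode (default: all in the table).
#' @param k half-window for the `seq_window` encoding.
#' @param radius contact radius in Angstrom for the `structural` encoding.
#' @param scale `"normalized"` (default) or `"raw"`.
#' @return numeric matrix (mutants x features) of class `feature_matrix`,
#'   with no missing cells.
#' @export
build_feature_matrix <- function(dataset, table,
                                 encodings = "delta",
                                 property_ids = NULL,
                                 k = 1L, radius = 8.0,
                                 scale = c("normalized", "raw")) {
  stopifnot(inherits(dataset, "mutant_dataset"), inherits(table, "property_table"))
  scale <- match.arg(scale)
  enc_order <- c("delta", "seq_window", "structural")
  bad <- setdiff(encodings, enc_order)
  if (length(bad) > 0) stop("unknown encoding(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  encodings <- enc_order[enc_order %in% encodings]
  if ("seq_window" %in% encodings && is.null(dataset$sequence)) {
    stop("seq_window encoding requested but the dataset has no sequence attached",
         call. = FALSE)
  }
  if ("structural" %in% encodings && is.null(dataset$structure)) {
    stop("structural encoding requested but the dataset has no structure attached",
         call. = FALSE)
  }
  if (is.null(property_ids)) property_ids <- table$property_ids
  unknown <- setdiff(property_ids, table$property_ids)
  if (length(unknown) > 0) stop("unknown property id(s): ",
                                paste(unknown, collapse = ", "), call. = FALSE)
  property_ids <- table$property_ids[table$property_ids %in% property_ids]
  rec <- dataset$records
  n <- nrow(rec)
  cols <- list()
  meta_enc <- character(0)
  meta_prop <- character(0)
  for (enc in encodings) {
    for (pid in property_ids) {
      vals <- switch(
        enc,
        delta = vapply(seq_len(n), function(i)
          delta_property(table, pid, rec$wild[i], rec$mutant[i], scale),
          numeric(1)),
        seq_window = vapply(seq_len(n), function(i)
          local_sequence_effect(table, pid, dataset$sequence, rec$position[i],
                                rec$mutant[i], k, scale),
          numeric(1)),
        structural = vapply(seq_len(n), function(i)
          structural_effect(table, pid, dataset$structure, rec$position[i],
                            rec$mutant[i], radius, scale),
          numeric(1))
      )
      cols[[paste(enc, pid, sep = ":")]] <- vals
      meta_enc <- c(meta_enc, enc)
      meta_prop <- c(meta_prop, pid)
    }
  }
  fm <- do.call(cbind, cols)
  rownames(fm) <- paste0(rec$wild, rec$position, rec$mutant)
  if (anyNA(fm)) stop("internal error: missing feature cell", call. = FALSE)
  structure(fm, encoding = meta_enc, property = meta_prop,
            k = as.integer(k), radius = radius, scale = scale,
            class = c("feature_matrix", class(fm)))
}
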