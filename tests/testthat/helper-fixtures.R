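# Shared fixtures and the independent brute-force oracle.

AA <- mutprop:::AA_CODES

# Single-property toy table with chosen residue values on the normalized
# scale. Remaining residues are filled with an even spread over [0, 1]
# (including both endpoints), so min-max normalization is the identity and
# the stated values pass through unchanged.
toy_table <- function(..., id = "toy") {
  vals <- c(...)
  stopifnot(all(names(vals) %in% AA), all(vals >= 0 & vals <= 1))
  others <- setdiff(AA, names(vals))
  raw <- setNames(numeric(20), AA)
  raw[names(vals)] <- vals
  raw[others] <- seq(0, 1, length.out = length(others))
  property_table(matrix(raw, nrow = 1, dimnames = list(id, AA)))
}

packaged_table <- function() {
  load_property_table(system.file("extdata", "aa_properties_synthetic49.tsv",
                                  package = "mutprop"))
}

# Independent oracle: enumerate all column subsets in REVERSE order, fit
# with lm, score by |cor(fitted, observed)|, and apply the documented
# tie-break (higher R, then smaller subset, then lexicographic order).
# Shares no code with the package's search path.
brute_force_best <- function(X, y, sizes) {
  lex_less <- function(a, b) {
    for (i in seq_len(min(length(a), length(b)))) {
      if (a[i] != b[i]) return(a[i] < b[i])
    }
    length(a) < length(b)
  }
  best <- NULL
  for (s in rev(sort(sizes))) {
    combos <- utils::combn(ncol(X), s)
    for (j in rev(seq_len(ncol(combos)))) {
      idx <- combos[, j]
      fit <- stats::lm(y ~ ., data = data.frame(y = y, X[, idx, drop = FALSE]))
      R <- abs(stats::cor(stats::fitted(fit), y))
      if (is.null(best) ||
          R > best$R ||
          (R == best$R && (length(idx) < length(best$idx) ||
                           (length(idx) == length(best$idx) &&
                            lex_less(idx, best$idx))))) {
        best <- list(idx = idx, R = R)
      }
    }
  }
  best
}

random_features <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("c", seq_len(p))))
}
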