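#' Configuration for synthetic mutant data
#'
#' Bundles the knobs of the synthetic-data generator. Defaults mirror the
#' strata typical of site-directed mutagenesis studies of olfactory
#' receptors: small mutant sets (6-28 records) whose response is a noisy
#' linear function of a few amino-acid property differences.
#'
#' @param seed integer seed; the generator is bit-identical given
#'   (config, seed).
#' @param n_mutants number of mutant records (>= 3).
#' @param n_properties number of properties in play (used when a table is
#'   simulated alongside).
#' @param true_subset integer indices (into the property table) of the
#'   properties that actually drive the response.
#' @param beta0 intercept of the true linear model.
#' @param beta slope per true property (recycled to `length(true_subset)`).
#' @param noise_sd Gaussian response noise, as a fraction of the SD of
#'   the noiseless responses (scale-free difficulty).
#' @param encoding which feature encoding carries the signal: `"delta"`,
#'   `"seq_window"` or `"structural"`.
#' @param k half-window for `seq_window`.
#' @param radius contact radius for `structural`.
#' @param class_margin class-separation gap for labelled sets, in
#'   normalized property units (see [simulate_classification_dataset()]);
#'   0 selects the random-label null model.
#' @param n_increase,n_decrease class sizes for labelled sets (defaults
#'   15/13, a typical small receptor mutant panel).
#' @param seq_length length of the generated receptor sequence.
#' @param geometry `"helix"` (ideal alpha-helical C-alpha trace) or
#'   `"random_packed"` for simulated structures.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_mutants = 28L, n_properties = 49L,
                              true_subset = 1:3, beta0 = 0.5,
                              beta = c(2, -1.5, 1), noise_sd = 0.05,
                              encoding = c("delta", "seq_window", "structural"),
                              k = 1L, radius = 8.0,
                              class_margin = 0.5,
                              n_increase = 15L, n_decrease = 13L,
                              seq_length = 300L,
                              geometry = c("helix", "random_packed")) {
  encoding <- match.arg(encoding)
  geometry <- match.arg(geometry)
  if (n_mutants < 3) stop("n_mutants must be >= 3", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (class_margin < 0) stop("class_margin must be >= 0", call. = FALSE)
  beta <- rep_len(beta, length(true_subset))
  structure(
    list(seed = as.integer(seed), n_mutants = as.integer(n_mutants),
         n_properties = as.integer(n_properties),
         true_subset = as.integer(true_subset), beta0 = beta0, beta = beta,
         noise_sd = noise_sd, encoding = encoding, k = as.integer(k),
         radius = radius, class_margin = class_margin,
         n_increase = as.integer(n_increase),
         n_decrease = as.integer(n_decrease),
         seq_length = as.integer(seq_length), geometry = geometry),
    class = "simulation_config"
  )
}

#' Simulate an amino-acid property table
#'
#' Each property draws its 20 residue values independently from a uniform
#' distribution on a random interval (random location in \[-10, 10\],
#' random width in \[1, 10\]) and is then min-max normalized, so the
#' simulated table satisfies every invariant of a loaded one.
#'
#' @param n_properties number of property rows (>= 1).
#' @param seed integer seed (bit-identical regeneration).
#' @return a [property_table] with ids `prop01`, `prop02`, ...
#' @export
simulate_property_table <- function(n_properties, seed = 1L) {
  if (n_properties < 1) stop("n_properties must be >= 1", call. = FALSE)
  with_seed(seed, {
    vals <- t(vapply(seq_len(n_properties), function(i) {
      lo <- runif(1, -10, 10)
      width <- runif(1, 1, 10)
      runif(20, lo, lo + width)
    }, numeric(20)))
    dimnames(vals) <- list(sprintf("prop%02d", seq_len(n_properties)), AA_CODES)
    property_table(vals,
                   description = sprintf("synthetic uniform scale (seed %d)", seed))
  })
}

random_sequence <- function(n) paste(sample(AA_CODES, n, replace = TRUE),
                                     collapse = "")

#' Simulate a residue-level structure
#'
#' `helix` places C-alpha positions on an ideal alpha helix (rise 1.5 A,
#' 100 degrees per residue, helix radius 2.3 A), which makes 8 A contact
#' neighborhoods non-trivial (interior residues have ~8 neighbors).
#' `random_packed` scatters points uniformly in a cube with a minimum
#' pairwise separation of 3.8 A (the C-alpha virtual bond length).
#'
#' @param n_residues number of residues (>= 1).
#' @param geometry `"helix"` or `"random_packed"`.
#' @param seed integer seed.
#' @param sequence optional residue string to assign along the trace
#'   (defaults to a random sequence).
#' @return a [structure_context].
#' @export
simulate_structure <- function(n_residues, geometry = c("helix", "random_packed"),
                               seed = 1L, sequence = NULL) {
  geometry <- match.arg(geometry)
  if (n_residues < 1) stop("n_residues must be >= 1", call. = FALSE)
  with_seed(seed, {
    residues <- if (is.null(sequence)) strsplit(random_sequence(n_residues), "")[[1]]
                else strsplit(toupper(sequence), "")[[1]][seq_len(n_residues)]
    if (geometry == "helix") {
      i <- seq_len(n_residues) - 1
      theta <- i * 100 * pi / 180
      structure_context(seq_len(n_residues), residues,
                        x = 2.3 * cos(theta), y = 2.3 * sin(theta),
                        z = 1.5 * i)
    } else {
      box <- max(10, 3.8 * ceiling(n_residues^(1 / 3)) * 2.5)
      pts <- matrix(NA_real_, n_residues, 3)
      placed <- 0
      attempts <- 0
      while (placed < n_residues && attempts < 10000 * n_residues) {
        cand <- runif(3, 0, box)
        attempts <- attempts + 1
        if (placed == 0 ||
            min(sqrt(colSums((t(pts[seq_len(placed), , drop = FALSE]) - cand)^2))) >= 3.8) {
          placed <- placed + 1
          pts[placed, ] <- cand
        }
      }
      if (placed < n_residues) stop("could not pack points at 3.8 A separation",
                                    call. = FALSE)
      structure_context(seq_len(n_residues), residues,
                        x = pts[, 1], y = pts[, 2], z = pts[, 3])
    }
  })
}

# Draw mutant records (positions without replacement where possible,
# wild from the sequence, mutant != wild) on a fresh random sequence.
draw_records <- function(config, sequence) {
  L <- nchar(sequence)
  seq_chars <- strsplit(sequence, "")[[1]]
  positions <- if (config$n_mutants <= L) sample(L, config$n_mutants)
               else sample(L, config$n_mutants, replace = TRUE)
  wild <- seq_chars[positions]
  mutant <- vapply(wild, function(w) sample(setdiff(AA_CODES, w), 1), character(1))
  data.frame(receptor_id = "synthOR1", position = positions, wild = wild,
             mutant = unname(mutant), response = 0,
             location_class = sample(c("TM", "loop"), config$n_mutants,
                                     replace = TRUE, prob = c(0.7, 0.3)),
             stringsAsFactors = FALSE)
}

#' Simulate a mutant dataset with known linear property dependence
#'
#' Generates a receptor sequence (and, for the structural encoding, a
#' helical structure along it), draws wild/mutant/position records, and
#' sets the response to
#' \deqn{Y = \beta_0 + \sum_{s \in S} \beta_s f_s + \epsilon,}
#' where \eqn{f_s} is the configured encoding's feature for true-subset
#' property s and \eqn{\epsilon} is Gaussian with SD equal to
#' `noise_sd` times the SD of the noiseless responses. The ground truth
#' (subset ids, coefficients, noise) is attached as the `"ground_truth"`
#' attribute so recovery can be tested closed-loop. A draw in which a
#' true-subset feature comes out constant is regenerated (bounded
#' retries) with a warning.
#'
#' @param table a [property_table].
#' @param config a [simulation_config].
#' @return a [mutant_dataset] with sequence (and structure if needed)
#'   attached.
#' @export
simulate_mutation_dataset <- function(table, config) {
  stopifnot(inherits(table, "property_table"), inherits(config, "simulation_config"))
  if (any(config$true_subset > length(table$property_ids))) {
    stop("true_subset indexes beyond the property table", call. = FALSE)
  }
  true_ids <- table$property_ids[config$true_subset]
  with_seed(config$seed, {
    for (attempt in seq_len(20)) {
      sequence <- random_sequence(config$seq_length)
      rec <- draw_records(config, sequence)
      struct <- if (config$encoding == "structural") {
        simulate_structure(config$seq_length, config$geometry,
                           seed = sample.int(2^31 - 1, 1), sequence = sequence)
      } else NULL
      ds <- mutant_dataset(rec, sequence = sequence, structure = struct,
                           response_label = "synthetic response")
      fm <- build_feature_matrix(ds, table, encodings = config$encoding,
                                 property_ids = true_ids, k = config$k,
                                 radius = config$radius)
      if (any(apply(fm, 2L, stats::sd) == 0)) {
        warning("constant true-subset feature in draw; regenerating", call. = FALSE)
        next
      }
      noiseless <- config$beta0 + drop(fm %*% config$beta)
      eps_sd <- config$noise_sd * stats::sd(noiseless)
      y <- noiseless + rnorm(config$n_mutants, 0, eps_sd)
      ds$records$response <- y
      attr(ds, "ground_truth") <- list(
        true_subset = true_ids, beta0 = config$beta0, beta = config$beta,
        noise_sd = config$noise_sd, eps_sd = eps_sd,
        noiseless = noiseless, encoding = config$encoding, k = config$k,
        seed = config$seed)
      return(ds)
    }
    stop("failed to generate non-degenerate dataset in 20 attempts", call. = FALSE)
  })
}

#' Simulate a labelled increase/decrease classification set
#'
#' One designated property (the first entry of `true_subset`) carries the
#' class signal: `increase` mutants are drawn so its mutation-induced
#' change satisfies \eqn{\Delta P \ge} `class_margin`, `decrease` mutants
#' \eqn{\Delta P \le -}`class_margin` (normalized units), so
#' `class_margin` directly controls the class gap in feature space. The
#' response is \eqn{10 \Delta P} plus small sign-preserving Gaussian
#' noise, so [label_by_sign()] reproduces the construction.
#' `class_margin = 0` switches to the null model: records are drawn
#' without any constraint, the 15/13 labels are assigned by random
#' permutation, and responses carry the label sign but no feature
#' information.
#'
#' @param table a [property_table].
#' @param config a [simulation_config]; uses `seed`, `n_increase`,
#'   `n_decrease`, `class_margin`, `true_subset`, `noise_sd`, `k`,
#'   `seq_length`.
#' @return list with `labeled` (a `labeled_dataset` encoded via
#'   [encode_for_classification()] over the true-subset properties) and
#'   `dataset` (the underlying [mutant_dataset]).
#' @export
simulate_classification_dataset <- function(table, config) {
  stopifnot(inherits(table, "property_table"), inherits(config, "simulation_config"))
  pid <- table$property_ids[config$true_subset[1]]
  pvals <- table$normalized[pid, ]
  n_inc <- config$n_increase
  n_dec <- config$n_decrease
  margin <- config$class_margin
  if (margin > 0 && margin >= max(pvals) - min(pvals)) {
    stop("class_margin exceeds the property's normalized range", call. = FALSE)
  }
  with_seed(config$seed, {
    sequence <- random_sequence(config$seq_length)
    seq_chars <- strsplit(sequence, "")[[1]]
    draw_one <- function(sign_needed) {
      for (i in seq_len(10000)) {
        pos <- sample(config$seq_length, 1)
        w <- seq_chars[pos]
        if (margin == 0) {
          m <- sample(setdiff(AA_CODES, w), 1)
          return(c(pos = pos, wild = w, mutant = m))
        }
        ok <- if (sign_needed > 0) {
          names(pvals)[pvals - pvals[w] >= margin]
        } else {
          names(pvals)[pvals - pvals[w] <= -margin]
        }
        ok <- setdiff(ok, w)
        if (length(ok) > 0) {
          return(c(pos = pos, wild = w, mutant = sample(ok, 1)))
        }
      }
      stop("could not draw a mutant at the requested class margin", call. = FALSE)
    }
    signs <- c(rep(1, n_inc), rep(-1, n_dec))
    draws <- lapply(signs, draw_one)
    rec <- data.frame(
      receptor_id = "synthOR1",
      position = as.integer(vapply(draws, `[[`, character(1), "pos")),
      wild = vapply(draws, `[[`, character(1), "wild"),
      mutant = vapply(draws, `[[`, character(1), "mutant"),
      response = 0,
      location_class = sample(c("TM", "loop"), n_inc + n_dec,
                              replace = TRUE, prob = c(0.7, 0.3)),
      stringsAsFactors = FALSE)
    if (margin == 0) {
      # null model: labels independent of features
      lab_sign <- sample(signs)
      rec$response <- lab_sign * abs(rnorm(n_inc + n_dec, 1, 0.3))
    } else {
      dp <- pvals[rec$mutant] - pvals[rec$wild]
      resp <- 10 * dp + rnorm(n_inc + n_dec, 0, 0.3)
      flipped <- sign(resp) != sign(dp)
      resp[flipped] <- sign(dp[flipped]) * 0.1
      rec$response <- unname(resp)
    }
    ds <- mutant_dataset(rec, sequence = sequence,
                         response_label = "synthetic delta-EC50")
    true_ids <- table$property_ids[config$true_subset]
    labeled <- encode_for_classification(ds, table, true_ids, k = config$k)
    attr(labeled, "ground_truth") <- list(
      separating_property = pid, class_margin = margin,
      null_model = margin == 0, seed = config$seed)
    list(labeled = labeled, dataset = ds)
  })
}
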