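# Synthetic classification datasets and tabulated reward functions, so every
# supervised-learning stage and every gradient oracle is testable without any
# download.

new_synthetic_dataset <- function(features, labels, metadata) {
  if (!all(is.finite(features))) stop("features must be finite")
  if (nrow(features) != length(labels)) {
    stop("one label per feature row required")
  }
  if (length(unique(labels)) < max(labels) + 1) {
    stop("every class must have at least one instance")
  }
  structure(list(features = features, labels = as.integer(labels),
                 metadata = metadata),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic dataset '%s': %d instances, %d features, %d classes\n",
              x$metadata$generator, nrow(x$features), ncol(x$features),
              length(unique(x$labels))))
  invisible(x)
}

#' Separable multi-class Gaussian clusters
#'
#' Class centers sit at the vertices of a scaled simplex (`separation` times
#' the standard basis vectors); instances are centers plus isotropic
#' Gaussian noise. `separation = 0` collapses all classes onto one cloud
#' (chance-level Bayes accuracy); `separation >> noise_sd` is perfectly
#' separable.
#'
#' @param n_classes number of classes C >= 2.
#' @param dim feature dimension (>= `n_classes`).
#' @param n_per_class instances per class.
#' @param separation distance scale of the class centers (>= 0).
#' @param noise_sd isotropic noise standard deviation.
#' @param nonnegative shift features into the nonnegative orthant
#'   (spike-like inputs).
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @return a `synthetic_dataset` with `features` (n x dim), 0-based `labels`
#'   and `metadata`.
#' @export
make_cluster_classification <- function(n_classes, dim, n_per_class,
                                        separation, noise_sd = 1,
                                        nonnegative = FALSE, seed = 1L) {
  if (n_classes < 2) stop("`n_classes` must be >= 2")
  if (separation < 0) stop("`separation` must be >= 0")
  if (dim < n_classes) stop("`dim` must be >= `n_classes` for simplex centers")
  if (n_per_class < 1) stop("`n_per_class` must be >= 1")
  n <- n_classes * n_per_class
  labels <- rep(0:(n_classes - 1L), each = n_per_class)
  centers <- diag(separation, n_classes, dim)
  features <- with_seed(seed, {
    centers[labels + 1L, , drop = FALSE] +
      matrix(stats::rnorm(n * dim, sd = noise_sd), n, dim)
  })
  if (nonnegative) features <- features - min(features)
  new_synthetic_dataset(features, labels,
                        list(generator = "cluster", n_classes = n_classes,
                             dim = dim, n_per_class = n_per_class,
                             separation = separation, noise_sd = noise_sd,
                             nonnegative = nonnegative, seed = seed))
}

digit_glyph_strings <- function() {
  list(
    c("..####..", ".#....#.", ".#....#.", ".#....#.",
      ".#....#.", ".#....#.", ".#....#.", "..####.."),
    c("...##...", "..###...", "...##...", "...##...",
      "...##...", "...##...", "...##...", ".######."),
    c("..####..", ".#....#.", "......#.", ".....#..",
      "....#...", "...#....", "..#.....", ".######."),
    c("..####..", ".#....#.", "......#.", "...###..",
      "......#.", "......#.", ".#....#.", "..####.."),
    c("....##..", "...#.#..", "..#..#..", ".#...#..",
      ".######.", ".....#..", ".....#..", ".....#.."),
    c(".######.", ".#......", ".#......", ".#####..",
      "......#.", "......#.", ".#....#.", "..####.."),
    c("..####..", ".#......", ".#......", ".#####..",
      ".#....#.", ".#....#.", ".#....#.", "..####.."),
    c(".######.", "......#.", ".....#..", "....#...",
      "...#....", "...#....", "...#....", "...#...."),
    c("..####..", ".#....#.", ".#....#.", "..####..",
      ".#....#.", ".#....#.", ".#....#.", "..####.."),
    c("..####..", ".#....#.", ".#....#.", "..#####.",
      "......#.", "......#.", "......#.", "..####..")
  )
}

# 10 x 64 binary matrix of the noise-free digit templates
digit_templates <- function() {
  t(vapply(digit_glyph_strings(), function(g) {
    as.numeric(strsplit(paste(g, collapse = ""), "")[[1]] == "#")
  }, numeric(64)))
}

#' Digit-like 8x8 pixel patterns
#'
#' Ten fixed binary glyphs (one per digit 0-9) on an 8x8 grid, corrupted by
#' independent pixel flips — a desk-scale stand-in for handwritten-digit
#' data that keeps full training sweeps in the minutes range. At
#' `pixel_noise = 0` the dataset contains exactly 10 distinct feature
#' patterns; as `pixel_noise` approaches 0.5 the labels become
#' uninformative.
#'
#' @param n_per_class noisy instances per digit.
#' @param pixel_noise per-pixel flip probability in \[0, 0.5).
#' @param seed RNG seed.
#' @return a `synthetic_dataset` with 64 binary features and labels 0-9.
#' @export
make_digit_patterns <- function(n_per_class, pixel_noise = 0.1, seed = 1L) {
  if (pixel_noise < 0 || pixel_noise >= 0.5) {
    stop("`pixel_noise` must lie in [0, 0.5)")
  }
  templates <- digit_templates()
  n <- 10L * n_per_class
  labels <- rep(0:9, each = n_per_class)
  base <- templates[labels + 1L, , drop = FALSE]
  features <- with_seed(seed, {
    flips <- matrix(stats::runif(n * 64L) < pixel_noise, n, 64L)
    abs(base - flips)  # flip where indicated
  })
  new_synthetic_dataset(features, labels,
                        list(generator = "digit_patterns",
                             n_per_class = n_per_class,
                             pixel_noise = pixel_noise, seed = seed))
}

# --- tabulated reward functions (exact enumeration oracle) -----------------

all_release_patterns <- function(k) {
  idx <- 0:(2^k - 1L)
  vapply(seq_len(k), function(b) (idx %/% 2^(b - 1L)) %% 2L, numeric(2^k))
}

#' Tabulated reward over K synapses
#'
#' A reward function on the 2^K binary release patterns, stored exhaustively
#' so expected reward and exact gradients can be enumerated.
#'
#' @param table numeric vector of length 2^K; entry `i` is the reward of the
#'   pattern whose bits (least-significant first) encode `i - 1`.
#' @param target optional target pattern recorded in the object.
#' @return a `tabular_reward` with fields `K`, `table`, `target`.
#' @export
tabular_reward <- function(table, target = NULL) {
  k <- log2(length(table))
  if (k != round(k) || k < 1) stop("`table` length must be a power of two")
  if (k > 12) stop("K > 12: enumeration table too large")
  structure(list(K = as.integer(k), table = as.numeric(table),
                 target = target),
            class = "tabular_reward")
}

#' Target-pattern (Hamming) reward
#'
#' `R(theta) = 1 - Hamming(theta, target) / K`: maximal (1) at the target
#' release pattern, 0 at its complement. The standard bandit for
#' parameter-recovery tests of the plasticity rule.
#'
#' @param K number of synapses (<= 12).
#' @param target binary vector of length K; `NULL` draws one under `seed`.
#' @param seed seed for a random target.
#' @return a [tabular_reward()].
#' @export
make_target_pattern_reward <- function(K, target = NULL, seed = 1L) {
  if (K > 12) stop("K > 12: enumeration table too large")
  target <- target %||% with_seed(seed, stats::rbinom(K, 1L, 0.5))
  if (length(target) != K || !all(target %in% c(0, 1))) {
    stop("`target` must be a binary vector of length K")
  }
  patterns <- all_release_patterns(K)
  hamming <- as.numeric(patterns %*% rep(1, K)) +
    sum(target) - 2 * as.numeric(patterns %*% target)
  tabular_reward(1 - hamming / K, target = target)
}

#' Reward of one release sample under a tabulated reward
#'
#' @param reward_fn a [tabular_reward()].
#' @param sample binary vector or matrix with K entries.
#' @return scalar reward.
#' @export
tabular_reward_value <- function(reward_fn, sample) {
  bits <- as.numeric(sample)
  if (length(bits) != reward_fn$K) stop("sample has wrong length")
  reward_fn$table[sum(bits * 2^(seq_along(bits) - 1L)) + 1L]
}

#' Exact expected reward and gradient by enumeration
#'
#' Brute-force oracle over all 2^K release patterns:
#' `J(rho) = sum_theta P(theta | rho) R(theta)` and the exact score-function
#' gradient `dJ/drho_k = sum_theta P(theta|rho) R(theta) (theta_k - rho_k) /
#' (rho_k (1 - rho_k))`. Independent of the Monte-Carlo estimators it
#' validates.
#'
#' @param rho numeric vector of K release probabilities in (0, 1).
#' @param reward_fn a [tabular_reward()].
#' @return list with `J` (scalar) and `grad` (length-K vector).
#' @export
enumerate_reward <- function(rho, reward_fn) {
  k <- reward_fn$K
  rho <- as.numeric(rho)
  if (length(rho) != k) stop("`rho` must have length K")
  if (any(rho <= 0 | rho >= 1)) stop("`rho` must lie strictly inside (0, 1)")
  patterns <- all_release_patterns(k)
  logp <- patterns %*% log(rho) + (1 - patterns) %*% log(1 - rho)
  p <- as.numeric(exp(logp))
  pr <- p * reward_fn$table
  grad <- vapply(seq_len(k), function(b) {
    sum(pr * (patterns[, b] - rho[b])) / (rho[b] * (1 - rho[b]))
  }, numeric(1))
  list(J = sum(pr), grad = grad)
}

# --- CSV round trip ---------------------------------------------------------

#' Export a dataset as headered CSV
#'
#' Columns `f1..fd` plus a trailing `label` column.
#'
#' @param dataset a `synthetic_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- as.data.frame(dataset$features)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$label <- dataset$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset_csv()]
#'
#' @param path CSV file path.
#' @return a `synthetic_dataset`.
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path)
  lab <- df$label
  feats <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  dimnames(feats) <- NULL
  storage.mode(feats) <- "double"
  new_synthetic_dataset(feats, lab, list(generator = "csv", path = path))
}
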