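#' Generate an imbalanced two-cluster Gaussian dataset
#'
#' Two spherical Gaussian clusters with unit within-class spread, class mean
#' vectors `class_sep` apart along the first axis. Exactly
#' `round(boundary_frac * n)` rows (chosen seeded across both classes) are
#' instead drawn centred on the midpoint between the class means, emulating
#' "boundary samples"; exactly `round(noise_frac * n)` further rows are
#' mislabeled "noisy samples" — their features are drawn from the opposite
#' class's cluster while their label is kept, so class counts stay exact.
#' Counts are fixed, not binomial, which keeps tests exact. The planted
#' structure is recoverable from the provenance attribute.
#'
#' @param n_maj,n_min Majority and minority class sizes (`n_maj >= n_min >= 2`).
#' @param p Feature count.
#' @param class_sep Distance between class means, in within-class standard
#'   deviation units.
#' @param noise_frac Fraction of all rows planted as mislabeled noise, in
#'   \[0, 0.5\].
#' @param boundary_frac Fraction of all rows placed at the midpoint region,
#'   in \[0, 0.5\].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param maj_label,min_label Label values for the two classes.
#' @param positive_class Label treated as the case class; defaults to the
#'   minority.
#' @return A [labeled_dataset()] with an attribute `provenance`: a list with
#'   the config echo and the planted `noise_indices` and `boundary_indices`.
#' @export
generate_imbalanced <- function(n_maj, n_min, p = 2L, class_sep = 2,
                                noise_frac = 0, boundary_frac = 0,
                                seed = NULL, maj_label = "majority",
                                min_label = "minority",
                                positive_class = min_label) {
  stopifnot(n_maj >= n_min, n_min >= 2L, p >= 1L,
            noise_frac >= 0, noise_frac <= 0.5,
            boundary_frac >= 0, boundary_frac <= 0.5)
  n <- n_maj + n_min
  labels <- c(rep(maj_label, n_maj), rep(min_label, n_min))
  mu <- rbind(rep(0, p), c(class_sep, rep(0, p - 1L)))  # majority, minority
  own <- c(rep(1L, n_maj), rep(2L, n_min))
  n_bnd <- round(boundary_frac * n)
  n_noise <- round(noise_frac * n)
  X <- matrix(0, n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  bnd_idx <- integer(0); noise_idx <- integer(0)
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, "generate"), {
    X[] <- stats::rnorm(n * p) + mu[own, , drop = FALSE]
    if (n_bnd > 0L) {
      bnd_idx <- sort(sample.int(n, n_bnd))
      mid <- colMeans(mu)
      X[bnd_idx, ] <- matrix(stats::rnorm(n_bnd * p, sd = 0.5), n_bnd, p) +
        matrix(mid, n_bnd, p, byrow = TRUE)
    }
    if (n_noise > 0L) {
      pool <- setdiff(seq_len(n), bnd_idx)
      noise_idx <- sort(pool[sample.int(length(pool), n_noise)])
      opp <- 3L - own[noise_idx]
      X[noise_idx, ] <- matrix(stats::rnorm(n_noise * p), n_noise, p) +
        mu[opp, , drop = FALSE]
    }
  })
  ds <- labeled_dataset(X, labels, positive_class = positive_class)
  attr(ds, "provenance") <- list(
    config = list(n_maj = n_maj, n_min = n_min, p = p, class_sep = class_sep,
                  noise_frac = noise_frac, boundary_frac = boundary_frac,
                  seed = seed, maj_label = maj_label, min_label = min_label),
    noise_indices = noise_idx, boundary_indices = bnd_idx)
  ds
}

#' Dataset-shape presets emulating the study's clinical tables
#'
#' `"missed_abortion_like"` reproduces the shape of a 249 case / 112 normal
#' table with 7 features; `"diabetes_like"` a 500 case / 268 normal table
#' with 8 features (the Pima shape). Both use moderate class overlap
#' (`class_sep = 2`), 5% planted noisy samples and 10% boundary samples.
#' Only shape, imbalance and noise structure are emulated — not the real
#' features' semantics or covariance.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A [labeled_dataset()] with provenance, as in
#'   [generate_imbalanced()].
#' @export
preset_dataset <- function(name = c("missed_abortion_like", "diabetes_like"),
                           seed = NULL) {
  name <- match.arg(name)
  shape <- switch(name,
    missed_abortion_like = list(n_maj = 249L, n_min = 112L, p = 7L),
    diabetes_like = list(n_maj = 500L, n_min = 268L, p = 8L))
  generate_imbalanced(shape$n_maj, shape$n_min, p = shape$p, class_sep = 2,
                      noise_frac = 0.05, boundary_frac = 0.10, seed = seed,
                      maj_label = "case", min_label = "normal",
                      positive_class = "case")
}

#' Planted-noise provenance of a generated dataset
#'
#' @param ds A dataset from [generate_imbalanced()] or [preset_dataset()].
#' @return Integer vector of planted noisy-row indices.
#' @export
planted_noise <- function(ds) {
  pv <- attr(ds, "provenance")
  if (is.null(pv)) stop("dataset carries no generator provenance", call. = FALSE)
  pv$noise_indices
}
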