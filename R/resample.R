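#' Resampler configuration
#'
#' Bundles the tunable knobs shared by the resamplers. `k_smote` is the
#' neighbour count used when synthesising minority samples (conventionally 5);
#' `k_enn` the neighbour count used by the ENN editing pass (conventionally
#' 3).
#'
#' @param k_smote Neighbours considered per minority seed during synthesis.
#' @param k_enn Neighbours voting in the ENN editing pass.
#' @param edit_target Which rows ENN may delete: `"majority_only"` (the
#'   standalone ENN default) or `"both_classes"` (the default inside
#'   [smote_enn()]). `NULL` lets each resampler pick its own default.
#' @param seed Integer seed; every stochastic stage draws from a stream
#'   derived from it.
#' @param target_ratio Desired minority/majority count ratio after
#'   over-sampling, in (0, 1].
#' @param strict_eq4 Reproduce the extrapolating synthesis formula
#'   `x_seed + r * (x_seed - x_neighbor)` instead of the interpolating
#'   `x_seed + r * (x_neighbor - x_seed)`. Off by default; see the package
#'   vignette for why interpolation is the intended reading.
#' @param enn_rule Neighbourhood vote rule for ENN: `"majority"` deletes a row
#'   when a strict majority of its `k_enn` neighbours carries the other label;
#'   `"unanimity"` requires all of them to.
#' @return A list of class `resampler_config`.
#' @export
resampler_config <- function(k_smote = 5L, k_enn = 3L, edit_target = NULL,
                             seed = NULL, target_ratio = 1,
                             strict_eq4 = FALSE,
                             enn_rule = c("majority", "unanimity")) {
  stopifnot(k_smote >= 1L, k_enn >= 1L,
            target_ratio > 0, target_ratio <= 1)
  if (!is.null(edit_target))
    edit_target <- match.arg(edit_target, c("majority_only", "both_classes"))
  structure(list(k_smote = as.integer(k_smote), k_enn = as.integer(k_enn),
                 edit_target = edit_target, seed = seed,
                 target_ratio = target_ratio, strict_eq4 = isTRUE(strict_eq4),
                 enn_rule = match.arg(enn_rule)),
            class = "resampler_config")
}

new_resampled <- function(dataset, origin, deleted, before, method, cfg,
                          warn = character(0)) {
  structure(list(dataset = dataset, origin = origin,
                 deleted_original_indices = as.integer(deleted),
                 counts_before = before, counts_after = class_counts(dataset),
                 method = method, config = cfg, warnings = warn),
            class = "resampled_dataset")
}

#' @export
print.resampled_dataset <- function(x, ...) {
  fmt <- function(cc) paste0(cc$n_majority, "/", cc$n_minority)
  cat("<resampled_dataset> method =", x$method, "\n")
  cat("  Maj/Min:", fmt(x$counts_before), "->", fmt(x$counts_after), "\n")
  cat("  synthetic rows:", sum(x$origin == "synthetic"),
      "; deleted rows:", length(x$deleted_original_indices), "\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' SMOTE over-sampling
#'
#' Synthesises new minority-class rows until the minority count reaches
#' `round(target_ratio * majority count)`. Minority seeds are cycled
#' round-robin in row order; for each synthetic row one of the seed's
#' `k_smote` minority-class nearest neighbours is chosen uniformly, and the
#' new point is `x_seed + r * (x_neighbor - x_seed)` with `r ~ U(0, 1)`, i.e.
#' a point on the segment between seed and neighbour. Per synthetic row the
#' neighbour index is drawn first, then `r`. Original rows are retained
#' verbatim.
#'
#' @param ds A [labeled_dataset()].
#' @param cfg A [resampler_config()].
#' @return A `resampled_dataset`: the enlarged dataset plus provenance
#'   (per-row `origin` tags, before/after counts, config echo).
#' @export
smote <- function(ds, cfg = resampler_config()) {
  stopifnot(inherits(ds, "labeled_dataset"))
  before <- class_counts(ds)
  if (before$degenerate) stop("SMOTE needs two classes", call. = FALSE)
  if (before$n_minority < 2L)
    stop("minority class has a single point; cannot synthesise", call. = FALSE)
  if (cfg$k_smote >= before$n_minority)
    stop("k_smote = ", cfg$k_smote, " must be smaller than the minority count ",
         before$n_minority, call. = FALSE)
  n_target <- round(cfg$target_ratio * before$n_majority)
  n_syn <- max(0L, as.integer(n_target) - before$n_minority)
  origin <- rep("original", ds$n)
  if (n_syn == 0L)
    return(new_resampled(ds, origin, integer(0), before, "smote", cfg))

  min_rows <- which(ds$labels == before$minority)
  Xmin <- ds$features[min_rows, , drop = FALSE]
  ## k nearest minority neighbours of each minority row (self excluded,
  ## distance ties by ascending row index in the full dataset)
  d2 <- as.matrix(stats::dist(Xmin))^2
  diag(d2) <- Inf
  nb <- do.call(rbind, lapply(seq_along(min_rows), function(i)
    min_rows[order(d2[i, ], min_rows)[seq_len(cfg$k_smote)]]))

  syn <- matrix(0, n_syn, ds$p, dimnames = list(NULL, ds$feature_names))
  with_seed(if (is.null(cfg$seed)) NULL else derive_seed(cfg$seed, "smote"), {
    for (s in seq_len(n_syn)) {
      i <- ((s - 1L) %% before$n_minority) + 1L          # round-robin seed row
      j <- sample.int(cfg$k_smote, 1L)
      r <- stats::runif(1L)
      xs <- ds$features[min_rows[i], ]
      xn <- ds$features[nb[i, j], ]
      syn[s, ] <- if (cfg$strict_eq4) xs + r * (xs - xn) else xs + r * (xn - xs)
    }
  })
  out <- labeled_dataset(rbind(ds$features, syn),
                         c(ds$labels, rep(before$minority, n_syn)),
                         positive_class = ds$positive_class,
                         label_name = ds$label_name)
  new_resampled(out, c(origin, rep("synthetic", n_syn)), integer(0), before,
                "smote", cfg)
}

#' Edited nearest neighbour (ENN) under-sampling
#'
#' A single simultaneous editing pass: every eligible row whose label
#' disagrees with the vote of its `k_enn` nearest neighbours (self excluded,
#' neighbours drawn from the full dataset) is marked, and all marked rows are
#' deleted together. Eligibility follows `edit_target`; the standalone
#' default deletes majority-class rows only. Vote ties retain the row.
#'
#' @inheritParams smote
#' @return A `resampled_dataset` with `deleted_original_indices` referring to
#'   rows of `ds`. An emptied class sets a warning flag rather than erroring.
#' @export
enn <- function(ds, cfg = resampler_config()) {
  stopifnot(inherits(ds, "labeled_dataset"))
  before <- class_counts(ds)
  k <- cfg$k_enn
  if (k >= ds$n - 1L) stop("k_enn must be < n - 1", call. = FALSE)
  target <- if (is.null(cfg$edit_target)) "majority_only" else cfg$edit_target
  eligible <- if (target == "majority_only")
    which(ds$labels == before$majority) else seq_len(ds$n)
  nb <- knn_index_matrix(ds$features, k)
  marked <- vapply(eligible, function(i) {
    same <- sum(ds$labels[nb[i, ]] == ds$labels[i])
    if (cfg$enn_rule == "unanimity") same == 0L else same < (k - same)
  }, logical(1L))
  del <- eligible[marked]
  keep <- setdiff(seq_len(ds$n), del)
  warn <- character(0)
  for (lab in unique(ds$labels))
    if (!any(ds$labels[keep] == lab))
      warn <- c(warn, paste0("class '", lab, "' emptied by editing"))
  if (length(warn)) warning(paste(warn, collapse = "; "), call. = FALSE)
  out <- labeled_dataset(ds$features[keep, , drop = FALSE], ds$labels[keep],
                         positive_class = if (ds$positive_class %in% ds$labels[keep])
                           ds$positive_class else NULL,
                         label_name = ds$label_name)
  new_resampled(out, rep("original", length(keep)), del, before, "enn", cfg,
                warn)
}

#' Tomek-link under-sampling
#'
#' A Tomek link is a pair of opposite-class rows that are each other's single
#' nearest neighbour. The majority-class member of every link is deleted.
#' Deterministic: distance ties break by ascending row index.
#'
#' @inheritParams smote
#' @return A `resampled_dataset`.
#' @export
tomek_link <- function(ds, cfg = resampler_config()) {
  stopifnot(inherits(ds, "labeled_dataset"))
  before <- class_counts(ds)
  if (before$degenerate) stop("Tomek links need two classes", call. = FALSE)
  nn1 <- knn_index_matrix(ds$features, 1L)[, 1L]
  del <- integer(0)
  for (i in seq_len(ds$n)) {
    j <- nn1[i]
    if (i < j && nn1[j] == i && ds$labels[i] != ds$labels[j]) {
      maj_member <- if (ds$labels[i] == before$majority) i else j
      del <- c(del, maj_member)
    }
  }
  del <- sort(unique(del))
  keep <- setdiff(seq_len(ds$n), del)
  out <- labeled_dataset(ds$features[keep, , drop = FALSE], ds$labels[keep],
                         positive_class = ds$positive_class,
                         label_name = ds$label_name)
  new_resampled(out, rep("original", length(keep)), del, before, "tomek_link",
                cfg)
}

## Compose SMOTE with an editing stage, keeping provenance coherent:
## origin tags survive and deleted indices refer to the post-SMOTE dataset.
hybrid_resample <- function(ds, cfg, edit_fun, method, edit_default) {
  s <- smote(ds, cfg)
  ecfg <- cfg
  if (is.null(ecfg$edit_target)) ecfg$edit_target <- edit_default
  e <- edit_fun(s$dataset, ecfg)
  keep <- setdiff(seq_len(s$dataset$n), e$deleted_original_indices)
  new_resampled(e$dataset, s$origin[keep], e$deleted_original_indices,
                class_counts(ds), method, cfg, e$warnings)
}

#' SMOTE-ENN hybrid resampling
#'
#' First balances the classes with [smote()], then runs an [enn()] editing
#' pass over the over-sampled dataset with both classes eligible for
#' deletion, so both noisy originals and noisy synthetic rows are removed.
#' Both class counts may end below the input counts.
#'
#' @inheritParams smote
#' @return A `resampled_dataset`; `deleted_original_indices` refer to rows of
#'   the intermediate post-SMOTE dataset, and `origin` tags mark which
#'   surviving rows are synthetic.
#' @export
smote_enn <- function(ds, cfg = resampler_config()) {
  hybrid_resample(ds, cfg, enn, "smote_enn", "both_classes")
}

#' SMOTE-Tomek hybrid resampling
#'
#' [smote()] followed by [tomek_link()] removal on the over-sampled dataset.
#'
#' @inheritParams smote
#' @return A `resampled_dataset` with provenance as in [smote_enn()].
#' @export
smote_tomek <- function(ds, cfg = resampler_config()) {
  hybrid_resample(ds, cfg, tomek_link, "smote_tomek", "both_classes")
}

#' Write a resampled dataset with its provenance sidecar
#'
#' The dataset is written as CSV ([write_dataset_csv()]); provenance (method,
#' config echo, before/after counts, synthetic and deleted row indices) goes
#' to a JSON sidecar next to it.
#'
#' @param rs A `resampled_dataset`.
#' @param csv_path Output CSV path.
#' @param json_path Sidecar path; defaults to `csv_path` with a `.json`
#'   extension.
#' @return Invisibly, `c(csv_path, json_path)`.
#' @export
write_resampled <- function(rs, csv_path,
                            json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(rs, "resampled_dataset"))
  write_dataset_csv(rs$dataset, csv_path)
  cfg <- rs$config
  side <- list(method = rs$method,
               config = cfg[!vapply(cfg, is.null, logical(1L))],
               counts_before = rs$counts_before[c("majority", "n_majority",
                                                 "minority", "n_minority")],
               counts_after = rs$counts_after[c("majority", "n_majority",
                                                "minority", "n_minority")],
               synthetic_row_indices = which(rs$origin == "synthetic"),
               deleted_original_indices = rs$deleted_original_indices,
               warnings = rs$warnings)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
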