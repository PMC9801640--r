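new_ensemble <- function(members, weights, rule, prototype, meta = list()) {
  structure(list(members = members, weights = weights, rule = rule,
                 positive_class = prototype$positive_class,
                 classes = prototype$classes, p = prototype$p,
                 feature_names = prototype$feature_names, meta = meta),
            class = "ensemble_model")
}

tree_params_defaults <- function(params) {
  defaults <- list(max_depth = 10L, min_samples_leaf = 1L)
  defaults[names(params)] <- params
  defaults
}

#' Train a bagging ensemble of decision trees
#'
#' Draws `T` bootstrap resamples of size `n` (with replacement), trains one
#' tree per resample, and predicts by unweighted majority vote.
#'
#' @param ds A [labeled_dataset()].
#' @param T Ensemble size.
#' @param params Named list of tree hyperparameters
#'   (`max_depth`, `min_samples_leaf`).
#' @param seed Integer seed for the bootstrap draws.
#' @param bootstrap Diagnostic switch; `FALSE` trains every member on the full
#'   dataset, so `T = 1` reduces to a plain tree.
#' @return An object of class `ensemble_model`.
#' @export
train_bagging <- function(ds, T = 100L, params = list(), seed = NULL,
                          bootstrap = TRUE) {
  train_bootstrap_ensemble(ds, T, params, seed, bootstrap, m = NULL,
                           rule = "bagging")
}

#' Train a random forest
#'
#' Bagging's bootstrap plus a random `m`-subset of features considered at
#' every split (default `ceiling(sqrt(p))`); unweighted majority vote.
#'
#' @inheritParams train_bagging
#' @param m Features considered per split.
#' @return An object of class `ensemble_model`.
#' @export
train_random_forest <- function(ds, T = 100L, m = ceiling(sqrt(ds$p)),
                                params = list(), seed = NULL,
                                bootstrap = TRUE) {
  m <- as.integer(m)
  if (m < 1L || m > ds$p) stop("m must be in 1..p", call. = FALSE)
  train_bootstrap_ensemble(ds, T, params, seed, bootstrap, m = m,
                           rule = "random_forest")
}

train_bootstrap_ensemble <- function(ds, T, params, seed, bootstrap, m, rule) {
  stopifnot(inherits(ds, "labeled_dataset"), T >= 1L)
  pr <- tree_params_defaults(params)
  members <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, rule), {
    lapply(seq_len(T), function(t) {
      idx <- if (bootstrap) sample.int(ds$n, ds$n, replace = TRUE)
             else seq_len(ds$n)
      sub <- labeled_dataset(ds$features[idx, , drop = FALSE], ds$labels[idx],
                             positive_class = if (ds$positive_class %in% ds$labels[idx])
                               ds$positive_class else NULL,
                             label_name = ds$label_name)
      ## feature-subset draws (when m < p) come from this same seeded stream
      build_tree(sub, pr$max_depth, as.integer(pr$min_samples_leaf),
                 if (is.null(m)) sub$p else m,
                 rep(1 / sub$n, sub$n))
    })
  })
  proto <- list(positive_class = ds$positive_class,
                classes = sort(unique(ds$labels)), p = ds$p,
                feature_names = ds$feature_names)
  new_ensemble(members, rep(1, T), rule, proto,
               meta = list(T = T, bootstrap = bootstrap, m = m, params = pr,
                           seed = seed))
}

#' Train an AdaBoost.M1 ensemble of decision trees
#'
#' Row weights start uniform at `1/n`. Round `t` trains a weighted tree,
#' computes the weighted error `eps_t`, sets `beta_t = eps_t / (1 - eps_t)`,
#' multiplies misclassified rows' weights by `1 / beta_t`, renormalises, and
#' gives the member vote weight `log(1 / beta_t)`. A perfect round
#' (`eps_t = 0`) is kept with a capped large vote weight and training stops;
#' a round with `eps_t >= 0.5` is discarded and training stops — at the first
#' round this leaves a flagged majority-class predictor.
#'
#' @inheritParams train_bagging
#' @return An object of class `ensemble_model`; `meta$rounds` records per-round
#'   `eps` and `beta`, and `meta$degenerate` flags the majority-class fallback.
#' @export
train_adaboost <- function(ds, T = 100L, params = list(), seed = NULL) {
  stopifnot(inherits(ds, "labeled_dataset"), T >= 1L)
  pr <- tree_params_defaults(params)
  w <- rep(1 / ds$n, ds$n)
  members <- list(); alphas <- numeric(0)
  rounds <- data.frame(eps = numeric(0), beta = numeric(0))
  w_next <- list()                      # row-weight vector after each update
  cap <- log(1 / 1e-10)                 # vote weight of an error-free member
  degenerate <- FALSE
  for (t in seq_len(T)) {
    tree <- build_tree(ds, pr$max_depth, as.integer(pr$min_samples_leaf),
                       ds$p, w)
    pred <- predict(tree, ds$features, type = "class")
    mis <- pred != ds$labels
    eps <- sum(w[mis])
    if (eps == 0) {
      members <- c(members, list(tree)); alphas <- c(alphas, cap)
      rounds <- rbind(rounds, data.frame(eps = eps, beta = 0))
      break
    }
    if (eps >= 0.5) {
      if (t == 1L) degenerate <- TRUE
      break
    }
    beta <- eps / (1 - eps)
    members <- c(members, list(tree)); alphas <- c(alphas, log(1 / beta))
    rounds <- rbind(rounds, data.frame(eps = eps, beta = beta))
    w[mis] <- w[mis] / beta
    w <- w / sum(w)
    w_next[[length(w_next) + 1L]] <- w
  }
  proto <- list(positive_class = ds$positive_class,
                classes = sort(unique(ds$labels)), p = ds$p,
                feature_names = ds$feature_names)
  if (length(members) == 0L) {
    ## best-effort constant predictor for the degenerate first round
    cc <- class_counts(ds)
    leaf <- structure(list(nodes = list(list(
      leaf = TRUE, pred = cc$majority,
      pos_frac = as.numeric(cc$majority == ds$positive_class),
      n = ds$n, n_pos = sum(ds$labels == ds$positive_class),
      n_neg = sum(ds$labels != ds$positive_class))), root = 1L,
      positive_class = ds$positive_class, classes = proto$classes,
      feature_names = ds$feature_names, p = ds$p,
      params = list(max_depth = 0L, min_samples_leaf = 1L, m = ds$p)),
      class = "tree_model")
    members <- list(leaf); alphas <- 1
  }
  rounds$w_next <- w_next[seq_len(nrow(rounds))]
  new_ensemble(members, alphas, "adaboost", proto,
               meta = list(T = T, params = pr, seed = seed, rounds = rounds,
                           degenerate = degenerate))
}

#' Predict from an ensemble
#'
#' The score is the weighted share of member votes for the positive class;
#' the label is the weighted-vote argmax, with exact ties broken toward the
#' positive class (so sensitivity is never silently sacrificed).
#'
#' @param object An `ensemble_model`.
#' @param newdata Feature matrix, data frame, single row, or
#'   [labeled_dataset()].
#' @param type `"class"`, `"score"`, or `"both"`.
#' @param ... Unused.
#' @return Labels, positive-class scores in \[0, 1\], or a data frame.
#' @export
predict.ensemble_model <- function(object, newdata,
                                   type = c("class", "score", "both"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata, object$p)
  votes <- vapply(object$members,
                  function(mb) predict(mb, X, type = "class") ==
                    object$positive_class,
                  logical(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  score <- as.numeric(votes %*% object$weights) / sum(object$weights)
  neg <- setdiff(object$classes, object$positive_class)
  if (length(neg) == 0L) neg <- object$positive_class
  pred <- ifelse(score >= 0.5, object$positive_class, neg[1L])
  switch(type, class = pred, score = score,
         both = data.frame(class = pred, score = score,
                           stringsAsFactors = FALSE))
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> rule = ", x$rule, ", T = ", length(x$members),
      ", positive class = ", x$positive_class, "\n", sep = "")
  if (isTRUE(x$meta$degenerate))
    cat("  degenerate: majority-class fallback (first round eps >= 0.5)\n")
  invisible(x)
}

## ---- JSON serialisation ----------------------------------------------------

tree_to_list <- function(tr) {
  list(nodes = tr$nodes, root = tr$root, positive_class = tr$positive_class,
       classes = tr$classes, feature_names = tr$feature_names, p = tr$p,
       params = tr$params)
}

list_to_tree <- function(x) {
  nodes <- lapply(x$nodes, function(nd) {
    nd$leaf <- isTRUE(nd$leaf)
    if (!nd$leaf) {
      nd$feature <- as.integer(nd$feature)
      nd$left <- as.integer(nd$left); nd$right <- as.integer(nd$right)
    }
    nd
  })
  structure(list(nodes = nodes, root = as.integer(x$root),
                 positive_class = x$positive_class,
                 classes = unlist(x$classes),
                 feature_names = unlist(x$feature_names),
                 p = as.integer(x$p), params = x$params),
            class = "tree_model")
}

#' Serialise a model to JSON
#'
#' Writes a tree or ensemble (nodes, thresholds, vote weights, config echo)
#' as a JSON document; [read_model_json()] restores a model giving identical
#' predictions.
#'
#' @param model A `tree_model` or `ensemble_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  doc <- if (inherits(model, "tree_model")) {
    c(list(kind = "tree"), tree_to_list(model))
  } else if (inherits(model, "ensemble_model")) {
    list(kind = "ensemble", rule = model$rule,
         members = lapply(model$members, tree_to_list),
         weights = model$weights, positive_class = model$positive_class,
         classes = model$classes, feature_names = model$feature_names,
         p = model$p,
         meta = model$meta[setdiff(names(model$meta), "rounds")])
  } else stop("not a model", call. = FALSE)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Restore a model written by [write_model_json()]
#'
#' @param path JSON file path.
#' @return A `tree_model` or `ensemble_model`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (identical(doc$kind, "tree")) return(list_to_tree(doc))
  members <- lapply(doc$members, list_to_tree)
  structure(list(members = members, weights = as.numeric(unlist(doc$weights)),
                 rule = doc$rule, positive_class = doc$positive_class,
                 classes = unlist(doc$classes),
                 feature_names = unlist(doc$feature_names),
                 p = as.integer(doc$p), meta = doc$meta),
            class = "ensemble_model")
}
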