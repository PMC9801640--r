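#' Gini impurity of a label vector
#'
#' `1 - sum(p_c^2)` over the (optionally weighted) class proportions: 0 for a
#' pure node, 0.5 for a balanced binary node.
#'
#' @param labels Vector of class labels.
#' @param weights Optional non-negative case weights.
#' @return The impurity, a number in \[0, 0.5\] for two classes.
#' @export
gini_impurity <- function(labels, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(labels))
  w <- tapply(weights, labels, sum)
  p <- w / sum(w)
  1 - sum(p^2)
}

#' Train a CART-style binary decision tree
#'
#' Greedy top-down induction minimising weighted Gini impurity. Splits are
#' axis-aligned with thresholds at midpoints of adjacent observed values;
#' induction stops at `max_depth`, at a pure node, when a split cannot leave
#' `min_samples_leaf` rows on each side, or when no split strictly reduces
#' impurity (so identical feature rows with mixed labels yield a majority
#' leaf). When `m < p`, each split considers a random `m`-subset of features,
#' drawn from the current RNG stream. Candidate-feature ties break toward the
#' lower feature index, threshold ties toward the smaller threshold.
#'
#' @param ds A [labeled_dataset()].
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_samples_leaf Minimum rows routed to each leaf.
#' @param m Features considered per split; `NULL` means all `p`.
#' @param sample_weights Optional non-negative per-row weights (used directly
#'   in the impurity computation, not via resampling).
#' @param seed Optional seed; only consulted when `m < p`.
#' @return An object of class `tree_model`.
#' @export
train_tree <- function(ds, max_depth = 10L, min_samples_leaf = 1L, m = NULL,
                       sample_weights = NULL, seed = NULL) {
  stopifnot(inherits(ds, "labeled_dataset"), ds$n >= 1L)
  if (is.null(sample_weights)) sample_weights <- rep(1 / ds$n, ds$n)
  if (any(sample_weights < 0) || sum(sample_weights) <= 0)
    stop("sample weights must be non-negative and not all zero", call. = FALSE)
  if (is.null(m)) m <- ds$p
  m <- as.integer(m)
  if (m < 1L || m > ds$p) stop("m must be in 1..p", call. = FALSE)
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, "tree"),
            build_tree(ds, max_depth, as.integer(min_samples_leaf), m,
                       sample_weights))
}

build_tree <- function(ds, max_depth, min_leaf, m, w) {
  X <- ds$features
  y <- as.integer(ds$labels == ds$positive_class)   # 1 = positive class
  nodes <- new.env(parent = emptyenv())
  nodes$tab <- list()
  add_node <- function(rec) {
    nodes$tab[[length(nodes$tab) + 1L]] <- rec
    length(nodes$tab)
  }
  neg_label <- {
    lv <- sort(unique(ds$labels))
    if (length(lv) == 2L) setdiff(lv, ds$positive_class) else ds$positive_class
  }

  grow <- function(idx, depth) {
    wi <- w[idx]; yi <- y[idx]
    W <- sum(wi); wpos <- sum(wi[yi == 1L])
    pos_frac <- if (W > 0) wpos / W else 0
    ## vote-tie inside a leaf breaks toward the positive class
    pred <- if (pos_frac >= 0.5) ds$positive_class else neg_label
    make_leaf <- function() add_node(list(
      leaf = TRUE, pred = pred, pos_frac = pos_frac,
      n = length(idx), n_pos = sum(yi == 1L), n_neg = sum(yi == 0L)))
    if (depth >= max_depth || length(idx) < 2L * min_leaf ||
        all(yi == yi[1L]))
      return(make_leaf())

    cand <- if (m < ncol(X)) sort(sample.int(ncol(X), m)) else seq_len(ncol(X))
    node_imp <- 1 - (wpos / W)^2 - ((W - wpos) / W)^2
    best <- list(gain = 1e-12, feature = NA_integer_, threshold = NA_real_)
    for (j in cand) {
      xj <- X[idx, j]
      o <- order(xj)
      xs <- xj[o]; ws <- wi[o]; ys <- yi[o]
      nidx <- length(idx)
      cut <- which(xs[-nidx] < xs[-1L])               # distinct-value boundaries
      cut <- cut[cut >= min_leaf & (nidx - cut) >= min_leaf]
      if (length(cut) == 0L) next
      cw  <- cumsum(ws)
      cwp <- cumsum(ws * ys)
      wl <- cw[cut]; wpl <- cwp[cut]
      wr <- W - wl;  wpr <- wpos - wpl
      gl <- 1 - (wpl / wl)^2 - ((wl - wpl) / wl)^2
      gr <- 1 - (wpr / wr)^2 - ((wr - wpr) / wr)^2
      gl[wl == 0] <- 0; gr[wr == 0] <- 0
      child_imp <- (wl * gl + wr * gr) / W
      gain <- node_imp - child_imp
      b <- which.max(gain)                             # first max: smaller threshold
      if (gain[b] > best$gain) {
        best <- list(gain = gain[b], feature = j,
                     threshold = (xs[cut[b]] + xs[cut[b] + 1L]) / 2)
      }
    }
    if (is.na(best$feature)) return(make_leaf())
    left_rows <- idx[X[idx, best$feature] <= best$threshold]
    right_rows <- idx[X[idx, best$feature] > best$threshold]
    id <- add_node(list(leaf = FALSE))                 # reserve slot, fill below
    lid <- grow(left_rows, depth + 1L)
    rid <- grow(right_rows, depth + 1L)
    nodes$tab[[id]] <- list(leaf = FALSE, feature = best$feature,
                            threshold = best$threshold, left = lid, right = rid,
                            n = length(idx))
    id
  }
  root <- grow(seq_len(ds$n), 0L)
  structure(list(nodes = nodes$tab, root = root,
                 positive_class = ds$positive_class,
                 classes = sort(unique(ds$labels)),
                 feature_names = ds$feature_names, p = ds$p,
                 params = list(max_depth = max_depth,
                               min_samples_leaf = min_leaf, m = m)),
            class = "tree_model")
}

route_rows <- function(model, X) {
  ## returns the leaf node id for each row of X
  out <- integer(nrow(X))
  assign_node <- function(rows, id) {
    nd <- model$nodes[[id]]
    if (isTRUE(nd$leaf)) { out[rows] <<- id; return(invisible()) }
    go_left <- X[rows, nd$feature] <= nd$threshold
    if (any(go_left)) assign_node(rows[go_left], nd$left)
    if (any(!go_left)) assign_node(rows[!go_left], nd$right)
  }
  if (nrow(X) > 0L) assign_node(seq_len(nrow(X)), model$root)
  out
}

as_feature_matrix <- function(newdata, p) {
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$features
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != p)
    stop("newdata has ", ncol(newdata), " features; model expects ", p,
         call. = FALSE)
  newdata
}

#' Predict from a decision tree
#'
#' @param object A `tree_model`.
#' @param newdata Feature matrix, data frame, single row, or
#'   [labeled_dataset()].
#' @param type `"class"` for predicted labels, `"score"` for the leaf's
#'   positive-class fraction, `"both"` for a data frame with both.
#' @param ... Unused.
#' @return Labels, scores, or a data frame, one entry per row.
#' @export
predict.tree_model <- function(object, newdata,
                               type = c("class", "score", "both"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata, object$p)
  leaf_ids <- route_rows(object, X)
  pred <- vapply(leaf_ids, function(i) object$nodes[[i]]$pred, character(1L))
  score <- vapply(leaf_ids, function(i) object$nodes[[i]]$pos_frac, numeric(1L))
  switch(type, class = pred, score = score,
         both = data.frame(class = pred, score = score,
                           stringsAsFactors = FALSE))
}

#' @export
print.tree_model <- function(x, ...) {
  n_leaf <- sum(vapply(x$nodes, function(nd) isTRUE(nd$leaf), logical(1L)))
  cat("<tree_model> ", length(x$nodes), " nodes (", n_leaf, " leaves), ",
      "max_depth = ", x$params$max_depth, ", m = ", x$params$m, "/", x$p,
      "\n", sep = "")
  invisible(x)
}
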