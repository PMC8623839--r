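# Mutable CART decision trees and random forests.
#
# A tree is a flat node table (node 1 = root): `feature` (1-based split
# column, 0 marks a leaf), `threshold`, `left`/`right` (1-based child ids, 0
# at leaves) and `counts`, an `n_nodes x K` matrix of training class counts.
# The routing rule is `x[feature] <= threshold` goes left, everywhere.  Leaf
# prediction is the argmax of the counts, ties to the lowest class index.
# Trees are plain R lists, so the SER/STRUT surgery operates on copies and
# never mutates the source model.

#' Construct a decision tree from a node table
#'
#' @param feature Integer vector of 1-based split columns; 0 marks a leaf.
#' @param threshold Numeric split values (ignored at leaves).
#' @param left,right Integer 1-based child node ids; 0 at leaves.
#' @param counts `n_nodes x K` matrix of per-node class counts.
#' @param classes Class labels (e.g. `0:G`), one per counts column.
#' @return An object of class `emg_tree`.
#' @export
new_emg_tree <- function(feature, threshold, left, right, counts, classes) {
  counts <- as.matrix(counts)
  n <- length(feature)
  stopifnot(length(threshold) == n, length(left) == n, length(right) == n,
            nrow(counts) == n, ncol(counts) == length(classes))
  structure(list(feature = as.integer(feature),
                 threshold = as.numeric(threshold),
                 left = as.integer(left), right = as.integer(right),
                 counts = counts, classes = classes),
            class = "emg_tree")
}

tree_from_cpp <- function(lst, classes) {
  new_emg_tree(lst$feature, lst$threshold, lst$left, lst$right, lst$counts,
               classes)
}

#' @export
print.emg_tree <- function(x, ...) {
  n_leaf <- sum(x$feature == 0L)
  cat(sprintf("decision tree: %d nodes (%d leaves), %d classes\n",
              length(x$feature), n_leaf, length(x$classes)))
  invisible(x)
}

# Map labels onto 0-based class indices, validating membership.
class_index <- function(y, classes) {
  idx <- match(y, classes) - 1L
  if (anyNA(idx)) stop("labels outside the model's class set")
  idx
}

#' Induce a CART decision tree
#'
#' CART with Gini impurity: at each node, candidate thresholds are the
#' midpoints between consecutive distinct sorted values of each considered
#' feature, the split maximizing the impurity decrease is taken (ties to the
#' lower feature index, then the smaller threshold), and growth continues
#' until nodes are pure or no improving split exists (no depth cap).  Every
#' node stores its training class counts.  When `mtry < ncol(X)` the features
#' considered at each node are sampled through R's RNG, so the result is
#' deterministic given the RNG state.
#'
#' @param X Numeric feature matrix.
#' @param y Label vector (values in `classes`).
#' @param classes Class label set; defaults to the sorted unique labels.
#' @param mtry Features considered per node; default all.
#' @param rows Training row indices (duplicates allowed, e.g. a bootstrap
#'   resample).
#' @return An object of class `emg_tree`.
#' @export
induce_tree <- function(X, y, classes = sort(unique(y)), mtry = ncol(X),
                        rows = seq_len(nrow(X))) {
  X <- as.matrix(X)
  if (nrow(X) == 0 || length(rows) == 0) stop("cannot induce a tree on empty data")
  stopifnot(length(y) == nrow(X))
  yi <- class_index(y, classes)
  lst <- cpp_induce_tree(X, yi, length(classes), as.integer(mtry),
                         as.integer(rows))
  tree_from_cpp(lst, classes)
}

#' Train a random forest
#'
#' A collection of CART trees (default 100), each induced on a bootstrap
#' resample of the rows with `sqrt(d)` features sampled per node, combined by
#' simple majority voting.  Deterministic in `seed`.
#'
#' @param X Numeric feature matrix.
#' @param y Label vector.
#' @param classes Class label set (defaults to the sorted unique labels);
#'   supply explicitly when some class may be absent from `y`.
#' @param n_trees Number of trees (the experiment protocols fix 100).
#' @param mtry Features sampled per node; default `floor(sqrt(d))`.
#' @param bootstrap Resample rows with replacement per tree.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `emg_forest`.
#' @examples
#' X <- matrix(rnorm(60), 30, 2)
#' y <- rep(0:1, each = 15)
#' X[y == 1, 1] <- X[y == 1, 1] + 4
#' fit <- train_forest(X, y, n_trees = 11, seed = 1)
#' table(predict(fit, X), y)
#' @export
train_forest <- function(X, y, classes = sort(unique(y)), n_trees = 100,
                         mtry = max(1L, base::floor(sqrt(ncol(X)))),
                         bootstrap = TRUE, seed = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("cannot train a forest on empty data")
  yi <- class_index(y, classes)
  build <- function() {
    lst <- cpp_train_forest(X, yi, length(classes), as.integer(mtry),
                            as.integer(n_trees), isTRUE(bootstrap))
    lapply(lst, tree_from_cpp, classes = classes)
  }
  trees <- if (is.null(seed)) build() else with_local_seed(seed, build())
  structure(list(trees = trees, classes = classes,
                 n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 bootstrap = bootstrap, seed = seed, d = ncol(X)),
            class = "emg_forest")
}

#' @export
print.emg_forest <- function(x, ...) {
  nodes <- vapply(x$trees, function(t) length(t$feature), integer(1))
  cat(sprintf(
    "random forest: %d trees (%.0f nodes on average), %d features, classes {%s}\n",
    length(x$trees), mean(nodes), x$d, paste(x$classes, collapse = ", ")))
  invisible(x)
}

tree_to_cpp <- function(tree) {
  unclass(tree)[c("feature", "threshold", "left", "right", "counts")]
}

#' Predict classes with a decision tree
#'
#' @param object An `emg_tree`.
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return Predicted labels (leaf counts argmax, ties to the lowest class).
#' @export
predict.emg_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  object$classes[cpp_tree_predict(tree_to_cpp(object), newdata) + 1L]
}

#' Predict classes with a random forest
#'
#' Each tree votes its leaf argmax; the forest returns the simple majority,
#' with ties resolved to the lowest class index.
#'
#' @param object An `emg_forest`.
#' @param newdata Numeric feature matrix with `object$d` columns.
#' @param type `"class"` for majority labels, `"votes"` for the
#'   `rows x trees` matrix of per-tree labels.
#' @param ... Unused.
#' @return Predicted labels, or the vote matrix.
#' @export
predict.emg_forest <- function(object, newdata, type = c("class", "votes"),
                               ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d) {
    stop("newdata has ", ncol(newdata), " features; the forest was trained on ",
         object$d)
  }
  votes <- cpp_forest_votes(lapply(object$trees, tree_to_cpp), newdata)
  if (type == "votes") {
    return(matrix(object$classes[votes + 1L], nrow(votes), ncol(votes)))
  }
  maj <- cpp_majority_vote(votes, length(object$classes))
  object$classes[maj + 1L]
}

#' Route samples through a tree
#'
#' Returns, for every node, the set of rows of `X` reaching it: a row goes
#' left iff `x[feature] <= threshold`.  The root receives all rows; each row
#' reaches exactly one leaf, and an internal node's membership is the disjoint
#' union of its children's.
#'
#' @param tree An `emg_tree`.
#' @param X Numeric feature matrix.
#' @return A list of integer row-index vectors, one per node id.
#' @export
route <- function(tree, X) {
  X <- as.matrix(X)
  leaf <- cpp_tree_leaf(tree_to_cpp(tree), X)
  n_nodes <- length(tree$feature)
  members <- vector("list", n_nodes)
  for (v in seq_len(n_nodes)) members[[v]] <- integer(0)
  sp <- split(seq_len(nrow(X)), leaf)
  for (nm in names(sp)) members[[as.integer(nm)]] <- sp[[nm]]
  # children always carry larger ids than their parent (DFS construction)
  for (v in rev(seq_len(n_nodes))) {
    if (tree$feature[v] != 0L) {
      members[[v]] <- sort(c(members[[tree$left[v]]],
                             members[[tree$right[v]]]))
    }
  }
  members
}

#' Serialize a forest to a file
#'
#' The forest is stored as a plain named list of per-tree node tables
#' (feature, threshold, left, right, counts) plus the class set and training
#' metadata, so a round trip reproduces identical predictions.
#'
#' @param forest An `emg_forest`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forest <- function(forest, path) {
  stopifnot(inherits(forest, "emg_forest"))
  payload <- list(
    container = "emgadapt_forest", version = 1L,
    classes = forest$classes, n_trees = forest$n_trees, mtry = forest$mtry,
    bootstrap = forest$bootstrap, seed = forest$seed, d = forest$d,
    trees = lapply(forest$trees, tree_to_cpp)
  )
  saveRDS(payload, path)
  invisible(path)
}

#' Read a forest written by [write_forest()]
#'
#' @param path File path.
#' @return The `emg_forest`.
#' @export
read_forest <- function(path) {
  p <- readRDS(path)
  if (!identical(p$container, "emgadapt_forest")) {
    stop("not an emgadapt forest container: ", path)
  }
  trees <- lapply(p$trees, tree_from_cpp, classes = p$classes)
  structure(list(trees = trees, classes = p$classes, n_trees = p$n_trees,
                 mtry = p$mtry, bootstrap = p$bootstrap, seed = p$seed,
                 d = p$d),
            class = "emg_forest")
}
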