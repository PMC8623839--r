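# Decision-forest domain adaptation: SER (structure expansion/reduction),
# STRUT (threshold structure transfer) and their majority-vote combinations.
# Both tree operations are pure: they return new trees and leave the source
# model untouched.

#' Adapt a tree to target data by structure expansion/reduction (SER)
#'
#' Expansion: at every source leaf, a full CART tree (all features, no
#' bootstrap) is induced on the target rows reaching that leaf and grafted in
#' its place.  Reduction (bottom-up): at every internal node reached by target
#' rows, the subtree error `E_S` (misclassified fraction of the node's target
#' rows under the current subtree) is compared with the leaf error `E_L`
#' (misclassified fraction if the node were collapsed to a leaf predicting the
#' target-majority class); if `E_S > E_L` (strictly -- ties keep the subtree)
#' the subtree is pruned into a leaf.  All leaf counts at reached leaves are
#' replaced by the target empirical distribution; leaves no target row reaches
#' retain their source counts.
#'
#' @param tree An `emg_tree` induced on source data.
#' @param X_T,y_T Target training rows and labels.
#' @return The adapted `emg_tree`; the input is not modified.
#' @export
ser_tree <- function(tree, X_T, y_T) {
  X_T <- as.matrix(X_T)
  if (nrow(X_T) == 0) stop("SER needs a non-empty target set at the root")
  yi <- class_index(y_T, tree$classes)
  lst <- cpp_ser_tree(tree_to_cpp(tree), X_T, yi, length(tree$classes))
  tree_from_cpp(lst, tree$classes)
}

#' Adapt a tree to target data by structure transfer (STRUT)
#'
#' Top-down, every internal node keeps its feature but discards its numeric
#' threshold: a new threshold is selected on the target rows reaching the node
#' by [select_threshold()] (divergence gain maximized among information-gain
#' local maxima, against the source child distributions).  Parents are
#' re-thresholded before their children are visited with the re-routed rows.
#' A branch that cannot be reached in the target domain is pruned: when the
#' rows at a node cannot be separated on its feature (all values identical),
#' the node is contracted to the child selected by its source threshold and
#' the unreachable sibling subtree is dropped.  Leaf counts come from the
#' target data.
#'
#' @param tree An `emg_tree` induced on source data.
#' @param X_T,y_T Target training rows and labels.
#' @param min_ig_frac Admissibility floor passed to [select_threshold()].
#' @return The adapted `emg_tree` (input unmodified), with attributes
#'   `diag_ig` and `diag_ig_max`: per surviving node, the information gain of
#'   the selected threshold and the maximal information gain over all
#'   candidates at that node (`NA` at leaves).
#' @export
strut_tree <- function(tree, X_T, y_T, min_ig_frac = 0.5) {
  X_T <- as.matrix(X_T)
  if (nrow(X_T) == 0) stop("STRUT needs a non-empty target set at the root")
  yi <- class_index(y_T, tree$classes)
  lst <- cpp_strut_tree(tree_to_cpp(tree), X_T, yi, length(tree$classes),
                        min_ig_frac)
  out <- tree_from_cpp(lst, tree$classes)
  attr(out, "diag_ig") <- lst$diag_ig
  attr(out, "diag_ig_max") <- lst$diag_ig_max
  out
}

#' STRUT threshold selection for one node
#'
#' Candidate thresholds are the midpoints of consecutive distinct sorted
#' values.  The information gain `IG` (Gini impurity decrease, matching tree
#' induction) is computed at each candidate; candidates that are IG local
#' maxima (IG at least that of both neighbours, endpoints compared to their
#' single neighbour) -- the discrete version of the epsilon-neighborhood
#' condition -- and whose IG retains at least `min_ig_frac` of the node's
#' maximal IG are admissible.  (On a piecewise-constant IG curve, tail
#' candidates splitting off a handful of rows are formally local maxima but
#' carry no information; the floor keeps the divergence criterion arbitrating
#' among informative thresholds only.)  Among admissible candidates the
#' returned threshold maximizes the divergence gain
#' `DG = 1 - (nL/n) JSD2(QL, QhatL) - (nR/n) JSD2(QR, QhatR)`,
#' where `QhatL`/`QhatR` are the induced target child label distributions and
#' `JSD2` is the base-2 Jensen-Shannon divergence (so `DG` is in `[0, 1]`,
#' reaching 1 when the induced distributions equal the originals).  Ties go to
#' the smallest threshold.
#'
#' @param values Numeric feature values of the target rows at the node (at
#'   least two distinct values).
#' @param labels Class indices in `0 .. K-1` paired with `values`.
#' @param QL,QR Original (source) left/right child label distributions,
#'   length-`K` probability vectors.
#' @param min_ig_frac Fraction of the node's maximal IG an admissible
#'   candidate must retain (in `[0, 1]`; 0 reduces admissibility to the bare
#'   local-maximum condition).
#' @return A list of class `threshold_search`: `threshold`, `ig`, `dg`,
#'   `ig_max`, plus the full candidate trace (`candidates`, `candidate_ig`,
#'   `candidate_dg`, logical `admissible`).
#' @export
select_threshold <- function(values, labels, QL, QR, min_ig_frac = 0.5) {
  stopifnot(length(values) == length(labels), length(QL) == length(QR),
            min_ig_frac >= 0, min_ig_frac <= 1)
  K <- length(QL)
  if (any(labels < 0 | labels >= K)) stop("labels must be indices in 0..K-1")
  res <- cpp_select_threshold(as.numeric(values), as.integer(labels),
                              as.integer(K), as.numeric(QL), as.numeric(QR),
                              min_ig_frac)
  if (!isTRUE(res$ok)) {
    stop("all values identical: no candidate threshold (node unreachable)")
  }
  structure(list(threshold = res$threshold, ig = res$ig, dg = res$dg,
                 ig_max = res$ig_max, candidates = res$candidates,
                 candidate_ig = res$candidate_ig,
                 candidate_dg = res$candidate_dg,
                 admissible = as.logical(res$admissible)),
            class = "threshold_search")
}

adapt_forest <- function(forest, X_T, y_T, tree_fun) {
  stopifnot(inherits(forest, "emg_forest"))
  X_T <- as.matrix(X_T)
  if (ncol(X_T) != forest$d) stop("target features do not match the forest")
  trees <- lapply(forest$trees, tree_fun, X_T = X_T, y_T = y_T)
  out <- forest
  out$trees <- trees
  out
}

#' Adapt every tree of a forest with SER
#'
#' Applies [ser_tree()] independently to each tree; the output has the same
#' number of trees and the source forest is left unmodified.
#'
#' @param forest Source `emg_forest`.
#' @param X_T,y_T Target training rows and labels.
#' @return The adapted `emg_forest`.
#' @export
ser_forest <- function(forest, X_T, y_T) {
  adapt_forest(forest, X_T, y_T, ser_tree)
}

#' Adapt every tree of a forest with STRUT
#'
#' Applies [strut_tree()] independently to each tree; the output has the same
#' number of trees and the source forest is left unmodified.
#'
#' @param forest Source `emg_forest`.
#' @param X_T,y_T Target training rows and labels.
#' @param min_ig_frac Admissibility floor passed to [select_threshold()].
#' @return The adapted `emg_forest`.
#' @export
strut_forest <- function(forest, X_T, y_T, min_ig_frac = 0.5) {
  adapt_forest(forest, X_T, y_T, function(tree, X_T, y_T) {
    strut_tree(tree, X_T, y_T, min_ig_frac = min_ig_frac)
  })
}

#' Majority-vote union of two forests
#'
#' The union of all decision trees of both forests, predicting by simple
#' majority voting over every tree with the standard tie rule (lowest class
#' index).  Used for the SER+Target, STRUT+Target and MIX+Target ensembles.
#'
#' @param forest_a,forest_b Forests over the same class set.
#' @return An `emg_forest` with `n_trees = n_a + n_b`.
#' @export
vote_union <- function(forest_a, forest_b) {
  stopifnot(inherits(forest_a, "emg_forest"), inherits(forest_b, "emg_forest"))
  if (!identical(forest_a$classes, forest_b$classes)) {
    stop("forests have different class sets")
  }
  if (forest_a$d != forest_b$d) stop("forests have different feature counts")
  out <- forest_a
  out$trees <- c(forest_a$trees, forest_b$trees)
  out$n_trees <- length(out$trees)
  out$seed <- NULL
  out
}

#' MIX: majority-vote union of the SER and STRUT forests
#'
#' @param forest_ser,forest_strut Adapted forests over the same class set.
#' @return An `emg_forest` with all trees of both (e.g. 200 for two 100-tree
#'   forests).
#' @export
mix_forests <- function(forest_ser, forest_strut) {
  vote_union(forest_ser, forest_strut)
}
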