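#' Binary recursive partitioning for threshold discovery
#'
#' Fits a classification tree of depth at most `max_depth` by exhaustive
#' split search: at every node each candidate split (the midpoints between
#' consecutive distinct values of each feature) is scored by the decrease in
#' Gini impurity, and the best split is taken. Pure nodes and splits with no
#' impurity decrease stop the recursion; leaves are labeled by majority
#' (ties going to the negative class). This is the procedure used to find
#' the operating thresholds of risk predictors such as SFAR and CSI.
#'
#' @param x data.frame of numeric features (typically `sfar` and `csi`).
#' @param labels 0/1 outcomes.
#' @param max_depth maximal tree depth (default 2).
#' @return object of class `"threshold_tree"`: the recursive node structure
#'   plus `features` used. Convert to an ordered-rule model with
#'   [as_ivc_model()].
#' @export
fit_threshold_tree <- function(x, labels, max_depth = 2) {
  x <- as.data.frame(x)
  y <- as_binary(labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  node <- grow_node(x, y, depth = 0L, max_depth = max_depth)
  out <- list(root = node, features = names(x))
  class(out) <- "threshold_tree"
  out
}

gini <- function(y) {
  p <- mean(y)
  2 * p * (1 - p)
}

## best split of one node: exhaustive over features and midpoints
best_split <- function(x, y) {
  n <- length(y)
  g0 <- gini(y)
  best <- NULL
  for (f in sort(names(x))) {      # alphabetical tie-break across features
    v <- x[[f]]
    u <- sort(unique(v))
    if (length(u) < 2L) next
    cuts <- (u[-1L] + u[-length(u)]) / 2
    for (thr in cuts) {
      left <- v <= thr
      nl <- sum(left)
      if (nl == 0L || nl == n) next
      dec <- g0 - (nl * gini(y[left]) + (n - nl) * gini(y[!left])) / n
      if (is.null(best) || dec > best$decrease + 1e-12)
        best <- list(feature = f, threshold = thr, decrease = dec)
    }
  }
  best
}

grow_node <- function(x, y, depth, max_depth) {
  leaf <- function() list(type = "leaf", n = length(y),
                          prob = mean(y),
                          label = as.integer(mean(y) > 0.5))
  if (depth >= max_depth || length(unique(y)) < 2L) return(leaf())
  sp <- best_split(x, y)
  if (is.null(sp) || sp$decrease <= 1e-12) return(leaf())
  left <- x[[sp$feature]] <= sp$threshold
  list(type = "split", feature = sp$feature, threshold = sp$threshold,
       decrease = sp$decrease, n = length(y),
       left = grow_node(x[left, , drop = FALSE], y[left],
                        depth + 1L, max_depth),
       right = grow_node(x[!left, , drop = FALSE], y[!left],
                         depth + 1L, max_depth))
}

#' @export
print.threshold_tree <- function(x, ...) {
  cat("Threshold tree (Gini recursive partition)\n")
  show <- function(node, indent, prefix) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s%s-> %s (n = %d, p = %.3f)\n", pad, prefix,
                  if (node$label == 1) "high risk" else "low risk",
                  node$n, node$prob))
    } else {
      cat(sprintf("%s%s%s <= %g ?\n", pad, prefix, node$feature,
                  node$threshold))
      show(node$left, indent + 1L, "yes: ")
      show(node$right, indent + 1L, "no:  ")
    }
  }
  show(x$root, 0L, "")
  invisible(x)
}

#' @param object a `"threshold_tree"`.
#' @param newdata data.frame with the tree's features.
#' @param type `"class"` (0/1) or `"prob"` (leaf event proportion).
#' @param ... unused.
#' @rdname fit_threshold_tree
#' @export
predict.threshold_tree <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  one <- function(row) {
    node <- object$root
    while (node$type == "split") {
      node <- if (newdata[[node$feature]][row] <= node$threshold) node$left
              else node$right
    }
    if (type == "class") node$label else node$prob
  }
  vapply(seq_len(nrow(newdata)), one, numeric(1))
}

#' Convert a fitted threshold tree into an ordered-rule model
#'
#' Trees whose high-risk leaves hang directly off the split cascade (the
#' common shape when risk is "feature A beyond its threshold, else feature B
#' beyond its threshold") are rewritten exactly as an ordered rule list
#' evaluated first-match-wins, the form used by [classify_risk()]. Trees
#' without that shape (e.g. both children of the root split again on noisy
#' data) are reduced to one `">"` rule per feature at the first threshold
#' the tree uses for it — the natural reading when risk increases in every
#' feature, as it does for SFAR and CSI; such rule sets carry attribute
#' `"exact" = FALSE` because they summarize rather than replicate the tree.
#'
#' @param tree a [fit_threshold_tree()] result.
#' @return an [ivc_model()] with the extracted rules and the tree attached.
#' @export
as_ivc_model <- function(tree) {
  stopifnot(inherits(tree, "threshold_tree"))
  rules <- extract_rule_chain(tree$root, tree$features)
  if (is.null(rules)) {
    rules <- first_thresholds(tree$root)
    attr(rules, "exact") <- FALSE
  }
  ivc_model(rules, tree = tree)
}

## breadth-first: the first threshold each feature is split on
first_thresholds <- function(root) {
  rules <- data.frame(feature = character(0), threshold = numeric(0),
                      direction = character(0))
  queue <- list(root)
  while (length(queue)) {
    node <- queue[[1L]]
    queue <- queue[-1L]
    if (node$type != "split") next
    if (!node$feature %in% rules$feature)
      rules <- rbind(rules, data.frame(feature = node$feature,
                                       threshold = node$threshold,
                                       direction = ">"))
    queue <- c(queue, list(node$left, node$right))
  }
  rules
}

## walk the cascade: at each split, one child must be a leaf; a high-risk
## leaf emits a rule, then recurse into the other child. Returns NULL when
## the tree is not a cascade.
extract_rule_chain <- function(node, features) {
  rules <- data.frame(feature = character(0), threshold = numeric(0),
                      direction = character(0))
  if (node$type == "leaf" && node$label == 1)  # degenerate: everyone high
    return(data.frame(feature = features[1L], threshold = -Inf,
                      direction = ">"))
  while (node$type == "split") {
    lleaf <- node$left$type == "leaf"
    rleaf <- node$right$type == "leaf"
    if (!lleaf && !rleaf) return(NULL)
    if (lleaf && node$left$label == 1 && rleaf && node$right$label == 1) {
      ## both high: any value is high risk; encode as an always-true rule
      rules <- rbind(rules, data.frame(feature = node$feature,
                                       threshold = -Inf, direction = ">"))
      return(rules)
    }
    if (rleaf && node$right$label == 1) {
      rules <- rbind(rules, data.frame(feature = node$feature,
                                       threshold = node$threshold,
                                       direction = ">"))
      node <- if (lleaf) node$left else node$left
    } else if (lleaf && node$left$label == 1) {
      rules <- rbind(rules, data.frame(feature = node$feature,
                                       threshold = node$threshold,
                                       direction = "<="))
      node <- node$right
    } else {
      ## the leaf child is low risk: just descend into the non-leaf child
      node <- if (lleaf) node$right else node$left
      if (lleaf && rleaf) break
    }
  }
  rules
}
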