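#' Train an activity-level decision tree
#'
#' Fits an information-gain decision tree (rpart with the "information" split
#' criterion, minimum leaf size 5, no cost-complexity pruning) on a table of
#' per-window features, then converts it to a portable nested-node structure
#' used for prediction and JSON serialisation. Training is deterministic; the
#' seed is recorded as model metadata.
#'
#' @param features Data frame of per-window features with a `label` factor
#'   column (see [dataset_features()]); at least two classes must be present.
#' @param seed Integer recorded in the model metadata.
#' @param min_leaf Minimum number of observations in any leaf (default 5).
#' @return Object of class `activity_tree`: `tree` (nested nodes), `classes`,
#'   `features`, `seed` and the underlying `rpart` fit.
#' @export
train_tree <- function(features, seed = 1, min_leaf = 5) {
  if (!"label" %in% names(features)) stop("'features' needs a 'label' column")
  features$label <- droplevels(factor(features$label))
  if (nlevels(features$label) < 2)
    stop("training data must contain at least two classes")
  fit <- withr::with_seed(seed, rpart::rpart(
    label ~ ., data = features, method = "class",
    parms = list(split = "information"),
    control = rpart::rpart.control(minbucket = min_leaf,
                                   minsplit = 2 * min_leaf,
                                   cp = 0, xval = 0, maxcompete = 0,
                                   maxsurrogate = 0, usesurrogate = 0)
  ))
  structure(list(tree = rpart_to_nodes(fit, levels(features$label)),
                 classes = levels(features$label),
                 features = setdiff(names(features), "label"),
                 seed = seed, fit = fit),
            class = "activity_tree")
}

# Walk the rpart frame (node ids in rownames; one splits row per internal
# node, in frame order, when competes/surrogates are disabled) into a nested
# list. "lt": left child takes var < threshold; "ge": left takes var >= thr.
rpart_to_nodes <- function(fit, classes) {
  frame <- fit$frame
  ids <- as.integer(rownames(frame))
  internal <- which(frame$var != "<leaf>")
  build <- function(id) {
    r <- match(id, ids)
    if (frame$var[r] == "<leaf>") {
      return(list(leaf = TRUE, class = classes[frame$yval[r]],
                  n = frame$n[r]))
    }
    k <- match(r, internal)
    list(leaf = FALSE,
         var = as.character(frame$var[r]),
         threshold = unname(fit$splits[k, "index"]),
         op = if (fit$splits[k, "ncat"] < 0) "lt" else "ge",
         left = build(2L * id), right = build(2L * id + 1L))
  }
  build(1L)
}

#' Predict activity categories with a portable tree
#'
#' Walks the nested-node structure, so models freshly trained and models
#' loaded back from JSON predict identically.
#'
#' @param model An `activity_tree`.
#' @param newdata Data frame containing the model's feature columns.
#' @return Factor of predicted classes with levels `model$classes`.
#' @export
predict_tree <- function(model, newdata) {
  missing_f <- setdiff(model$features, names(newdata))
  if (length(missing_f) > 0)
    stop("newdata lacks feature columns: ", paste(missing_f, collapse = ", "))
  one <- function(row) {
    node <- model$tree
    while (!isTRUE(node$leaf)) {
      x <- row[[node$var]]
      go_left <- if (node$op == "lt") x < node$threshold else x >= node$threshold
      node <- if (go_left) node$left else node$right
    }
    node$class
  }
  preds <- vapply(seq_len(nrow(newdata)), function(i) one(newdata[i, ]),
                  character(1))
  factor(preds, levels = model$classes)
}

#' Serialise / load an activity tree as JSON
#'
#' The JSON document has fields `format` ("activity-tree/1"), `classes`,
#' `features`, `seed` and `tree`, where `tree` is the nested node structure:
#' internal nodes `{var, threshold, op, left, right}` (op "lt" sends
#' `var < threshold` left, "ge" sends `var >= threshold` left) and leaves
#' `{leaf: true, class, n}`. The underlying rpart fit is not serialised.
#'
#' @param model An `activity_tree`.
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` returns an
#'   `activity_tree`.
#' @export
write_model <- function(model, path) {
  doc <- list(format = "activity-tree/1", classes = model$classes,
              features = model$features, seed = model$seed,
              tree = model$tree)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$format) || doc$format != "activity-tree/1")
    stop("not an activity-tree model file: ", path)
  structure(list(tree = doc$tree,
                 classes = unlist(doc$classes),
                 features = unlist(doc$features),
                 seed = doc$seed, fit = NULL),
            class = "activity_tree")
}

#' @export
print.activity_tree <- function(x, ...) {
  count <- function(node) if (isTRUE(node$leaf)) 1 else
    count(node$left) + count(node$right)
  cat("Activity-level decision tree:", count(x$tree), "leaves,",
      length(x$classes), "classes\n")
  invisible(x)
}

#' Stratified k-fold cross-validation of the activity classifier
#'
#' Folds are stratified per class (fold sizes within a class differ by at most
#' one) and assigned reproducibly under `seed`. Precision and recall are
#' pooled over folds from the aggregate confusion matrix.
#'
#' @param features Labeled feature table (see [dataset_features()]); every
#'   class must have at least `k` members.
#' @param k Number of folds (default 10, must be >= 2).
#' @param seed Integer seed for the fold assignment.
#' @param min_leaf Passed to [train_tree()].
#' @return List with `per_class` (data.frame class/precision/recall),
#'   `accuracy`, `confusion` (true x predicted) and `folds`.
#' @export
cross_validate <- function(features, k = 10, seed = 1, min_leaf = 5) {
  if (k < 2) stop("'k' must be >= 2")
  features$label <- droplevels(factor(features$label))
  counts <- table(features$label)
  if (any(counts < k))
    stop("every class needs at least k = ", k, " members")
  folds <- integer(nrow(features))
  folds_draw <- withr::with_seed(seed, {
    lapply(levels(features$label), function(cl) {
      idx <- which(features$label == cl)
      sample(rep(seq_len(k), length.out = length(idx)))
    })
  })
  for (ci in seq_along(levels(features$label))) {
    folds[features$label == levels(features$label)[ci]] <- folds_draw[[ci]]
  }
  lev <- levels(features$label)
  confusion <- matrix(0L, length(lev), length(lev),
                      dimnames = list(true = lev, predicted = lev))
  for (fold in seq_len(k)) {
    train <- features[folds != fold, , drop = FALSE]
    test  <- features[folds == fold, , drop = FALSE]
    model <- train_tree(train, seed = seed, min_leaf = min_leaf)
    pred  <- predict_tree(model, test)
    pred  <- factor(as.character(pred), levels = lev)
    confusion <- confusion + unclass(table(test$label, pred))
  }
  precision <- diag(confusion) / pmax(colSums(confusion), 1)
  recall    <- diag(confusion) / pmax(rowSums(confusion), 1)
  list(per_class = data.frame(class = lev,
                              precision = unname(precision),
                              recall = unname(recall)),
       accuracy = sum(diag(confusion)) / sum(confusion),
       confusion = confusion,
       folds = folds)
}
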