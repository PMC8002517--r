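#' Subset a feature space by subject labels
#'
#' Keeps the rows whose subject label lies in `labels`, preserving row order.
#'
#' @param space A [build_feature_space()] result.
#' @param labels Integer set of subject labels (non-empty, all present).
#' @return A `feature_space` with `length(labels) * N` rows.
#' @export
subset_features <- function(space, labels) {
  stopifnot(inherits(space, "feature_space"))
  labels <- unique(as.integer(labels))
  if (length(labels) == 0L) stop("empty label set", call. = FALSE)
  unknown <- setdiff(labels, unique(space$labels))
  if (length(unknown))
    stop("label(s) not present in feature space: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- space$labels %in% labels
  structure(list(matrix = space$matrix[keep, , drop = FALSE],
                 labels = space$labels[keep],
                 config_id = space$config_id,
                 n_per_subject = space$n_per_subject,
                 config = space$config),
            class = "feature_space")
}

# One train/predict round for any supported classifier kind.
.train_predict <- function(train_x, train_y, test_x, clf) {
  train_y <- factor(train_y)
  switch(clf$kind,
    knn = as.character(class::knn(train_x, test_x, train_y, k = clf$neighbors)),
    naive_bayes = {
      df <- as.data.frame(train_x)
      fit <- e1071::naiveBayes(df, train_y)
      as.character(stats::predict(fit, as.data.frame(test_x)))
    },
    decision_tree = {
      df <- data.frame(.y = train_y, as.data.frame(train_x))
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(minsplit = 2, cp = 0.001,
                                                         xval = 0))
      as.character(stats::predict(fit, as.data.frame(test_x), type = "class"))
    },
    lda = {
      fit <- MASS::lda(train_x, grouping = train_y, tol = 1e-8)
      as.character(stats::predict(fit, test_x)$class)
    },
    stop("unsupported classifier kind: ", clf$kind, call. = FALSE))
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds, so every class appears in every training split.
.stratified_folds <- function(labels, kfold) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(kfold), length(idx))
  }
  fold
}

#' Cross-validated identification accuracy at one openness step
#'
#' Repetitive batch learning: the classifier is refit from scratch on the
#' training folds of the step's feature space and evaluated on the held-out
#' fold; the step accuracy is the micro-averaged fraction of correct
#' predictions pooled over all folds (equal to the fold-accuracy mean when
#' folds have equal size).
#'
#' @param space_j Feature space restricted to the step's enrolled labels.
#' @param clf A [classifier_spec()].
#' @param kfold Number of stratified cross-validation folds.
#' @param seed Seed controlling the fold shuffle.
#' @return An object of class `step_evaluation`: list with `accuracy`,
#'   `fold_accuracies`, `n_classes`, `labels`, `confusion`.
#' @export
evaluate_step <- function(space_j, clf, kfold, seed = 1L) {
  stopifnot(inherits(space_j, "feature_space"), inherits(clf, "classifier_spec"))
  kfold <- check_number(kfold, "kfold", lower = 2, integer = TRUE)
  counts <- table(space_j$labels)
  if (any(counts < kfold))
    stop(sprintf("every class needs at least kfold = %d rows (smallest has %d)",
                 kfold, min(counts)), call. = FALSE)
  y <- as.character(space_j$labels)
  with_seed(seed, {
    fold <- .stratified_folds(y, kfold)
    pred <- character(length(y))
    fold_acc <- numeric(kfold)
    for (f in seq_len(kfold)) {
      te <- fold == f
      pred[te] <- .train_predict(space_j$matrix[!te, , drop = FALSE], y[!te],
                                 space_j$matrix[te, , drop = FALSE], clf)
      fold_acc[f] <- mean(pred[te] == y[te])
    }
    structure(list(accuracy = mean(pred == y),
                   fold_accuracies = fold_acc,
                   n_classes = length(counts),
                   labels = sort(unique(space_j$labels)),
                   confusion = table(truth = y, predicted = pred)),
              class = "step_evaluation")
  })
}

#' Openness accuracy of one feature space
#'
#' Runs the class-update loop: for each of the M label sequences and each of
#' the R steps, the feature space is restricted to the enrolled labels and a
#' cross-validated identification accuracy is computed with a full classifier
#' refit (repetitive batch learning). Fold partitions are redrawn
#' independently at every step of every sequence.
#'
#' @param space A [build_feature_space()] result covering all simulated labels.
#' @param sim An [simulate_openness()] result.
#' @param clf A [classifier_spec()]; defaults to the one recorded in the
#'   space's pipeline configuration.
#' @param kfold Folds; defaults likewise.
#' @param seed Seed for the fold shuffles.
#' @return An object of class `openness_accuracy`: list with `per_sequence`
#'   (`M x R` accuracy matrix), `mean` (length-R column mean), `sizes`,
#'   `config_id`.
#' @export
run_openness <- function(space, sim, clf = NULL, kfold = NULL, seed = 1L) {
  stopifnot(inherits(space, "feature_space"), inherits(sim, "openness_sim"))
  clf <- clf %||% space$config$classifier
  kfold <- kfold %||% space$config$kfold
  if (is.null(clf) || is.null(kfold))
    stop("classifier and kfold must be given when the feature space carries no config",
         call. = FALSE)
  all_labels <- unique(unlist(lapply(sim$sequences, function(s) s[[length(s)]])))
  missing <- setdiff(all_labels, unique(space$labels))
  if (length(missing))
    stop("simulation labels absent from feature space: ",
         paste(sort(missing), collapse = ", "), call. = FALSE)
  M <- length(sim$sequences)
  R <- length(sim$sizes)
  oa <- matrix(NA_real_, nrow = M, ncol = R)
  for (i in seq_len(M)) {
    for (j in seq_len(R)) {
      sp <- subset_features(space, sim$sequences[[i]][[j]])
      ev <- evaluate_step(sp, clf, kfold, seed = sub_seed(seed, (i - 1L) * R + j))
      oa[i, j] <- ev$accuracy
    }
  }
  structure(list(per_sequence = oa,
                 mean = colMeans(oa),
                 sizes = sim$sizes,
                 config_id = space$config_id),
            class = "openness_accuracy")
}

#' @export
print.openness_accuracy <- function(x, ...) {
  cat(sprintf("Openness accuracy [%s]: %d sequence(s) x %d steps\n",
              x$config_id, nrow(x$per_sequence), ncol(x$per_sequence)))
  cat("  mean accuracy:", paste(sprintf("%.3f", x$mean), collapse = " "), "\n")
  invisible(x)
}

#' Write per-step openness accuracies to a tidy CSV
#'
#' One row per (sequence, step): `config_id`, `sequence`, `step`,
#' `n_classes`, `accuracy`.
#'
#' @param oa An [run_openness()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_openness_accuracy <- function(oa, path) {
  stopifnot(inherits(oa, "openness_accuracy"))
  M <- nrow(oa$per_sequence); R <- ncol(oa$per_sequence)
  df <- data.frame(config_id = oa$config_id,
                   sequence = rep(seq_len(M), each = R),
                   step = rep(seq_len(R), times = M),
                   n_classes = rep(oa$sizes, times = M),
                   accuracy = as.vector(t(oa$per_sequence)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy openness-accuracy CSV
#'
#' @param path CSV written by [write_openness_accuracy()].
#' @return An `openness_accuracy` object.
#' @export
read_openness_accuracy <- function(path) {
  df <- utils::read.csv(path)
  M <- max(df$sequence); R <- max(df$step)
  oa <- matrix(NA_real_, M, R)
  oa[cbind(df$sequence, df$step)] <- df$accuracy
  sizes <- integer(R)
  sizes[df$step] <- df$n_classes
  structure(list(per_sequence = oa, mean = colMeans(oa),
                 sizes = sizes, config_id = as.character(df$config_id[1])),
            class = "openness_accuracy")
}
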