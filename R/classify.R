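#' Subject-level train/test split with grouped hemispheres
#'
#' Splits a subject x subfield metric table into disjoint train and test
#' sets at the subject level: both hemispheres and all subfield rows of a
#' subject land on the same side. When the table holds fewer subjects than
#' `n_train + n_test`, the 70/30-style proportions are preserved.
#'
#' @param table data.frame with a `subject` column (e.g.
#'   [make_subfield_table()]).
#' @param n_train,n_test subject counts (defaults 70/30).
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_subjects <- function(table, n_train = 70, n_test = 30, seed = 1L) {
  subjects <- unique(table$subject)
  n <- length(subjects)
  if (n < 2) stop("need at least 2 subjects")
  if (n < n_train + n_test) {
    prop <- n_train / (n_train + n_test)
    n_train <- max(1L, round(prop * n))
    n_test <- n - n_train
    if (n_test < 1) { n_train <- n - 1L; n_test <- 1L }
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(subjects)
  tr <- perm[seq_len(n_train)]
  te <- perm[n_train + seq_len(n_test)]
  if (length(intersect(tr, te))) stop("train/test subject overlap detected")
  list(train = table[table$subject %in% tr, , drop = FALSE],
       test = table[table$subject %in% te, , drop = FALSE])
}

#' Train a multinomial L2-regularized logistic classifier
#'
#' Softmax regression minimizing cross-entropy with a ridge penalty on the
#' coefficients, the simple interpretable model used to ask whether
#' subfield-averaged microstructure separates the subfields. Features are
#' standardized using training-set statistics (the L2 penalty is
#' scale-sensitive); the optimizer is deterministic.
#'
#' @param train data.frame of training rows.
#' @param features feature column names (default ODI, NDI, T1w/T2w; set to
#'   `c("fa", "md")` for the DTI variant).
#' @param label_col outcome column (default `"subfield"`).
#' @param C inverse regularization strength (default 1); the ridge penalty
#'   is `1 / (C * n_train)` on the glmnet scale.
#' @return a `subfield_classifier` with the fitted model, feature scaling
#'   and class levels.
#' @export
train_classifier <- function(train, features = c("odi", "ndi", "t1wt2w"),
                             label_col = "subfield", C = 1) {
  y <- droplevels(factor(train[[label_col]]))
  if (nlevels(y) < 2) stop("training data must contain at least 2 classes")
  X <- as.matrix(train[, features, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  lambda <- 1 / (C * nrow(Xs))
  fit <- glmnet::glmnet(Xs, y, family = "multinomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  structure(list(model = fit, features = features, label_col = label_col,
                 center = ctr, scale = scl, levels = levels(y),
                 lambda = lambda, n_train = nrow(Xs)),
            class = "subfield_classifier")
}

#' @export
predict.subfield_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  Xs <- scale(X, center = object$center, scale = object$scale)
  pr <- predict(object$model, newx = Xs, type = "class")
  factor(as.vector(pr), levels = object$levels)
}

#' Evaluate a subfield classifier on held-out data
#'
#' Builds the test-set confusion matrix (true classes in rows) and
#' per-class precision, recall and
#' \eqn{F_1 = 2\,\mathrm{precision}\cdot\mathrm{recall} /
#' (\mathrm{precision}+\mathrm{recall})} (defined as 0 when precision +
#' recall = 0). Classes present in the test set but unseen in training are
#' counted and warned about.
#'
#' @param model a [train_classifier()] object.
#' @param test data.frame of held-out rows.
#' @return a `subfield_report`: `confusion` (counts), `metrics` data.frame
#'   (class, precision, recall, f1, support), `macro_f1`, `accuracy`,
#'   `n_test`.
#' @export
evaluate_classifier <- function(model, test) {
  truth <- factor(test[[model$label_col]])
  unseen <- setdiff(levels(droplevels(truth)), model$levels)
  if (length(unseen)) {
    warning("test classes unseen in training: ", paste(unseen, collapse = ", "))
  }
  lev <- union(model$levels, levels(truth))
  truth <- factor(as.character(truth), levels = lev)
  pred <- factor(as.character(predict(model, test)), levels = lev)
  confusion <- table(truth = truth, predicted = pred)
  tp <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  rec <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  metrics <- data.frame(class = lev, precision = as.numeric(prec),
                        recall = as.numeric(rec), f1 = as.numeric(f1),
                        support = as.numeric(rowSums(confusion)),
                        stringsAsFactors = FALSE)
  present <- metrics$support > 0
  structure(list(confusion = confusion, metrics = metrics,
                 macro_f1 = mean(metrics$f1[present]),
                 accuracy = sum(tp) / sum(confusion),
                 n_test = nrow(test)),
            class = "subfield_report")
}

#' @export
print.subfield_report <- function(x, ...) {
  cat(sprintf("Subfield classifier report: accuracy %.3f, macro-F1 %.3f (n = %d)\n",
              x$accuracy, x$macro_f1, x$n_test))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' End-to-end subfield separability analysis
#'
#' Convenience wrapper: subject-level split, training and evaluation.
#'
#' @inheritParams split_subjects
#' @inheritParams train_classifier
#' @return a `subfield_report` (with the split sizes attached).
#' @export
subfield_separability <- function(table, features = c("odi", "ndi", "t1wt2w"),
                                  label_col = "subfield", n_train = 70,
                                  n_test = 30, seed = 1L, C = 1) {
  sp <- split_subjects(table, n_train, n_test, seed)
  model <- train_classifier(sp$train, features, label_col, C)
  rep <- evaluate_classifier(model, sp$test)
  rep$n_train_subjects <- length(unique(sp$train$subject))
  rep$n_test_subjects <- length(unique(sp$test$subject))
  rep
}
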