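# Fixture with one class placed at the centroid of four well-separated
# classes, mimicking the CA2-like overlap regime.
overlap_means <- function() {
  m <- rbind(Sub = c(0.2, 0.2, 1.0),
             CA1 = c(1.0, 0.2, 1.0),
             CA2 = c(0.6, 0.6, 1.6),   # centroid of the others
             CA3 = c(0.2, 1.0, 2.2),
             "DG/CA4" = c(1.0, 1.0, 2.2))
  colnames(m) <- c("odi", "ndi", "t1wt2w")
  m
}

test_that("subject splits are disjoint, reproducible, and hemisphere-grouped", {
  tab <- make_subfield_table(10, seed = 1)
  sp <- split_subjects(tab, n_train = 7, n_test = 3, seed = 2)
  expect_length(intersect(unique(sp$train$subject), unique(sp$test$subject)), 0)
  expect_equal(length(unique(sp$train$subject)), 7)
  sp2 <- split_subjects(tab, n_train = 7, n_test = 3, seed = 2)
  expect_identical(sp$train, sp2$train)
  # both hemispheres of a subject travel together
  for (side in list(sp$train, sp$test)) {
    hemi_counts <- table(side$subject, side$hemisphere)
    expect_true(all(hemi_counts %in% c(0, 5)))
    expect_true(all(rowSums(hemi_counts) %in% c(0, 10)))
  }
  # 70/30 proportions preserved when fewer subjects are available
  sp3 <- split_subjects(tab, seed = 1)
  expect_equal(length(unique(sp3$train$subject)), 7)
})

test_that("well-separated classes are classified perfectly", {
  m <- overlap_means()
  m["CA2", ] <- c(0.6, 0.05, 3.2)       # move CA2 away: all separable
  tab <- make_subfield_table(40, class_means = m,
                             class_cov = diag(c(0.02, 0.02, 0.02)^2), seed = 5)
  rep <- subfield_separability(tab, n_train = 28, n_test = 12, seed = 1)
  expect_equal(rep$accuracy, 1)
  expect_true(all(rep$metrics$f1 == 1))
})

test_that("shuffled labels drop performance to chance", {
  tab <- make_subfield_table(30, seed = 4)
  f1s <- vapply(1:20, function(s) {
    shuffled <- tab
    set.seed(s)
    shuffled$subfield <- sample(shuffled$subfield)
    sp <- split_subjects(shuffled, n_train = 21, n_test = 9, seed = s)
    model <- train_classifier(sp$train)
    evaluate_classifier(model, sp$test)$macro_f1
  }, numeric(1))
  expect_lt(abs(mean(f1s) - 0.2), 0.1)
})

test_that("a centroid-placed class attains the lowest F1", {
  tab <- make_subfield_table(100, class_means = overlap_means(),
                             class_cov = diag(c(0.12, 0.12, 0.3)^2), seed = 6)
  rep <- subfield_separability(tab, n_train = 70, n_test = 30, seed = 1)
  f1 <- stats::setNames(rep$metrics$f1, rep$metrics$class)
  expect_equal(names(which.min(f1)), "CA2")
})

test_that("duplicated feature columns leave predictions unchanged", {
  # a duplicated column splits its ridge weight, which perturbs predictions
  # at strong regularization; in the vanishing-penalty limit the fitted
  # probabilities are invariant, and at the default penalty predictions must
  # stay essentially unchanged
  tab <- make_subfield_table(20, seed = 7)
  sp <- split_subjects(tab, n_train = 14, n_test = 6, seed = 1)
  tab2 <- tab
  tab2$odi2 <- tab2$odi
  sp2 <- split_subjects(tab2, n_train = 14, n_test = 6, seed = 1)
  m1 <- train_classifier(sp$train, C = 1e6)
  m2 <- train_classifier(sp2$train, features = c("odi", "odi2", "ndi", "t1wt2w"),
                         C = 1e6)
  expect_identical(as.character(predict(m1, sp$test)),
                   as.character(predict(m2, sp2$test)))
  d1 <- train_classifier(sp$train)
  d2 <- train_classifier(sp2$train, features = c("odi", "odi2", "ndi", "t1wt2w"))
  agree <- mean(as.character(predict(d1, sp$test)) ==
                as.character(predict(d2, sp2$test)))
  expect_gte(agree, 0.9)
})

test_that("report metrics are consistent with the confusion matrix", {
  tab <- make_subfield_table(30, seed = 8)
  rep <- subfield_separability(tab, n_train = 21, n_test = 9, seed = 2)
  cm <- rep$confusion
  # micro-averaged recall equals accuracy
  expect_equal(sum(diag(cm)) / sum(cm), rep$accuracy)
  for (i in seq_along(rep$metrics$class)) {
    cl <- rep$metrics$class[i]
    p <- if (sum(cm[, cl]) > 0) cm[cl, cl] / sum(cm[, cl]) else 0
    r <- if (sum(cm[cl, ]) > 0) cm[cl, cl] / sum(cm[cl, ]) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    expect_equal(rep$metrics$precision[i], unname(p))
    expect_equal(rep$metrics$recall[i], unname(r))
    expect_equal(rep$metrics$f1[i], unname(f))
  }
  expect_true(all(rep$metrics$f1 >= 0 & rep$metrics$f1 <= 1))
})

test_that("training refuses single-class data and warns on unseen classes", {
  tab <- make_subfield_table(10, seed = 9)
  only_sub <- tab[tab$subfield == "Sub", ]
  expect_error(train_classifier(only_sub), "2 classes")

  train <- tab[tab$subfield != "CA2" & tab$subject %in% unique(tab$subject)[1:7], ]
  model <- train_classifier(droplevels(train))
  test <- tab[tab$subject %in% unique(tab$subject)[8:10], ]
  expect_warning(rep <- evaluate_classifier(model, test), "unseen")
  expect_equal(sum(rep$confusion), nrow(test))
})
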