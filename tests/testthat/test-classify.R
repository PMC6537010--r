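two_clusters <- function(n_per = 10, gap = 30, dim = 5, seed = 1) {
  set.seed(seed)
  f <- rbind(matrix(rnorm(n_per * dim, 0), n_per),
             matrix(rnorm(n_per * dim, gap), n_per))
  list(features = f, labels = rep(c("a", "b"), each = n_per))
}

test_that("well-separated clusters classify perfectly; singleton classes cannot", {
  ev <- loso_knn_evaluate(two_clusters())
  expect_equal(ev$accuracy, 1)
  expect_equal(sum(ev$confusion), 20)
  expect_equal(sum(diag(ev$confusion)), 20)

  # one sample per class: the only same-class sample is always held out
  singletons <- list(features = diag(4) * 10, labels = letters[1:4])
  expect_equal(loso_knn_evaluate(singletons)$accuracy, 0)
})

test_that("confusion matrix and accuracy are consistent", {
  set.seed(5)
  data <- list(features = matrix(rnorm(60 * 4), 60),
               labels = rep(c("x", "y", "z"), 20))
  ev <- loso_knn_evaluate(data, k = 3)
  expect_equal(sum(ev$confusion), 60)
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / 60)
  expect_equal(ev$accuracy, mean(ev$predictions$correct))
})

test_that("LOSO-KNN matches the brute-force all-pairs oracle fold for fold", {
  set.seed(6)
  for (metric in c("euclidean", "chi2")) {
    for (k in c(1, 3)) {
      feats <- matrix(sample(0:20, 40 * 12, TRUE), 40)
      labels <- sample(c("p", "q", "r"), 40, TRUE)
      got <- loso_knn_evaluate(list(features = feats, labels = labels),
                               k = k, metric = metric)
      want <- oracle_loso_knn(feats, labels, k = k, metric = metric)
      expect_identical(got$predictions$predicted, want$predictions)
      expect_equal(got$accuracy, want$accuracy)
    }
  }
})

test_that("evaluation is deterministic and validates its settings", {
  data <- two_clusters(seed = 9)
  e1 <- loso_knn_evaluate(data, k = 3)
  e2 <- loso_knn_evaluate(data, k = 3)
  expect_identical(e1$predictions, e2$predictions)
  expect_error(loso_knn_evaluate(data, k = 0), "k")
  expect_error(loso_knn_evaluate(data, k = 20), "k")
  expect_error(loso_knn_evaluate(data, metric = "cosine"))
  expect_error(loso_knn_evaluate(list(features = diag(3),
                                      labels = rep("a", 3))), "classes")
})

test_that("class centers are per-class means (or medoids on request)", {
  # one sample per class: centers equal the samples
  data <- list(features = rbind(c(1, 2), c(5, 5)), labels = c("a", "b"))
  expect_equal(unname(class_centers(data)), unname(data$features))

  # duplicated samples: center equals them
  data <- list(features = rbind(c(3, 3), c(3, 3)), labels = c("a", "a"))
  expect_equal(unname(class_centers(data)[1, ]), c(3, 3))

  set.seed(10)
  feats <- matrix(rnorm(30), 10, 3)
  labels <- rep(c("a", "b"), 5)
  centers <- class_centers(list(features = feats, labels = labels))
  for (cl in c("a", "b")) {
    expect_equal(centers[cl, ],
                 apply(feats[labels == cl, ], 2, mean))
  }
  med <- class_centers(list(features = feats, labels = labels),
                       type = "medoid")
  expect_true(all(apply(med, 1, function(m) {
    any(apply(feats, 1, function(r) all(r == m)))
  })))
})

test_that("membership components follow the inverse-square-distance law", {
  centers <- rbind(a = c(0, 0), b = c(3, 0))
  ra <- expression_components(c(1, 0), centers)   # d = (1, 2)
  expect_equal(unname(ra), c(0.8, 0.2))

  # equal distances -> uniform profile
  centers <- rbind(a = c(1, 0), b = c(-1, 0), c = c(0, 1), d = c(0, -1))
  expect_equal(unname(expression_components(c(0, 0), centers)), rep(0.25, 4))

  # zero-distance limit: all mass on the coincident center
  expect_equal(unname(expression_components(c(1, 0), centers)),
               c(1, 0, 0, 0))

  expect_error(expression_components(c(1, 0, 0), centers), "mismatch")
})

test_that("component profiles are normalized and non-negative on random inputs", {
  set.seed(12)
  for (trial in 1:20) {
    centers <- matrix(rnorm(6 * 8), 6)
    rownames(centers) <- letters[1:6]
    sample_vec <- rnorm(8)
    for (metric in c("euclidean", "chi2")) {
      ra <- expression_components(abs(sample_vec), abs(centers),
                                  metric = metric)
      expect_true(all(ra >= 0))
      expect_lt(abs(sum(ra) - 1), 1e-9)
    }
  }
})
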