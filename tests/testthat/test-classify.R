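make_table <- function(n_per_class = 20, sep = 5, sd = 0.1, seed = 1,
                       labels = c("cyst", "normal")) {
  set.seed(seed)
  n <- n_per_class
  df <- data.frame(
    image_id = sprintf("im%03d", seq_len(2 * n)),
    label = rep(labels, each = n),
    f1 = c(rnorm(n, sep, sd), rnorm(n, -sep, sd)),
    f2 = c(rnorm(n, sep, sd), rnorm(n, -sep, sd)),
    stringsAsFactors = FALSE)
  feature_table(df, method = "toy")
}

test_that("feature_table validates its contract", {
  expect_error(feature_table(data.frame(a = 1)), "image_id")
  df <- data.frame(image_id = c("a", "a"), label = c("cyst", "normal"),
                   f = c(1, 2))
  expect_error(feature_table(df), "duplicated")
  df <- data.frame(image_id = c("a", "b"), label = c("cyst", "normal"),
                   f = c(1, NA))
  expect_error(feature_table(df), "missing")
})

test_that("split_dataset: stratified counts, determinism, edge cases", {
  tab <- make_table(40)
  sp <- split_dataset(tab, 2 / 3, seed = 5)
  expect_equal(sum(sp$train$label == "cyst"), 26)     # floor(2/3 * 40)
  expect_equal(sum(sp$test$label == "cyst"), 14)
  expect_equal(sum(sp$train$label == "normal"), 26)
  expect_length(intersect(sp$train$image_id, sp$test$image_id), 0)
  expect_setequal(c(sp$train$image_id, sp$test$image_id), tab$image_id)

  sp2 <- split_dataset(tab, 2 / 3, seed = 5)
  expect_identical(sp$train$image_id, sp2$train$image_id)  # seeded determinism

  expect_error(split_dataset(tab, 0), "strictly")
  expect_error(split_dataset(tab, 1), "strictly")
  one <- tab[c(1, 41), ]
  expect_error(split_dataset(feature_table(one, "toy"), 0.5), "at least 2")
})

test_that("separable clouds are fit perfectly and deterministically", {
  tab <- make_table(20)
  m <- fit_svm(tab)
  pred <- predict(m, tab)
  expect_equal(mean(pred$predicted == pred$truth), 1)   # training accuracy 1
  expect_true(all(sign(pred$score) == ifelse(pred$predicted == "lesion", 1, -1)))

  m2 <- fit_svm(tab)
  expect_identical(predict(m2, tab)$score, pred$score)  # refit is identical

  # permuting rows permutes outputs identically
  perm <- sample(nrow(tab))
  predp <- predict(m, tab[perm, ])
  expect_equal(predp$score, pred$score[perm])

  expect_error(fit_svm(tab[tab$label == "cyst", ]), "single class")
  expect_error(predict(m, make_table(5)[, -4]), "mismatch")
})

test_that("linear kernel also separates the toy clouds", {
  tab <- make_table(15, seed = 3)
  m <- fit_svm(tab, kernel = "linear")
  expect_equal(mean(predict(m, tab)$predicted == predict(m, tab)$truth), 1)
})

test_that("no class signal gives chance-level held-out accuracy", {
  accs <- vapply(1:50, function(s) {
    set.seed(s)
    df <- data.frame(image_id = sprintf("i%02d", 1:40),
                     label = rep(c("cyst", "normal"), each = 20),
                     f1 = rnorm(40), f2 = rnorm(40),
                     stringsAsFactors = FALSE)
    sp <- split_dataset(feature_table(df, "noise"), 0.5, seed = s)
    pred <- predict(fit_svm(sp$train), sp$test)
    mean(pred$predicted == pred$truth)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("standardization constants come from the training split only", {
  tab <- make_table(30, seed = 9)
  sp <- split_dataset(tab, 0.5, seed = 2)
  m <- fit_svm(sp$train)
  expect_equal(unname(m$center), unname(colMeans(as.matrix(sp$train[-(1:2)]))))
  expect_false(isTRUE(all.equal(unname(m$center),
                                unname(colMeans(as.matrix(sp$test[-(1:2)]))))))
})

test_that("models round-trip through JSON persistence", {
  tab <- make_table(10, seed = 4)
  m <- fit_svm(tab)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, tab)$score, predict(m, tab)$score, tolerance = 1e-12)
})
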