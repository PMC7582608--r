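separable_table <- function(n = 20, seed = 71) {
  withr::with_seed(seed, {
    outcome <- rep(c("pre_event", "control"), each = n / 2)
    tibble::tibble(
      recording_id = paste0("r", 1:n),
      patient_id = paste0("p", 1:n),
      outcome = outcome,
      a = ifelse(outcome == "pre_event", runif(n, 0.7, 1), runif(n, 0, 0.3)),
      b = runif(n)
    )
  })
}

test_that("hyperparameter grids match their arithmetic/geometric specs", {
  g <- hyperparameter_grids()
  expect_equal(g$cost[1], 0.5)
  expect_equal(g$cost[length(g$cost)], 10)
  expect_length(g$cost, 20)
  expect_true(all(abs(diff(g$cost) - 0.5) < 1e-12))
  expect_length(g$gamma, 37)
  expect_equal(min(g$gamma), 2^-15)
  expect_equal(max(g$gamma), 8)
  expect_equal(round(g$gamma[30], 4), 0.7071)  # exponent -0.5
  expect_true(all(abs(diff(log2(g$gamma)) - 0.5) < 1e-12))
})

test_that("native decision margins agree with libsvm's decision values", {
  set.seed(77)
  X <- matrix(runif(60), 30, 2)
  y <- factor(rep(c("control", "pre_event"), 15),
              levels = c("control", "pre_event"))
  for (gamma in c(0.1, 1, 4)) {
    fit <- hrvprint:::fit_rbf_svm(X, y, cost = 2, gamma = gamma)
    m <- e1071::svm(X, y, type = "C-classification", kernel = "radial",
                    cost = 2, gamma = gamma, scale = FALSE)
    dv <- drop(attr(predict(m, X, decision.values = TRUE),
                    "decision.values"))
    oriented <- if (grepl("^pre_event", colnames(
      attr(predict(m, X, decision.values = TRUE), "decision.values")))) {
      dv
    } else {
      -dv
    }
    expect_equal(hrvprint:::rbf_margin(fit, X), unname(oriented),
                 tolerance = 1e-9)
  }
})

test_that("rank-statistic AUC equals brute-force pair counting", {
  set.seed(83)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    expect_equal(auc_rank(scores, pos), oracle_auc(scores, pos))
  }
  # hand-traced case: 3 of 4 positive-negative pairs concordant
  expect_equal(auc_rank(c(0.9, 0.8, 0.7, 0.2), c(TRUE, FALSE, TRUE, FALSE)),
               0.75)
  expect_equal(auc_rank(rep(1, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)),
               0.5)
  expect_error(auc_rank(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("a separable table trains and evaluates perfectly", {
  tab <- separable_table()
  model <- train_final(tab, c("a", "b"), cost = 2, gamma = 1)
  ev <- evaluate_model(model, tab)
  expect_equal(ev$auc, 1)
  expect_equal(ev$accuracy, 100)
  expect_true(ev$auc_lower <= 1 && ev$auc_upper >= ev$auc)
  expect_lt(ev$accuracy_lower, 100)  # Wilson interval never collapses
  expect_error(evaluate_model(model, dplyr::filter(tab, outcome == "control")),
               "both outcomes")
})

test_that("models round-trip through the JSON bundle exactly", {
  tab <- separable_table(n = 24, seed = 91)
  model <- train_final(tab, c("a", "b"), cost = 3.5, gamma = 0.7071)
  path <- withr::local_tempfile(fileext = ".json")
  write_hrvprint_model(model, path)
  back <- read_hrvprint_model(path)
  probe <- separable_table(n = 16, seed = 101)
  expect_equal(predict(back, probe), predict(model, probe),
               tolerance = 1e-9)
  expect_equal(back$features, model$features)
  expect_equal(back$scaler$min, model$scaler$min)
})

test_that("the kernel limit gamma -> 0 flattens the decision margin", {
  tab <- separable_table(n = 20, seed = 107)
  m_small <- train_final(tab, c("a", "b"), cost = 1, gamma = 1e-12)
  margins <- predict(m_small, tab)
  expect_lt(diff(range(margins)), 1e-4 * max(abs(margins) + 1e-12) + 1e-6)
})

test_that("evaluation intervals match closed-form CI oracles", {
  # Hanley-McNeil with AUC 0.75, n1 = n0 = 10
  ci <- hrvprint:::auc_hanley_ci(0.75, 10, 10)
  q1 <- 0.75 / 1.25; q2 <- 2 * 0.75^2 / 1.75
  se <- sqrt((0.75 * 0.25 + 9 * (q1 - 0.5625) + 9 * (q2 - 0.5625)) / 100)
  expect_equal(unname(ci["upper"] - ci["lower"]), 2 * qnorm(0.975) * se,
               tolerance = 1e-12)
  # Wilson interval for 8/10 against stats::prop.test's uncorrected form
  w <- hrvprint:::wilson_ci(8, 10)
  pt <- prop.test(8, 10, correct = FALSE)$conf.int
  expect_equal(unname(w), as.numeric(pt), tolerance = 1e-9)
})

test_that("tidy and glance summarize fitted models", {
  tab <- separable_table()
  model <- train_final(tab, c("a", "b"), cost = 2, gamma = 1)
  td <- generics::tidy(model)
  expect_equal(nrow(td), length(model$coefs))
  gl <- generics::glance(model)
  expect_equal(gl$cost, 2)
  expect_equal(gl$n_features, 2)
  expect_s3_class(generics::tidy(model$scaler), "tbl_df")
})
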