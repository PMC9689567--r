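test_that("correlation pruning keeps one of a duplicated pair, in scan order", {
  tab <- make_feature_table(n_subjects = 4, n_lifts = 5, seed = 2, features = list(
    A = function(d) rnorm(nrow(d)),
    B = function(d) rnorm(nrow(d))
  ))
  tab$A2 <- tab$A  # exact duplicate, later in the table
  expect_equal(prune_correlated(tab), c("A", "B"))
})

test_that("orthogonal features survive; strongly correlated pairs lose the later one", {
  set.seed(999)
  n <- 200
  z <- rnorm(n)
  tab <- make_feature_table(n_subjects = 5, n_lifts = 20, seed = 5, features = list(
    X1 = function(d) z,
    X2 = function(d) rnorm(n),                     # independent of X1
    X3 = function(d) 0.95 * z + sqrt(1 - 0.95^2) * rnorm(n)  # r ~ 0.95 with X1
  ))
  expect_gt(abs(cor(tab$X1, tab$X3)), 0.7)  # oracle: the pair really is correlated
  expect_lt(abs(cor(tab$X1, tab$X2)), 0.7)
  expect_equal(prune_correlated(tab), c("X1", "X2"))
})

test_that("constant features are dropped with a warning", {
  tab <- make_feature_table(n_subjects = 4, n_lifts = 5, features = list(
    A = function(d) rnorm(nrow(d)), K = function(d) rep(3, nrow(d))
  ))
  expect_warning(kept <- prune_correlated(tab),
                 class = "liftrisk_constant_feature")
  expect_equal(kept, "A")
})

sim_two_feature_table <- function(n_per_class = 150, shift = 2, seed = 1) {
  make_feature_table(n_subjects = 15, n_lifts = n_per_class / 15, seed = seed,
    features = list(
      F1 = function(d) rnorm(nrow(d)) + shift * (d$label == "RISK"),
      F2 = function(d) rnorm(nrow(d)) + shift / 2 * (d$label == "RISK")
    ))
}

test_that("outlier removal flags an injected gross outlier and little else", {
  tab <- sim_two_feature_table(seed = 8)
  out_clean <- remove_outliers(tab, c("F1", "F2"))
  expect_lte(nrow(out_clean$removed), 0.02 * nrow(tab))
  # inject a gross label-inconsistent outlier: a NO_RISK lift placed deep
  # inside RISK feature territory (10 SD along F1)
  tab2 <- tab
  stopifnot(tab2$label[5] == "NO_RISK")
  tab2$F1[5] <- 10; tab2$F2[5] <- 5
  out <- remove_outliers(tab2, c("F1", "F2"))
  expect_true(any(out$removed$subject == tab2$subject[5] &
                    out$removed$lift_index == tab2$lift_index[5] &
                    out$removed$trial == tab2$trial[5]))
  # oracle: leave-one-out refit moves the coefficients most for that row
  dat <- data.frame(F1 = tab2$F1, F2 = tab2$F2,
                    y = as.integer(tab2$label == "RISK"))
  full <- coef(suppressWarnings(glm(y ~ F1 + F2, binomial, dat)))
  loo_shift <- vapply(c(5, 1, 50, 120, 200, 280), function(i) {
    sum((coef(suppressWarnings(glm(y ~ F1 + F2, binomial, dat[-i, ]))) - full)^2)
  }, numeric(1))
  expect_equal(which.max(loo_shift), 1L)  # row 5 dominates
})

test_that("outlier removal refuses under-determined tables", {
  tab <- sim_two_feature_table()[1:8, ]
  expect_error(remove_outliers(tab, c("F1", "F2")), "refusing")
})

test_that("a perfectly separating feature is retained with 100% resubstitution", {
  tab <- make_feature_table(n_subjects = 10, n_lifts = 10, seed = 4, features = list(
    S = function(d) (d$label == "RISK") * 2 + runif(nrow(d), -0.5, 0.5),
    N = function(d) rnorm(nrow(d))
  ))
  suppressWarnings(m <- fit_risk_model(tab, c("S", "N")))
  expect_true("S" %in% m$final_features)
  expect_equal(m$accuracy, 100)
  expect_true(m$separation)
})

test_that("pure-noise features yield an empty or near-chance model", {
  accs <- vapply(1:20, function(s) {
    tab <- make_feature_table(n_subjects = 25, n_lifts = 10, seed = 100 + s,
      features = setNames(
        lapply(1:10, function(i) function(d) rnorm(nrow(d))),
        paste0("N", 1:10)
      ))
    m <- fit_risk_model(tab, paste0("N", 1:10))
    if (!length(m$final_features)) 50 else m$accuracy
  }, numeric(1))
  expect_true(all(accs <= 60))
})

test_that("events-per-variable is the smallest class over the final feature count", {
  tab <- sim_two_feature_table(shift = 1.5, seed = 9)
  m <- fit_risk_model(tab, c("F1", "F2"))
  expect_equal(m$events_per_variable,
               min(table(tab$label)) / length(m$final_features))
  g <- glance(m)
  expect_equal(g$n_final_features, length(m$final_features))
  expect_equal(nrow(tidy(m)), length(m$final_features))
})

test_that("published-style confusion counts reproduce the printed percentages", {
  m <- classification_metrics(matrix(c(218, 49, 39, 207), 2, 2))
  expect_equal(m$accuracy, 82.8)
  expect_equal(m$sensitivity, 84.8)
  expect_equal(m$specificity, 80.9)
  expect_equal(m$n_correct, 425)
})

test_that("degenerate predictors force the metric identities", {
  perfect <- evaluate_classification(rep(c("NO_RISK", "RISK"), 50),
                                     rep(c("NO_RISK", "RISK"), 50))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  constant <- evaluate_classification(rep("NO_RISK", 200),
                                      rep(c("NO_RISK", "RISK"), each = 100))
  expect_equal(constant$accuracy, 50.0)
  expect_equal(constant$sensitivity, 100.0)
  expect_equal(constant$specificity, 0.0)
})

test_that("metric identities hold for random confusion matrices", {
  set.seed(13)
  for (i in 1:50) {
    cm <- matrix(sample(0:200, 4), 2, 2)
    if (any(rowSums(cm) == 0)) next
    m <- classification_metrics(cm)
    expect_equal(m$n_correct, sum(diag(cm)))
    expect_equal(m$accuracy, round(100 * sum(diag(cm)) / sum(cm) + 1e-9, 1),
                 tolerance = 0.051)
    expect_equal(m$sensitivity, round(100 * cm[1, 1] / sum(cm[1, ]) + 1e-9, 1),
                 tolerance = 0.051)
  }
})

test_that("evaluation rejects malformed inputs", {
  expect_error(evaluate_classification(c("NO_RISK"), c("NO_RISK", "RISK")),
               "equal length")
  expect_error(evaluate_classification(c("MAYBE"), c("RISK")), "labels")
})
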