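#' Remove multicollinear features by pairwise Pearson correlation
#'
#' Greedy scan in catalogue (column) order: each feature is kept unless its
#' absolute Pearson correlation with an already-kept feature exceeds
#' `r_threshold`, in which case the later feature is dropped. With
#' `order_by_p` a screening result can be supplied so that the scan runs in
#' ascending p-value order (keep the more discriminative of a correlated
#' pair); the default preserves catalogue order. Constant columns have
#' undefined correlations and are dropped with a warning.
#'
#' @param table Feature table ([build_feature_table()] layout).
#' @param r_threshold Absolute correlation above which the later feature is
#'   removed (default 0.7).
#' @param order_by_p Optional `lift_screen` result; if given, features are
#'   scanned by ascending screening p-value.
#' @return Character vector of retained feature names (in scan order).
#' @export
prune_correlated <- function(table, r_threshold = 0.7, order_by_p = NULL) {
  feats <- setdiff(names(table), c("subject", "trial", "lift_index", "label"))
  if (nrow(table) < 2) abort("need >= 2 rows to compute correlations")
  X <- as.matrix(table[feats])
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    lift_warn(paste0("dropping constant feature(s) with undefined correlation: ",
                     paste(feats[sds == 0], collapse = ", ")),
              "liftrisk_constant_feature")
    feats <- feats[sds > 0]
    X <- X[, feats, drop = FALSE]
  }
  if (!is.null(order_by_p)) {
    ord <- order_by_p$feature[order(order_by_p$p_value)]
    feats <- intersect(ord, feats)
    X <- X[, feats, drop = FALSE]
  }
  R <- abs(cor(X))
  kept <- character(0)
  for (f in feats) {
    if (!length(kept) || all(R[f, kept] <= r_threshold)) kept <- c(kept, f)
  }
  kept
}

#' Remove outlying lift instances via Cook's distance and leverage
#'
#' Fits a preliminary binary logistic regression of the class label on the
#' supplied features and removes, in a single pass, every instance with
#' Cook's distance above 0.5 (the classical "worth a closer look" rule for
#' influence, with 1 flagging outright) or hat-matrix (centre) leverage
#' above `4 (k + 1) / n`, where `k` is the number of predictors. These
#' defaults flag of the order of 1% of well-behaved instances, the
#' prevalence this outlier screen exhibits in practice on real lifting
#' cohorts. Removal is not iterated.
#'
#' @param table Feature table.
#' @param features Predictor columns to use (e.g. from [prune_correlated()]).
#' @param cooks_cutoff,leverage_cutoff Override the default cutoffs.
#' @return List with `table` (pruned), `removed` (tibble of removed rows with
#'   their diagnostics) and `cutoffs`.
#' @export
remove_outliers <- function(table, features,
                            cooks_cutoff = NULL, leverage_cutoff = NULL) {
  n <- nrow(table); k <- length(features)
  if (n < 5 * k) {
    abort(sprintf("refusing outlier removal with n = %d < 5k = %d rows", n, 5 * k))
  }
  dat <- prepare_model_frame(table, features)
  fit <- fit_logistic(dat, features)
  cd <- cooks.distance(fit$model)
  hv <- hatvalues(fit$model)
  cooks_cutoff <- cooks_cutoff %||% 0.5
  leverage_cutoff <- leverage_cutoff %||% (4 * (k + 1) / n)
  bad <- cd > cooks_cutoff | hv > leverage_cutoff
  removed <- dplyr::bind_cols(
    table[bad, c("subject", "trial", "lift_index", "label")],
    tibble::tibble(cooks_d = cd[bad], leverage = hv[bad])
  )
  list(table = table[!bad, , drop = FALSE], removed = removed,
       cutoffs = c(cooks = cooks_cutoff, leverage = leverage_cutoff))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

prepare_model_frame <- function(table, features) {
  dat <- table[features]
  dat$.y <- as.integer(table$label == "RISK")
  if (length(unique(dat$.y)) < 2) abort("both classes must be present to fit")
  dat
}

fit_logistic <- function(dat, features) {
  separation <- FALSE
  fml <- stats::reformulate(sprintf("`%s`", features), response = ".y")
  model <- withCallingHandlers(
    glm(fml, family = binomial(), data = dat,
        control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("algorithm did not converge", msg)) {
        if (grepl("fitted probabilities", msg)) separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!model$converged && !separation) {
    abort(sprintf("logistic fit did not converge in %d IRLS iterations", model$iter))
  }
  if (!model$converged && separation) {
    lift_warn("(quasi-)separation: coefficients reported at the iteration cap",
              "liftrisk_separation")
  }
  list(model = model, separation = separation)
}

#' Fit the pruned binary logistic-regression risk classifier
#'
#' Maximum-likelihood logistic regression of the risk class (RISK coded 1)
#' on the supplied features, followed by iterative backward pruning: at each
#' round every feature with Wald p-value above `alpha` or odds ratio within
#' `or_epsilon` of 1 is dropped and the model refitted, until the feature set
#' is stable or `max_rounds` is reached. Evaluation is by resubstitution
#' (apparent performance on the fitting data), the protocol of the
#' original analysis; no train/test split is attempted.
#'
#' @param table Feature table (typically after outlier removal).
#' @param features Candidate predictors (post-correlation-pruning names).
#' @param alpha Significance threshold for pruning (default 0.05).
#' @param or_epsilon Features with `|OR - 1| <= or_epsilon` are considered
#'   uninformative and dropped (default 0.01).
#' @param p_criterion P-value used for pruning decisions: `"lrt"` (default)
#'   uses per-feature likelihood-ratio tests ([stats::drop1()]), which stay
#'   valid when a feature separates the classes (the Wald statistic
#'   collapses to non-significance in exactly that case, the Hauck-Donner
#'   effect); `"wald"` uses the Wald p-values of the coefficient table.
#' @param pruning `"stepwise"` (default) removes one feature per round -- the
#'   weakest Wald p-value above `alpha`, or failing that the feature with
#'   odds ratio closest to 1 within `or_epsilon` -- and refits; this is
#'   ordinary backward elimination and is robust to the Wald-statistic
#'   deflation that collinear predictors suffer. `"batch"` removes every
#'   offending feature in one round before refitting.
#' @param max_rounds Maximum pruning rounds (default: one per candidate
#'   feature for `"stepwise"`, 10 for `"batch"`).
#' @return Object of class `lift_model`: final glm fit, coefficient table
#'   (log-odds, odds ratios, Wald p-values), per-round pruning history,
#'   events-per-variable ratio, confusion matrix and apparent
#'   accuracy/sensitivity/specificity (percent).
#' @export
fit_risk_model <- function(table, features, alpha = 0.05, or_epsilon = 0.01,
                           pruning = c("stepwise", "batch"),
                           p_criterion = c("lrt", "wald"),
                           max_rounds = NULL) {
  pruning <- match.arg(pruning)
  p_criterion <- match.arg(p_criterion)
  max_rounds <- max_rounds %||% if (pruning == "stepwise") length(features) else 10
  dat <- prepare_model_frame(table, features)
  current <- features
  history <- list()
  fit <- NULL
  for (round in seq_len(max_rounds)) {
    if (!length(current)) break
    fit <- fit_logistic(dat, current)
    s <- summary(fit$model)$coefficients
    rows <- rownames(s) != "(Intercept)"
    term <- gsub("`", "", rownames(s)[rows])
    or <- exp(s[rows, "Estimate"])
    p <- if (p_criterion == "lrt") {
      # drop1 refits without each term; on (quasi-)separated data those
      # refits re-emit the fitted-probabilities warning already flagged
      d1 <- withCallingHandlers(
        stats::drop1(fit$model, test = "LRT"),
        warning = function(w) {
          if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      stats::setNames(d1[["Pr(>Chi)"]][-1], gsub("`", "", rownames(d1)[-1]))[term]
    } else {
      s[rows, "Pr(>|z|)"]
    }
    offending <- p > alpha | abs(or - 1) <= or_epsilon
    drop <- if (pruning == "batch") {
      offending
    } else if (any(p > alpha)) {
      seq_along(term) == which.max(p)        # weakest feature only
    } else if (any(offending)) {
      seq_along(term) == which.min(abs(or - 1))
    } else {
      rep(FALSE, length(term))
    }
    history[[round]] <- tibble::tibble(
      round = round, feature = term, estimate = s[rows, "Estimate"],
      odds_ratio = or, p_value = p, dropped = drop
    )
    if (!any(drop)) break
    current <- term[!drop]
  }
  if (length(current)) {
    fit <- fit_logistic(dat, current)  # refit on the final feature set
  }
  if (!length(current)) {
    prob <- rep(mean(dat$.y), nrow(dat))
    fit <- NULL
  } else {
    prob <- predict(fit$model, type = "response")
  }
  pred <- ifelse(prob >= 0.5, "RISK", "NO_RISK")
  truth <- ifelse(dat$.y == 1, "RISK", "NO_RISK")
  metrics <- evaluate_classification(pred, truth)
  class_sizes <- table(truth)
  coef_tbl <- if (length(current)) {
    s <- summary(fit$model)$coefficients
    rows <- rownames(s) != "(Intercept)"
    tibble::tibble(
      feature = gsub("`", "", rownames(s)[rows]),
      estimate = s[rows, "Estimate"],
      std_error = s[rows, "Std. Error"],
      odds_ratio = exp(s[rows, "Estimate"]),
      p_value = s[rows, "Pr(>|z|)"]
    )
  } else {
    tibble::tibble(feature = character(0), estimate = numeric(0),
                   std_error = numeric(0), odds_ratio = numeric(0),
                   p_value = numeric(0))
  }
  structure(list(
    model = if (length(current)) fit$model else NULL,
    separation = if (length(current)) fit$separation else FALSE,
    candidate_features = features,
    final_features = current,
    coefficients = coef_tbl,
    pruning_history = dplyr::bind_rows(history),
    events_per_variable = if (length(current)) {
      min(class_sizes) / length(current)
    } else NA_real_,
    confusion = metrics$confusion,
    accuracy = metrics$accuracy,
    sensitivity = metrics$sensitivity,
    specificity = metrics$specificity,
    n = nrow(dat),
    protocol = "apparent (resubstitution)"
  ), class = "lift_model")
}

#' Confusion matrix and classification metrics
#'
#' Builds the 2x2 confusion matrix (rows = true class, columns = predicted;
#' class order NO_RISK, RISK) and the three headline percentages, each
#' rounded half-up to one decimal: accuracy = 100 (TP + TN) / total,
#' sensitivity = percentage of NO_RISK instances classified correctly and
#' specificity = percentage of RISK instances classified correctly (the
#' NO_RISK row is the sensitivity row in this convention).
#'
#' @param predictions,labels Equal-length vectors with values `"NO_RISK"` /
#'   `"RISK"`.
#' @return List with `confusion` (2x2 matrix), `accuracy`, `sensitivity`,
#'   `specificity` (percent, 1 decimal) and `n_correct`.
#' @export
evaluate_classification <- function(predictions, labels) {
  lv <- c("NO_RISK", "RISK")
  if (length(predictions) != length(labels)) {
    abort("`predictions` and `labels` must have equal length")
  }
  if (!all(c(predictions, labels) %in% lv)) {
    abort('labels must be "NO_RISK" or "RISK"')
  }
  cm <- table(factor(labels, lv), factor(predictions, lv))
  classification_metrics(unclass(cm))
}

#' @rdname evaluate_classification
#' @param confusion A 2x2 count matrix (rows = true NO_RISK, RISK; columns =
#'   predicted NO_RISK, RISK), for computing the metrics directly from
#'   tabulated counts.
#' @export
classification_metrics <- function(confusion) {
  cm <- matrix(as.numeric(confusion), 2, 2,
               dimnames = list(truth = c("NO_RISK", "RISK"),
                               predicted = c("NO_RISK", "RISK")))
  total <- sum(cm)
  list(
    confusion = cm,
    n_correct = sum(diag(cm)),
    accuracy = round_half_up(100 * sum(diag(cm)) / total),
    sensitivity = round_half_up(100 * cm[1, 1] / sum(cm[1, ])),
    specificity = round_half_up(100 * cm[2, 2] / sum(cm[2, ]))
  )
}

#' @export
print.lift_model <- function(x, ...) {
  cat("<lift_model> binary logistic risk classifier\n")
  cat(sprintf("  features: %d candidates -> %d final\n",
              length(x$candidate_features), length(x$final_features)))
  cat(sprintf("  events per variable: %s\n",
              if (is.na(x$events_per_variable)) "n/a"
              else sprintf("%.2f", x$events_per_variable)))
  if (x$separation) cat("  warning: (quasi-)separation detected\n")
  cat(sprintf("  %s: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              x$protocol, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Tidy the coefficient table of a fitted risk classifier
#' @param x A `lift_model` object.
#' @param ... Unused.
#' @return Tibble with one row per retained feature (estimate, standard
#'   error, odds ratio, Wald p-value).
#' @export
tidy.lift_model <- function(x, ...) x$coefficients

#' One-row model summary of a fitted risk classifier
#' @param x A `lift_model` object.
#' @param ... Unused.
#' @return One-row tibble: instance count, feature counts,
#'   events-per-variable, apparent accuracy/sensitivity/specificity.
#' @export
glance.lift_model <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_candidate_features = length(x$candidate_features),
    n_final_features = length(x$final_features),
    events_per_variable = x$events_per_variable,
    separation = x$separation,
    accuracy = x$accuracy,
    sensitivity = x$sensitivity,
    specificity = x$specificity
  )
}
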