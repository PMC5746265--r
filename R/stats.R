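#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples.  The exact
#' null distribution is used when `n1 + n2 <= 20` and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param x,y numeric samples (both nonempty).
#' @param variable optional variable name carried into the result.
#' @return object of class `group_comparison` with the U statistic and
#'   two-sided P value.
#' @export
mann_whitney <- function(x, y, variable = NA_character_) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 20L) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  structure(list(variable = variable, test = "mann_whitney",
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 exact = exact,
                 summary = data.frame(
                   group = c("x", "y"), n = c(length(x), length(y)),
                   median = c(median(x), median(y)),
                   mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y)))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s%s: statistic = %.4g, P = %.4g\n",
              x$test, if (is.na(x$variable)) "" else
                paste0(" [", x$variable, "]"),
              x$statistic, x$p_value))
  invisible(x)
}

#' Categorical group comparison
#'
#' Fisher's exact test when any expected cell count is below 5,
#' otherwise the chi-square test without continuity correction.
#'
#' @param tab a 2 x k contingency table of nonnegative integer counts.
#' @param variable optional variable name.
#' @return object of class `group_comparison`.
#' @export
categorical_test <- function(tab, variable = NA_character_) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an all-zero margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- fisher.test(tab)
    structure(list(variable = variable, test = "fisher",
                   statistic = NA_real_, p_value = ft$p.value,
                   table = tab), class = "group_comparison")
  } else {
    ct <- chisq.test(tab, correct = FALSE)
    structure(list(variable = variable, test = "chi_square",
                   statistic = unname(ct$statistic), p_value = ct$p.value,
                   table = tab), class = "group_comparison")
  }
}

#' Prune intercorrelated candidate predictors
#'
#' Builds a graph on the candidate variables with an edge wherever the
#' absolute Spearman rank correlation reaches `R_threshold` with
#' correlation P < 0.05; within each connected component only the
#' variable with the smallest group-comparison P value is kept
#' (lexicographic name as tie-break).
#'
#' @param table data.frame holding the candidate columns.
#' @param candidates character vector of column names (screened
#'   significant).
#' @param p_values named numeric vector of their screening P values.
#' @param R_threshold absolute Spearman correlation defining an edge
#'   (default 0.7).
#' @return list with `kept` (character), `components` (list), and the
#'   `edges` data.frame.
#' @export
spearman_prune <- function(table, candidates, p_values, R_threshold = 0.7) {
  if (length(candidates) == 0L)
    return(list(kept = character(0), components = list(),
                edges = data.frame()))
  missing_vars <- setdiff(candidates, names(table))
  if (length(missing_vars))
    stop("candidate variable(s) missing from table: ",
         paste(missing_vars, collapse = ", "))
  if (!all(candidates %in% names(p_values)))
    stop("p_values must be named for every candidate")
  if (R_threshold <= 0 || R_threshold >= 1)
    stop("R_threshold must lie in (0, 1)")
  k <- length(candidates)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- list()
  if (k > 1) {
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      ct <- suppressWarnings(
        cor.test(table[[candidates[a]]], table[[candidates[b]]],
                 method = "spearman", exact = FALSE))
      if (abs(ct$estimate) >= R_threshold && ct$p.value < 0.05) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
        edges[[length(edges) + 1L]] <-
          data.frame(var1 = candidates[a], var2 = candidates[b],
                     rho = unname(ct$estimate), p = ct$p.value)
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  comps <- split(candidates, roots)
  kept <- vapply(comps, function(vars) {
    p <- p_values[vars]
    vars[order(p, vars)][1]        # smallest P, name as tie-break
  }, character(1))
  list(kept = unname(sort(kept)), components = unname(comps),
       edges = if (length(edges)) do.call(rbind, edges) else data.frame())
}

logistic_fit_table <- function(fit, terms) {
  sm <- summary(fit)$coefficients
  rows <- intersect(terms, rownames(sm))
  data.frame(term = rows,
             coefficient = sm[rows, 1],
             se = sm[rows, 2],
             odds_ratio = exp(sm[rows, 1]),
             ci_low = exp(sm[rows, 1] - 1.96 * sm[rows, 2]),
             ci_high = exp(sm[rows, 1] + 1.96 * sm[rows, 2]),
             p_value = sm[rows, 4],
             row.names = NULL)
}

check_separation <- function(fit) {
  eps <- 1e-8
  fit$converged && !any(fit$fitted.values > 1 - eps | fit$fitted.values < eps)
}

#' Univariate logistic regression
#'
#' Maximum-likelihood logistic fit of a binary outcome on one predictor;
#' odds ratio per unit with a 95% Wald interval.  Perfectly separated
#' fits are flagged, not silently reported.
#'
#' @param x numeric predictor.
#' @param labels binary outcome (factor or 0/1), both classes present.
#' @param variable optional predictor name.
#' @return object of class `logistic_fit`.
#' @export
univariate_logistic <- function(x, labels, variable = "x") {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  df <- data.frame(y = y, x = x)
  names(df)[2] <- variable
  fit <- suppressWarnings(
    glm(stats::reformulate(variable, "y"), data = df, family = binomial()))
  structure(list(terms = logistic_fit_table(fit, variable),
                 converged = check_separation(fit),
                 log_likelihood = as.numeric(logLik(fit)),
                 fit = fit),
            class = "logistic_fit")
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) as.integer(labels == levels(labels)[2])
  else if (is.logical(labels)) as.integer(labels)
  else if (all(labels %in% c(0, 1))) as.integer(labels)
  else stop("labels must be binary (0/1, logical, or a two-level factor)")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$converged)
    cat("WARNING: fit flagged (non-convergence or separation)\n")
  if (nrow(x$terms) == 0) {
    cat("intercept-only model\n")
  } else {
    tt <- x$terms
    for (r in seq_len(nrow(tt)))
      cat(sprintf("%s: OR %.3f (%.3f-%.3f), P = %.4g\n", tt$term[r],
                  tt$odds_ratio[r], tt$ci_low[r], tt$ci_high[r],
                  tt$p_value[r]))
  }
  invisible(x)
}

#' Stepwise backward multivariate logistic regression
#'
#' Starts from the full model and repeatedly removes the term with the
#' largest removal P value (likelihood-ratio test by default) while that
#' P is at or above `threshold`, refitting after each removal.
#'
#' @param table data.frame with the predictor columns.
#' @param variables character vector of predictors for the full model.
#' @param labels binary outcome.
#' @param threshold removal threshold (default 0.10).
#' @param criterion `"LRT"` (default) or `"Wald"` removal P values.
#' @return a `logistic_fit` with the final model plus a `trail`
#'   data.frame of the removal sequence.
#' @export
backward_stepwise <- function(table, variables, labels, threshold = 0.10,
                              criterion = c("LRT", "Wald")) {
  criterion <- match.arg(criterion)
  if (length(variables) < 1L) stop("need at least one variable")
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  df <- cbind(data.frame(y = y), table[, variables, drop = FALSE])
  current <- variables
  trail <- list()
  repeat {
    form <- if (length(current)) stats::reformulate(current, "y") else y ~ 1
    fit <- suppressWarnings(glm(form, data = df, family = binomial()))
    if (length(current) == 0L) break
    if (criterion == "LRT") {
      d1 <- suppressWarnings(drop1(fit, test = "LRT"))
      pv <- d1[["Pr(>Chi)"]][-1]
      names(pv) <- rownames(d1)[-1]
    } else {
      sm <- summary(fit)$coefficients
      pv <- sm[match(current, rownames(sm)), 4]
      names(pv) <- current
    }
    worst <- names(pv)[order(-pv, names(pv))][1]
    if (is.na(pv[worst]) || pv[worst] >= threshold) {
      trail[[length(trail) + 1L]] <-
        data.frame(removed = worst, p_removal = unname(pv[worst]))
      current <- setdiff(current, worst)
    } else break
  }
  structure(list(terms = logistic_fit_table(fit, current),
                 variables = current,
                 converged = check_separation(fit),
                 log_likelihood = as.numeric(logLik(fit)),
                 trail = if (length(trail)) do.call(rbind, trail)
                 else data.frame(removed = character(0),
                                 p_removal = numeric(0)),
                 threshold = threshold, criterion = criterion,
                 fit = fit),
            class = "logistic_fit")
}

#' ROC curve analysis
#'
#' Empirical ROC over all score thresholds; AUC equals the Mann-Whitney
#' U statistic over `n1 * n2` (ties counted one half), 95% CI by DeLong,
#' and the reported cutoff maximizes the Youden index `J = sensitivity +
#' specificity - 1` (ties broken toward higher specificity).
#'
#' @param scores numeric predictor.
#' @param labels binary outcome (second factor level / 1 = event).
#' @param variable optional name.
#' @return object of class `roc_result`.
#' @export
roc_analysis <- function(scores, labels, variable = NA_character_) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (length(unique(scores)) < 2L) {
    warning("constant scores: AUC 0.5, cutoff undefined")
    return(structure(list(variable = variable, auc = 0.5,
                          ci = c(NA_real_, NA_real_), cutoff = NA_real_,
                          sensitivity = NA_real_, specificity = NA_real_,
                          direction = "undefined", flag = "constant-scores"),
                     class = "roc_result"))
  }
  ## (pROC warns that the DeLong interval of a degenerate AUC = 1 curve
  ## collapses; the reported CI is still the honest answer)
  r <- suppressWarnings(
    pROC::roc(response = y, predictor = scores, quiet = TRUE,
              direction = "auto", ci = TRUE, ci.method = "delong"))
  co <- pROC::coords(r, x = "all", ret = c("threshold", "sensitivity",
                                           "specificity"),
                     transpose = FALSE)
  J <- co$sensitivity + co$specificity - 1
  best <- which(J >= max(J) - 1e-12)
  best <- best[order(-co$specificity[best])][1]   # tie: higher specificity
  structure(list(variable = variable, auc = as.numeric(pROC::auc(r)),
                 ci = as.numeric(r$ci)[c(1, 3)],
                 cutoff = co$threshold[best],
                 sensitivity = co$sensitivity[best],
                 specificity = co$specificity[best],
                 direction = if (r$direction == "<")
                   "higher-score-event" else "lower-score-event",
                 flag = "ok"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC%s: AUC %.3f (95%% CI %.3f-%.3f), cutoff %.4g (sens %.2f, spec %.2f)\n",
              if (is.na(x$variable)) "" else paste0(" [", x$variable, "]"),
              x$auc, x$ci[1], x$ci[2], x$cutoff, x$sensitivity,
              x$specificity))
  invisible(x)
}
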