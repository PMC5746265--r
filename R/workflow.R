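#' Full recurrence-prediction workflow
#'
#' Executes, in order: (1) group screening — Mann-Whitney U for every
#' continuous variable, Fisher/chi-square for categorical ones; (2) the
#' P < 0.05 inclusion gate on the continuous screen; (3) Spearman
#' collinearity pruning of the gated set (each cluster of variables with
#' |R| above the threshold is represented by its lowest-P member); (4)
#' univariate logistic regression per kept variable; (5) stepwise
#' backward multivariate logistic regression on the kept set; (6) ROC
#' analysis per gated variable.  Records with missing analyzed fields are
#' dropped (count reported).
#'
#' @param cohort cohort data.frame with a two-level `group` column
#'   (`stable`/`recurrence`).
#' @param continuous character vector of continuous variable names
#'   (default: all numeric columns except identifiers).
#' @param categorical character vector of categorical variable names
#'   (default: factor/character columns except id/group).
#' @param gate_p screening inclusion threshold (default 0.05).
#' @param R_threshold Spearman pruning threshold (default 0.7).
#' @param removal_p stepwise removal threshold (default 0.10).
#' @param criterion stepwise removal criterion, `"LRT"` or `"Wald"`.
#' @return object of class `recurrence_report` with elements
#'   `screening`, `pruning`, `univariate`, `multivariate`, `roc`, and
#'   `config`.
#' @export
run_full_workflow <- function(cohort, continuous = NULL,
                              categorical = NULL, gate_p = 0.05,
                              R_threshold = 0.7, removal_p = 0.10,
                              criterion = c("LRT", "Wald")) {
  criterion <- match.arg(criterion)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  ## --- validation -----------------------------------------------------
  stage("screening", {
    if (!is.data.frame(cohort) || nrow(cohort) == 0L)
      stop("empty cohort")
    if (!"group" %in% names(cohort)) stop("cohort has no group column")
  })
  cohort$group <- factor(cohort$group, levels = c("stable", "recurrence"))
  if (is.null(continuous))
    continuous <- setdiff(names(cohort)[vapply(cohort, is.numeric,
                                               logical(1))], "id")
  if (is.null(categorical))
    categorical <- setdiff(names(cohort)[vapply(cohort, function(c)
      is.factor(c) || is.character(c), logical(1))], c("id", "group"))
  used <- c(continuous, categorical, "group")
  keep <- complete.cases(cohort[, used, drop = FALSE])
  n_dropped <- sum(!keep)
  cohort <- cohort[keep, , drop = FALSE]
  stage("screening", {
    if (nrow(cohort) == 0L) stop("no complete records")
    if (length(unique(cohort$group)) < 2L)
      stop("both outcome groups must be present")
  })
  g <- cohort$group

  ## --- 1. screening ---------------------------------------------------
  screening <- stage("screening", {
    rows <- lapply(continuous, function(v) {
      mw <- mann_whitney(cohort[[v]][g == "stable"],
                         cohort[[v]][g == "recurrence"], variable = v)
      data.frame(variable = v, test = "mann_whitney",
                 statistic = mw$statistic, p_value = mw$p_value)
    })
    crows <- lapply(categorical, function(v) {
      tab <- table(g, cohort[[v]])
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      ct <- categorical_test(tab, variable = v)
      data.frame(variable = v, test = ct$test,
                 statistic = if (is.null(ct$statistic)) NA_real_
                 else ct$statistic, p_value = ct$p_value)
    })
    do.call(rbind, c(rows, crows))
  })

  ## --- 2. gate + 3. pruning -------------------------------------------
  cont_scr <- screening[screening$test == "mann_whitney", ]
  gated <- cont_scr$variable[cont_scr$p_value < gate_p]
  pvals <- setNames(cont_scr$p_value, cont_scr$variable)
  pruning <- stage("pruning", spearman_prune(cohort, gated, pvals,
                                             R_threshold = R_threshold))

  ## --- 4. univariate logistic -----------------------------------------
  univariate <- stage("univariate", {
    if (length(pruning$kept) == 0L) NULL else
      do.call(rbind, lapply(pruning$kept, function(v) {
        fit <- univariate_logistic(cohort[[v]], g, variable = v)
        cbind(fit$terms, converged = fit$converged)
      }))
  })

  ## --- 5. multivariate stepwise ---------------------------------------
  multivariate <- stage("multivariate", {
    if (length(pruning$kept) == 0L) NULL else
      backward_stepwise(cohort, pruning$kept, g, threshold = removal_p,
                        criterion = criterion)
  })

  ## --- 6. ROC per gated variable --------------------------------------
  roc <- stage("roc", {
    if (length(gated) == 0L) NULL else
      do.call(rbind, lapply(gated, function(v) {
        r <- suppressWarnings(roc_analysis(cohort[[v]], g, variable = v))
        data.frame(variable = v, auc = r$auc, ci_low = r$ci[1],
                   ci_high = r$ci[2], cutoff = r$cutoff,
                   sensitivity = r$sensitivity,
                   specificity = r$specificity, direction = r$direction)
      }))
  })

  structure(list(screening = screening, gated = gated, pruning = pruning,
                 univariate = univariate, multivariate = multivariate,
                 roc = roc,
                 config = list(gate_p = gate_p, R_threshold = R_threshold,
                               removal_p = removal_p,
                               criterion = criterion,
                               cutoff_rule = "youden",
                               auc_ci = "delong",
                               n = nrow(cohort), n_dropped = n_dropped)),
            class = "recurrence_report")
}

#' @export
print.recurrence_report <- function(x, ...) {
  cat("== Recurrence prediction report ==\n")
  cat(sprintf("n = %d records (%d dropped incomplete)\n", x$config$n,
              x$config$n_dropped))
  cat("\n-- Screening (group comparison) --\n")
  scr <- x$screening
  scr$p_value <- signif(scr$p_value, 3)
  print(scr, row.names = FALSE)
  cat(sprintf("\nGate P < %.2g: %s\n", x$config$gate_p,
              if (length(x$gated)) paste(x$gated, collapse = ", ")
              else "(none)"))
  cat(sprintf("Kept after Spearman pruning (|R| >= %.2f): %s\n",
              x$config$R_threshold,
              if (length(x$pruning$kept)) paste(x$pruning$kept,
                                                collapse = ", ")
              else "(none)"))
  if (!is.null(x$univariate)) {
    cat("\n-- Univariate logistic regression --\n")
    uv <- x$univariate
    uv[2:7] <- lapply(uv[2:7], signif, 3)
    print(uv, row.names = FALSE)
  }
  if (!is.null(x$multivariate)) {
    cat("\n-- Multivariate (stepwise backward) --\n")
    print(x$multivariate)
  }
  if (!is.null(x$roc)) {
    cat("\n-- ROC --\n")
    rc <- x$roc
    rc[2:7] <- lapply(rc[2:7], signif, 3)
    print(rc, row.names = FALSE)
  }
  invisible(x)
}
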