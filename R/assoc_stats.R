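# Association and survival statistics: Pearson chi-square, Mann-Whitney U,
# Kaplan-Meier, log-rank, multivariate Cox proportional hazards.

#' Pearson chi-square test of independence
#'
#' Classic Pearson statistic on an r x c contingency table with expected
#' counts from the margins; two-sided p from the chi-square distribution with
#' (r-1)(c-1) degrees of freedom. No continuity correction by default —
#' recomputation of published LGG clinical association tables matches only
#' the uncorrected statistic. Yates correction is available for 2x2 tables
#' behind `correct = TRUE`.
#'
#' @param counts nonnegative integer matrix, at least 2x2.
#' @param correct apply Yates continuity correction (2x2 only).
#' @return list with `statistic`, `df`, `p`, `expected`.
#' @export
pearson_chi2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop_data("contingency table must be at least 2x2")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop_data("counts must be finite and nonnegative")
  }
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0) || any(cs == 0)) stop_data("zero row or column margin")
  expected <- outer(rs, cs) / n
  dev <- abs(counts - expected)
  if (correct) {
    if (!all(dim(counts) == c(2L, 2L))) {
      stop_cfg("continuity correction only defined for 2x2 tables")
    }
    dev <- pmax(dev - 0.5, 0)
  }
  stat <- sum(dev^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

# Midrank-based U statistic for sample x versus y.
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p by full enumeration of group assignments when the combined sample
#' size is at most `exact_max` (ties handled through midranks, so identical
#' multisets give p = 1 exactly); tie-corrected normal approximation (no
#' continuity correction) otherwise. Two-sided p is `2 * min(tail
#' probabilities)`, capped at 1.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max combined-size cutoff for exact enumeration (default 20).
#' @return list with `U` (for `x`), `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 20L) {
  if (length(x) == 0L || length(y) == 0L) stop_data("empty sample in U test")
  nx <- length(x); ny <- length(y); n <- nx + ny
  u <- u_statistic(x, y)
  if (n <= exact_max) {
    r <- rank(c(x, y))
    idx <- utils::combn(n, nx)
    offset <- nx * (nx + 1) / 2
    us <- colSums(matrix(r[idx], nrow = nx)) - offset
    p <- 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9))
    list(U = u, p = min(1, p), method = "exact")
  } else {
    mu <- nx * ny / 2
    tie <- table(c(x, y))
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = u, p = 1, method = "normal"))
    z <- (u - mu) / sqrt(sigma2)
    list(U = u, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
  }
}

check_survival_records <- function(time, event) {
  if (length(time) == 0L) stop_data("no survival records")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop_data("survival times must be positive")
  }
  if (!all(event %in% c(0, 1))) stop_data("event must be 0/1")
  invisible(NULL)
}

#' Kaplan-Meier estimate and median overall survival
#'
#' Product-limit estimator of the survival function. The median is the
#' earliest time at which the estimated survival drops to 0.5 or below
#' (reported as `NA` when the curve never reaches 0.5, e.g. under heavy
#' censoring).
#'
#' @param time positive event/censoring times (days).
#' @param event 0/1 event indicator (1 = death observed).
#' @return list with step-curve vectors `time`, `surv`, `n_risk`, `n_event`
#'   and scalar `median`.
#' @export
km_estimate <- function(time, event) {
  check_survival_records(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, censored = TRUE)
  med <- {
    drop <- which(fit$surv <= 0.5 + 1e-12)
    if (length(drop)) fit$time[drop[1]] else NA_real_
  }
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, median = med)
}

#' Log-rank test between survival groups
#'
#' Standard log-rank chi-square with `groups - 1` degrees of freedom.
#'
#' @param time,event survival records.
#' @param group group labels (at least two non-empty groups).
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  check_survival_records(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop_data("log-rank test needs at least two non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron handling of tied event times
#' (day-resolution data produce moderate ties). Collinear covariates are
#' rejected before fitting; suspected complete separation (runaway
#' coefficients) is flagged rather than silently reported.
#'
#' @param data data.frame containing `time`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @return list with `table` (coef, HR, se, z, p per covariate),
#'   `loglik`, `iter`, `separation_flag`.
#' @export
cox_fit <- function(data, covariates) {
  check_survival_records(data$time, data$event)
  if (sum(data$event) < 2L) stop_data("need at least 2 events for Cox fit")
  X <- stats::model.matrix(
    stats::reformulate(covariates), data = data)[, -1, drop = FALSE]
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    stop_data("collinear covariates in Cox model: rank-deficient design")
  }
  f <- stats::reformulate(covariates,
                          response = "survival::Surv(time, event)")
  fit <- survival::coxph(f, data = data, ties = "efron")
  sm <- summary(fit)
  tab <- data.frame(
    covariate = rownames(sm$coefficients),
    coef = sm$coefficients[, "coef"],
    HR = sm$coefficients[, "exp(coef)"],
    se = sm$coefficients[, "se(coef)"],
    z = sm$coefficients[, "z"],
    p = sm$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, loglik = fit$loglik, iter = fit$iter,
       separation_flag = any(abs(tab$coef) > 15))
}
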