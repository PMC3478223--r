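#' Aggregate per-nucleus features to per-patient medians
#'
#' Feature tables report one value per patient: the median over that
#' patient's nuclei (even counts: mean of the two central order
#' statistics). Patients with fewer than `min_nuclei` nuclei are rejected;
#' the published protocol measured at least 100 nuclei per patient, and the
#' threshold is configurable for small test cohorts.
#'
#' @param features data.frame with a `patient_id` column and numeric
#'   feature columns
#' @param min_nuclei minimum nuclei per patient (default 100)
#' @return data.frame, one row per patient, of feature medians
#' @export
aggregate_patient <- function(features, min_nuclei = 100L) {
  stopifnot(is.data.frame(features), "patient_id" %in% names(features))
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  num <- setdiff(num, c("patient_id"))
  cnt <- table(features$patient_id)
  bad <- names(cnt)[cnt < min_nuclei]
  if (length(bad)) {
    stop("too few nuclei (< ", min_nuclei, ") for patient(s): ",
         paste(bad, collapse = ", "))
  }
  ids <- sort(unique(features$patient_id))
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (f in num) {
    out[[f]] <- vapply(ids, function(p) {
      stats::median(features[[f]][features$patient_id == p])
    }, numeric(1))
  }
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' U statistic with midrank ties. The p-value is exact (from the null
#' distribution of U) when `n_x + n_y <= 16` and there are no ties;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric samples
#' @return list of class `ctx_test`: `statistic` (U of `x`), `p_value`,
#'   `method`
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  nx <- length(x); ny <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v) # midranks
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(all_v))
  if (!ties && nx + ny <= 16L) {
    # exact two-sided p: twice the smaller tail of the Wilcoxon U null law
    p <- 2 * min(stats::pwilcox(U, nx, ny),
                 1 - stats::pwilcox(U - 1, nx, ny))
    p <- min(1, p)
    method <- "mann_whitney_exact"
  } else {
    N <- nx + ny
    tj <- table(all_v)
    tiecorr <- sum(tj^3 - tj) / (N * (N - 1))
    sigma2 <- nx * ny / 12 * ((N + 1) - tiecorr)
    mu <- nx * ny / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "mann_whitney_normal"
  }
  structure(list(statistic = U, p_value = p, method = method),
            class = "ctx_test")
}

#' @export
print.ctx_test <- function(x, ...) {
  cat(sprintf("<%s: statistic = %.6g, p = %.4g>\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

# all permutations of 1..n as an n! x n matrix (n <= 8 in practice)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Spearman rank-order correlation (two-sided)
#'
#' rho is the Pearson correlation of midranks. For `n <= 8` the p-value is
#' exact by full permutation enumeration; otherwise it comes from the
#' t approximation with `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric samples, `n >= 3`
#' @return `ctx_test` list: `statistic` (rho), `p_value`, `method`
#' @export
spearman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y must be paired (equal length)")
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input vector: Spearman rho undefined")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "spearman_exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      t <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(t), n - 2)
    }
    method <- "spearman_t"
  }
  structure(list(statistic = rho, p_value = p, method = method),
            class = "ctx_test")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the binomial tails by bisection to 1e-10: the lower limit solves
#' `P(X >= successes | n, p) = (1 - level)/2` (0 when `successes = 0`), the
#' upper limit solves `P(X <= successes | n, p) = (1 - level)/2` (1 when
#' `successes = n`).
#'
#' @param successes,n counts, `0 <= successes <= n`
#' @param level confidence level in (0, 1), default 0.95
#' @return list of class `proportion_ci`: `successes`, `n`, `estimate`,
#'   `level`, `lower`, `upper`
#' @export
clopper_pearson_ci <- function(successes, n, level = 0.95) {
  if (!is.numeric(successes) || !is.numeric(n) ||
      successes != round(successes) || n != round(n) ||
      successes < 0 || n < 1 || successes > n) {
    stop("need integer counts with 0 <= successes <= n, n >= 1")
  }
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  alpha <- (1 - level) / 2
  bisect <- function(f, lo = 0, hi = 1) {
    # f increasing; find p with f(p) = 0
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-12) break
    }
    (lo + hi) / 2
  }
  lower <- if (successes == 0) 0 else {
    # P(X >= s | p) increases with p
    bisect(function(p) (1 - stats::pbinom(successes - 1, n, p)) - alpha)
  }
  upper <- if (successes == n) 1 else {
    # P(X <= s | p) decreases with p
    bisect(function(p) alpha - stats::pbinom(successes, n, p))
  }
  structure(list(successes = as.integer(successes), n = as.integer(n),
                 estimate = successes / n, level = level,
                 lower = lower, upper = upper),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("<%d/%d = %.1f%%; %g%% exact CI %.4f - %.4f>\n",
              x$successes, x$n, 100 * x$estimate, 100 * x$level,
              x$lower, x$upper))
  invisible(x)
}

# Breslow partial log-likelihood, score and information for one covariate,
# optionally stratified. Data must be ordered arbitrarily; handled here.
cox_loglik <- function(beta, time, event, x, strata) {
  ll <- 0; U <- 0; I <- 0
  for (s in unique(strata)) {
    sel <- strata == s
    t <- time[sel]; d <- event[sel]; z <- x[sel]
    ez <- exp(beta * z)
    for (tt in sort(unique(t[d == 1]))) {
      at_risk <- t >= tt
      dies <- (t == tt) & (d == 1)
      dk <- sum(dies)
      s0 <- sum(ez[at_risk])
      s1 <- sum(ez[at_risk] * z[at_risk])
      s2 <- sum(ez[at_risk] * z[at_risk]^2)
      ll <- ll + beta * sum(z[dies]) - dk * log(s0)
      U <- U + sum(z[dies]) - dk * s1 / s0
      I <- I + dk * (s2 / s0 - (s1 / s0)^2)
    }
  }
  list(ll = ll, U = U, I = I)
}

cox_fit <- function(time, event, x, strata = NULL, tol = 1e-8,
                    max_iter = 50L, beta_bound = 50) {
  if (is.null(strata)) strata <- rep(1L, length(time))
  keep <- !is.na(time) & !is.na(event) & !is.na(x)
  time <- time[keep]; event <- event[keep]; x <- x[keep]
  strata <- strata[keep]
  if (sum(event) < 2) stop("need at least 2 events for Cox regression")
  # information requires within-stratum covariate variation among at-risk sets
  informative <- vapply(unique(strata), function(s) {
    sel <- strata == s
    sum(event[sel]) >= 1 && length(unique(x[sel])) > 1L
  }, logical(1))
  if (!any(informative)) {
    stop("covariate is constant within every stratum carrying events: ",
         "no information for Cox regression")
  }
  beta <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    der <- cox_loglik(beta, time, event, x, strata)
    if (der$I <= 0) break
    step <- der$U / der$I
    # dampen huge steps (monotone-likelihood escape)
    if (abs(step) > 5) step <- sign(step) * 5
    beta <- beta + step
    if (abs(beta) > beta_bound) break # monotone likelihood
    if (abs(step) < tol) { converged <- TRUE; break }
  }
  der <- cox_loglik(beta, time, event, x, strata)
  se <- if (der$I > 0) 1 / sqrt(der$I) else NA_real_
  z <- beta / se
  list(coefficient = beta, se = se,
       p_value = 2 * stats::pnorm(-abs(z)),
       converged = converged && abs(beta) <= beta_bound)
}

#' Univariate Cox proportional-hazards regression
#'
#' Single-covariate partial-likelihood maximization with Breslow tie
#' handling, Newton-Raphson to 1e-8 (max 50 iterations). The Wald z gives
#' the p-value. Monotone likelihood (perfect separation; coefficient
#' drifting beyond +-50) is flagged with `converged = FALSE` instead of
#' diverging silently.
#'
#' @param patients data.frame with `time`, `event`, and covariate columns
#' @param covariate name of the covariate column
#' @return list of class `cox_result`: `coefficient` (B), `se`, `p_value`,
#'   `stratified`, `converged`
#' @export
cox_univariate <- function(patients, covariate) {
  stopifnot(is.data.frame(patients),
            all(c("time", "event", covariate) %in% names(patients)))
  x <- patients[[covariate]]
  if (length(unique(x)) < 2L) stop("covariate '", covariate, "' is constant")
  fit <- cox_fit(patients$time, patients$event, x)
  structure(c(fit, list(covariate = covariate, stratified = FALSE)),
            class = "cox_result")
}

#' Stratified Cox proportional-hazards regression
#'
#' The Breslow partial likelihood is the product of within-stratum terms,
#' so the strata variable's own (possibly confounding) effect is removed;
#' a covariate that is informative only through its association with the
#' strata loses its signal here. Strata without events contribute nothing.
#'
#' @inheritParams cox_univariate
#' @param strata name of the stratification column
#' @return `cox_result` with `stratified = TRUE`
#' @export
cox_stratified <- function(patients, covariate, strata) {
  stopifnot(is.data.frame(patients),
            all(c("time", "event", covariate, strata) %in% names(patients)))
  x <- patients[[covariate]]
  st <- patients[[strata]]
  fit <- cox_fit(patients$time, patients$event, x, strata = st)
  structure(c(fit, list(covariate = covariate, stratified = TRUE)),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox%s %s: B = %+.4g, p = %.4g%s>\n",
              if (x$stratified) " (stratified)" else "",
              x$covariate, x$coefficient, x$p_value,
              if (!x$converged) ", NOT converged (monotone likelihood?)" else ""))
  invisible(x)
}
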