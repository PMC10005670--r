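#' Fit a logistic response model
#'
#' Maximum-likelihood fit of a binomial model with logit link (iteratively
#' reweighted least squares, via [stats::glm()]). Collinear columns are
#' dropped with their coefficients reported as `NA`. Complete or
#' quasi-complete separation is detected (fitted probabilities numerically
#' 0/1) and the fit is redone with a tiny ridge penalty (1e-6) so that the
#' coefficients stay finite; the condition is reported in `separation`.
#'
#' @param outcome binary vector (0/1 or logical); 1 is the event class.
#' @param design numeric matrix or data frame of covariates (no intercept
#'   column; one is added).
#' @return object of class `logistic_fit`: `coefficients`, `log_lik`,
#'   `null_log_lik`, `fitted` (probabilities), `converged`, `separation`.
#' @export
fit_logistic <- function(outcome, design = NULL) {
  y <- as.numeric(outcome)
  stopifnot(all(y %in% 0:1))
  if (length(unique(y)) < 2)
    stop("outcome has a single class; logistic model undefined")
  X <- if (is.null(design) || NCOL(design) == 0)
    matrix(numeric(0), nrow = length(y), ncol = 0)
  else as.matrix(design)
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  dat <- data.frame(.y = y, X, check.names = FALSE)
  form <- if (ncol(X) == 0) .y ~ 1 else
    stats::reformulate(sprintf("`%s`", colnames(X)), response = ".y")

  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- stats::coef(fit)
  fitted <- stats::fitted(fit)
  converged <- fit$converged
  if (separation) {
    keep <- !is.na(coefs)
    Xr <- cbind(`(Intercept)` = 1, X)[, keep, drop = FALSE]
    b <- ridge_irls(y, Xr, lambda = 1e-6)
    coefs[keep] <- b
    eta <- as.numeric(Xr %*% b)
    fitted <- stats::plogis(eta)
  }
  ll <- bernoulli_log_lik(y, fitted)
  p0 <- mean(y)
  ll0 <- bernoulli_log_lik(y, rep(p0, length(y)))
  structure(list(coefficients = coefs, log_lik = ll, null_log_lik = ll0,
                 fitted = fitted, converged = converged,
                 separation = separation),
            class = "logistic_fit")
}

# internal: Bernoulli log-likelihood, probabilities clamped away from 0/1
bernoulli_log_lik <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# internal: ridge-penalised IRLS for the logit model (separation fallback)
ridge_irls <- function(y, X, lambda = 1e-6, max_iter = 100, tol = 1e-8) {
  b <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% b)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    grad <- crossprod(X, y - p) - lambda * b
    H <- crossprod(X * w, X) + lambda * diag(ncol(X))
    step <- solve(H, grad)
    b <- b + step
    if (sqrt(sum(grad^2)) < tol) break
  }
  as.numeric(b)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> logLik ", signif(x$log_lik, 6),
      " (null ", signif(x$null_log_lik, 6), "), McFadden R2 ",
      signif(mcfadden_r2(x), 4),
      if (x$separation) " [separation: ridge fallback]", "\n", sep = "")
  invisible(x)
}

#' McFadden's pseudo R-squared
#'
#' `1 - logLik(model) / logLik(null)` for a logistic model — the
#' likelihood-based analogue of explained variance; 0 when the model adds
#' nothing over the intercept, approaching 1 under near-perfect
#' separation.
#'
#' @param fit a `logistic_fit` or a binomial [stats::glm()] object.
#' @return proportion in `[0, 1)`.
#' @export
mcfadden_r2 <- function(fit) {
  if (inherits(fit, "glm")) {
    ll <- as.numeric(stats::logLik(fit))
    ll0 <- as.numeric(stats::logLik(stats::update(fit, . ~ 1)))
  } else {
    ll <- fit$log_lik; ll0 <- fit$null_log_lik
  }
  if (ll0 == 0) stop("null log-likelihood is zero; pseudo R2 undefined")
  max(0, 1 - ll / ll0)
}

#' Explained-variance contribution of a GRS over clinical covariates
#'
#' Fits nested least-squares models `outcome ~ covariates` and
#' `outcome ~ covariates + grs` and returns the R-squared increase — the
#' share of outcome variance the score explains beyond age, sex and BMI.
#' Nonnegative by construction. Rank-deficient covariate sets are handled
#' by [stats::lm()]'s pivoting (dropped columns, with a warning).
#'
#' @param outcome continuous outcome vector (e.g. TG change in mmol/L).
#' @param covariates numeric matrix/data frame of adjustment covariates, or
#'   `NULL` for none.
#' @param grs numeric GRS vector.
#' @return proportion in `[0, 1]` (multiply by 100 to report as percent).
#' @export
delta_r2 <- function(outcome, covariates, grs) {
  y <- as.numeric(outcome)
  n <- length(y)
  stopifnot(length(grs) == n)
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(X) && nrow(X) != n) stop("covariate rows must match outcome")
  k <- if (is.null(X)) 0 else ncol(X)
  if (n <= k + 3) stop("too few observations for the nested fits")
  r2 <- function(Z) {
    f <- if (is.null(Z)) stats::lm(y ~ 1) else stats::lm(y ~ Z)
    1 - sum(stats::residuals(f)^2) / sum((y - mean(y))^2)
  }
  max(0, r2(cbind(X, grs = grs)) - r2(X))
}

#' Two-sided unpaired t-test between groups
#'
#' Welch's unequal-variance form. The degenerate case of two exactly
#' constant groups is resolved directly: p = 1 for equal means, p = 0
#' otherwise.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return list with `statistic` and `p`.
#' @export
group_ttest <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    same <- mean(values_a) == mean(values_b)
    return(list(statistic = if (same) 0 else Inf, p = if (same) 1 else 0))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value)
}

#' Genotype-by-visit interaction test for a paired two-visit design
#'
#' Tests whether the TG change across the supplementation differs by
#' genotype, adjusting for covariates. With one measurement before and one
#' after per subject, the genotype-by-visit interaction contrast of a
#' random-intercept mixed model reduces algebraically to the genotype
#' coefficient of a change-score regression
#' `(tg_post - tg_baseline) ~ dosage + covariates`; that regression is what
#' is fit here, and the returned p-value is the coefficient's two-sided
#' t-test.
#'
#' @param tg_baseline,tg_post paired TG measurements (mmol/L).
#' @param dosage minor-allele dosage vector.
#' @param covariates optional numeric matrix/data frame (e.g. age, sex
#'   indicator, BMI).
#' @return list with `p`, `estimate` (mmol/L change per allele copy) and
#'   `statistic`.
#' @export
snp_visit_interaction <- function(tg_baseline, tg_post, dosage,
                                  covariates = NULL) {
  stopifnot(length(tg_baseline) == length(tg_post),
            length(dosage) == length(tg_baseline))
  if (stats::var(dosage, na.rm = TRUE) == 0 || all(is.na(dosage)))
    stop("dosage is monomorphic; interaction test undefined")
  delta <- tg_post - tg_baseline
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  fit <- if (is.null(X)) stats::lm(delta ~ dosage)
         else stats::lm(delta ~ dosage + X)
  tab <- summary(fit)$coefficients
  list(p = tab["dosage", "Pr(>|t|)"],
       estimate = tab["dosage", "Estimate"],
       statistic = tab["dosage", "t value"])
}

# internal: clinical covariate matrix (age, male indicator, BMI, optionally
# baseline TG) from a subject table; sex reference level is female
clinical_covariates <- function(subjects, baseline_tg = FALSE) {
  X <- cbind(age = subjects$age,
             sex_male = as.numeric(subjects$sex == "male"),
             bmi = subjects$bmi)
  if (baseline_tg) X <- cbind(X, tg_baseline = subjects$tg_baseline)
  X
}
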