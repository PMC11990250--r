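#' Mixed-effects association of one component with one outcome
#'
#' Fits `outcome ~ score + age + sex + (1 | site)` by REML and reports
#' the component's fixed-effect coefficient, its Wald standard error,
#' the two-sided Wald p-value, and the sign of the association. A
#' boundary fit (zero estimated site variance) is reported with a
#' warning rather than an error.
#'
#' @param component_scores numeric vector of per-subject component
#'   scores (the canonical variate).
#' @param outcome numeric outcome-change vector.
#' @param age,sex fixed-effect covariates.
#' @param site grouping factor (>= 2 levels).
#' @return An `association_result` data frame row: `coefficient`,
#'   `std_error`, `p_value`, `sign`, `n`, `singular_fit`.
#' @export
fit_lme_association <- function(component_scores, outcome, age, sex, site) {
  d <- data.frame(score = component_scores, outcome = outcome,
                  age = age, sex = sex, site = factor(site))
  d <- stats::na.omit(d)
  if (nlevels(droplevels(d$site)) < 2)
    stop("site must have at least 2 levels")
  fit <- suppressMessages(
    lme4::lmer(outcome ~ score + age + sex + (1 | site), data = d,
               REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")))
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("site random-intercept variance estimated at the boundary (0); ",
            "reporting the boundary fit")
  cf <- summary(fit)$coefficients
  est <- cf["score", "Estimate"]
  se <- cf["score", "Std. Error"]
  p <- 2 * stats::pnorm(-abs(est / se))
  out <- data.frame(coefficient = est, std_error = se, p_value = p,
                    sign = ifelse(est >= 0, "+", "-"), n = nrow(d),
                    singular_fit = singular)
  class(out) <- c("association_result", "data.frame")
  out
}

# marginal (fixed-effects) R^2: var of fixed-effect predictions over
# total outcome variance decomposition (fixed + random intercept + residual)
marginal_r2 <- function(fit) {
  fe <- as.numeric(stats::model.matrix(fit) %*% lme4::fixef(fit))
  vf <- stats::var(fe)
  vc <- lme4::VarCorr(fit)
  vr <- sum(vapply(vc, function(m) m[1, 1], numeric(1)))
  ve <- attr(vc, "sc")^2
  vf / (vf + vr + ve)
}

#' Outcome variance explained by the combined latent components
#'
#' Fits two random-intercept models — covariates only
#' (`outcome ~ age + sex + (1|site)`) and covariates plus all supplied
#' components from both views — and returns 100 times the increment in
#' the marginal (fixed-effects) R-squared. Negative increments are
#' clamped to 0 (flagged via the `"clamped"` attribute), since the
#' marginal R-squared of nested mixed models is not guaranteed monotone.
#'
#' @param gm_components n x a matrix of components from the first view.
#' @param fa_components n x b matrix of components from the second view.
#' @param outcome numeric outcome vector.
#' @param age,sex covariates.
#' @param site grouping factor.
#' @return Percent of outcome variance attributed to the components.
#' @export
variance_explained <- function(gm_components, fa_components, outcome,
                               age, sex, site) {
  gm <- as.matrix(gm_components); fa <- as.matrix(fa_components)
  n <- length(outcome)
  if (ncol(gm) + ncol(fa) >= n)
    stop("more components than subjects; the combined model would overfit")
  comps <- cbind(gm, fa)
  colnames(comps) <- sprintf("c%02d", seq_len(ncol(comps)))
  d <- data.frame(outcome = outcome, age = age, sex = sex,
                  site = factor(site), comps)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  f0 <- suppressMessages(lme4::lmer(outcome ~ age + sex + (1 | site),
                                    data = d, REML = TRUE, control = ctrl))
  rhs <- paste(c("age", "sex", colnames(comps)), collapse = " + ")
  f1 <- suppressMessages(lme4::lmer(
    stats::as.formula(paste("outcome ~", rhs, "+ (1 | site)")),
    data = d, REML = TRUE, control = ctrl))
  inc <- 100 * (marginal_r2(f1) - marginal_r2(f0))
  clamped <- inc < 0
  out <- max(inc, 0)
  attr(out, "clamped") <- clamped
  out
}

#' Cross-method correlation of component variates
#'
#' All-pairs Pearson correlations between two sets of component
#' variates over the same subjects, with the t-based two-sided p-value;
#' pairs are retained when `|r|` exceeds `threshold` (sign flips between
#' methods are expected and handled by the absolute-value rule).
#'
#' @param variates_a n x k1 matrix (e.g. linear CCA components).
#' @param variates_b n x k2 matrix (e.g. DCCAE components).
#' @param threshold retention threshold on `|r|` (default 0.15).
#' @return A `correlation_table` data frame: `index_a`, `index_b`, `r`,
#'   `p`; attribute `threshold`.
#' @export
cross_method_correlation <- function(variates_a, variates_b,
                                     threshold = 0.15) {
  A <- as.matrix(variates_a); B <- as.matrix(variates_b)
  if (nrow(A) != nrow(B)) stop("variate sets must share subjects (rows)")
  n <- nrow(A)
  R <- stats::cor(A, B)
  idx <- which(abs(R) > threshold, arr.ind = TRUE)
  out <- data.frame(index_a = idx[, 1], index_b = idx[, 2],
                    r = R[idx])
  out$p <- correlation_significance(out$r, n)
  out <- out[order(out$index_a, out$index_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("correlation_table", "data.frame")
  out
}
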