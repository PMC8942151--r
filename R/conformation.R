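# Acinar conformation analysis: fit the power law S = k * V^n over a breath
# by ordinary least squares on the log-log scale, and classify the
# conformational regime by the exponent (n = 2/3 isotropic balloon-like
# inflation, n < 2/3 predominantly ductal expansion, 2/3 < n < 1
# predominantly alveolar expansion, n ~ 1 recruitment-like behaviour).

#' Fit the surface-volume power law S = k * V^n
#'
#' Ordinary least squares of log(S) on log(V) (natural logs); the exponent n
#' is the slope and k = exp(intercept). Both the inflation and deflation
#' limbs of the breath are pooled by default.
#'
#' @param V,S positive volume and surface-area series of equal length >= 3.
#'   Alternatively `V` may be a `roi_series` object, in which case its `V`
#'   and `S` columns are used.
#' @param limb "both" (default), "inflation" or "deflation": which half of
#'   the breath to fit when exploring hysteresis (phases up to / from the
#'   volume peak).
#' @return an object of class `svn_fit` with components `n`, `k`,
#'   `r_squared`, `n_points`, `regime`, and the underlying `lm` fit.
#' @export
svn_fit <- function(V, S = NULL, limb = c("both", "inflation", "deflation")) {
  limb <- match.arg(limb)
  if (inherits(V, "roi_series")) {
    S <- V$series$S
    V <- V$series$V
  }
  V <- as.numeric(V); S <- as.numeric(S)
  assert_that(length(V) == length(S), "V and S must have equal length")
  assert_that(length(V) >= 3, "need at least 3 points to fit S = k V^n")
  assert_that(all(V > 0) && all(S > 0), "V and S must be strictly positive")
  if (limb != "both") {
    peak <- which.max(V)
    sel <- if (limb == "inflation") seq_len(peak) else peak:length(V)
    V <- V[sel]; S <- S[sel]
    assert_that(length(V) >= 3, "selected limb has fewer than 3 points")
  }
  lv <- log(V); ls <- log(S)
  assert_that(stats::var(lv) > 0, "V has zero variance on the log scale")
  fit <- lm(ls ~ lv)
  n <- unname(coef(fit)[2])
  k <- exp(unname(coef(fit)[1]))
  ss_tot <- sum((ls - mean(ls))^2)
  r2 <- 1 - sum(fit$residuals^2) / ss_tot
  structure(
    list(n = n, k = k, r_squared = r2, n_points = length(V),
         regime = classify_regime(n), V = V, S = S, limb = limb, lm = fit),
    class = "svn_fit"
  )
}

#' Classify the conformational regime from the exponent
#'
#' @param fit an `svn_fit` object or a bare exponent.
#' @param tol half-width of the band treated as consistent with a reference
#'   exponent (default 0.03, the typical between-ROI spread).
#' @return one of "ductal_dominant", "isotropic", "alveolar_dominant",
#'   "recruitment_like".
#' @export
classify_regime <- function(fit, tol = 0.03) {
  n <- if (inherits(fit, "svn_fit")) fit$n else as.numeric(fit)
  if (n < 2 / 3 - tol) "ductal_dominant"
  else if (n <= 2 / 3 + tol) "isotropic"
  else if (n < 1 - tol) "alveolar_dominant"
  else "recruitment_like"
}

#' @export
print.svn_fit <- function(x, digits = 4, ...) {
  cat(sprintf("S = k V^n fit (%d points, %s limb)\n", x$n_points, x$limb))
  cat(sprintf("  n = %.*g, k = %.*g, R^2 = %.4f\n", digits, x$n, digits, x$k,
              x$r_squared))
  cat(sprintf("  regime: %s\n", x$regime))
  invisible(x)
}

#' @export
summary.svn_fit <- function(object, ...) {
  s <- summary(object$lm)
  out <- list(
    n = object$n, k = object$k, r_squared = object$r_squared,
    n_se = s$coefficients[2, 2], log_k_se = s$coefficients[1, 2],
    n_points = object$n_points, regime = object$regime,
    residual_sd = s$sigma)
  class(out) <- "summary.svn_fit"
  out
}

#' @export
print.summary.svn_fit <- function(x, ...) {
  cat("Surface-volume power law S = k V^n (log-log OLS)\n")
  cat(sprintf("  n       = %.4f (SE %.4f)\n", x$n, x$n_se))
  cat(sprintf("  k       = %.4g (SE of log k %.4f)\n", x$k, x$log_k_se))
  cat(sprintf("  R^2     = %.4f on %d points; residual sd %.4g\n",
              x$r_squared, x$n_points, x$residual_sd))
  cat(sprintf("  regime  = %s\n", x$regime))
  invisible(x)
}

#' @export
coef.svn_fit <- function(object, ...) c(k = object$k, n = object$n)

#' @export
predict.svn_fit <- function(object, newdata = NULL, ...) {
  V <- if (is.null(newdata)) object$V
  else if (is.list(newdata)) newdata$V else as.numeric(newdata)
  object$k * V^object$n
}

#' @export
residuals.svn_fit <- function(object, type = c("log", "response"), ...) {
  type <- match.arg(type)
  if (type == "log") unname(stats::residuals(object$lm))
  else object$S - predict(object)
}

#' @export
plot.svn_fit <- function(x, ...) {
  graphics::plot(log(x$V), log(x$S), xlab = "log V", ylab = "log S",
                 main = sprintf("S = kV^n: n = %.3f (%s)", x$n, x$regime), ...)
  graphics::abline(log(x$k), x$n, col = "red3")
  invisible(x)
}

#' @export
simulate.svn_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- summary(object$lm)$sigma
  out <- replicate(nsim, object$k * object$V^object$n *
                     exp(rnorm(length(object$V), 0, sigma)), simplify = FALSE)
  as.data.frame(setNames(out, paste0("sim_", seq_len(nsim))))
}

#' Summarise exponents across regions of interest
#'
#' @param fits list of `svn_fit` objects (or numeric exponents), one per ROI.
#' @param ids optional ROI identifiers.
#' @param digits rounding applied to the reported mean and SD (2, matching
#'   the conventional presentation).
#' @return object of class `svn_table`: data.frame of per-ROI exponents plus
#'   `mean_n` and `sd_n`.
#' @export
summarize_rois <- function(fits, ids = NULL, digits = 2) {
  assert_that(length(fits) >= 1, "need at least one fit")
  ns <- vapply(fits, function(f) if (inherits(f, "svn_fit")) f$n else as.numeric(f),
               numeric(1))
  ks <- vapply(fits, function(f) if (inherits(f, "svn_fit")) f$k else NA_real_,
               numeric(1))
  if (is.null(ids)) ids <- paste0("R", seq_along(ns))
  tab <- data.frame(roi = ids, n = ns, k = ks)
  structure(
    list(table = tab,
         mean_n = round(mean(ns), digits),
         sd_n = if (length(ns) > 1) round(sd(ns), digits) else 0,
         digits = digits),
    class = "svn_table"
  )
}

#' @export
print.svn_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("m +/- SD  %.*f +/- %.*f\n", x$digits, x$mean_n, x$digits, x$sd_n))
  invisible(x)
}
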