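# Frequentist (Blackwelder) design for a two-arm non-inferiority trial on a
# binary endpoint.

#' Non-inferiority sample size (Blackwelder formula)
#'
#' Per-group sample size for a one-sided non-inferiority comparison of two
#' proportions:
#' \deqn{n = \frac{(z_{1-\alpha} + z_{1-\beta})^2\,
#'                 [p_S(1-p_S) + p_E(1-p_E)]}{(\delta - (p_S - p_E))^2}}
#' where \eqn{\delta} is the non-inferiority margin and the denominator is
#' the distance of the expected loss of effect to the margin. The variance
#' term is invariant to coding the endpoint as success or failure
#' (p and 1-p give the same `p(1-p)`), so either convention may be used.
#' By default the per-group value is rounded up (`ceiling`) and doubled;
#' reports print all intermediates so alternative rounding conventions can
#' be compared.
#'
#' @param p_standard expected outcome proportion, standard therapy.
#' @param p_new expected outcome proportion, new therapy.
#' @param margin non-inferiority margin \eqn{\delta} (proportion, > 0).
#' @param alpha one-sided significance level.
#' @param power intended power \eqn{1-\beta}.
#' @param z_alpha,z_beta optional overrides for the normal quantiles (by
#'   default computed at full precision from `alpha` and `power`).
#' @return object of class `ni_design`: list with `n_per_group`, `n_total`,
#'   `n_raw` (unrounded per-group value) and all intermediates.
#' @examples
#' ni_sample_size(0.233, 0.233, margin = 0.075)
#' @export
ni_sample_size <- function(p_standard, p_new, margin, alpha = 0.05, power = 0.80,
                           z_alpha = NULL, z_beta = NULL) {
  for (p in c(p_standard, p_new))
    if (!is.finite(p) || p <= 0 || p >= 1) stop("proportions must lie in (0, 1)", call. = FALSE)
  if (margin <= 0) stop("margin must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  loss <- p_standard - p_new
  if (margin - loss <= 1e-12)
    stop("no finite sample size: expected loss of effect reaches the margin", call. = FALSE)
  if (is.null(z_alpha)) z_alpha <- stats::qnorm(1 - alpha)
  if (is.null(z_beta)) z_beta <- stats::qnorm(power)
  variance <- p_standard * (1 - p_standard) + p_new * (1 - p_new)
  n_raw <- (z_alpha + z_beta)^2 * variance / (margin - loss)^2
  n_per_group <- ceiling(n_raw)
  structure(list(p_standard = p_standard, p_new = p_new, margin = margin,
                 alpha = alpha, power = power, z_alpha = z_alpha, z_beta = z_beta,
                 variance_term = variance, denominator = (margin - loss)^2,
                 n_raw = n_raw, n_per_group = n_per_group,
                 n_total = 2 * n_per_group,
                 rounding = "ceiling per group, then doubled"),
            class = "ni_design")
}

#' @export
print.ni_design <- function(x, ...) {
  cat("<ni_design> one-sided non-inferiority sample size\n")
  cat(sprintf("  p_standard = %g, p_new = %g, margin = %g\n",
              x$p_standard, x$p_new, x$margin))
  cat(sprintf("  alpha = %g (z = %.6f), power = %g (z = %.6f)\n",
              x$alpha, x$z_alpha, x$power, x$z_beta))
  cat(sprintf("  variance term = %.6f, squared margin distance = %.6f\n",
              x$variance_term, x$denominator))
  cat(sprintf("  n per group (raw) = %.4f -> %.0f (%s)\n",
              x$n_raw, x$n_per_group, x$rounding))
  cat(sprintf("  n total = %.0f\n", x$n_total))
  invisible(x)
}

#' One-sided non-inferiority test for two proportions
#'
#' Tests H0: `p_new <= p_standard - margin` (the new therapy is inferior by
#' more than the margin) against non-inferiority, using the normal
#' approximation with the sample-proportion standard error. Non-inferiority
#' is concluded when `z > qnorm(1 - alpha)`.
#'
#' @param x_standard,n_standard outcome count and size, standard arm.
#' @param x_new,n_new outcome count and size, new arm.
#' @param margin non-inferiority margin (proportion).
#' @param alpha one-sided significance level.
#' @return list with `z`, one-sided `p_value`, logical `non_inferior`,
#'   estimates and the critical value.
#' @export
ni_test <- function(x_standard, n_standard, x_new, n_new, margin, alpha = 0.05) {
  stopifnot(n_standard >= 1, n_new >= 1,
            x_standard >= 0, x_standard <= n_standard,
            x_new >= 0, x_new <= n_new)
  ps <- x_standard / n_standard
  pe <- x_new / n_new
  se <- sqrt(ps * (1 - ps) / n_standard + pe * (1 - pe) / n_new)
  if (se == 0)
    stop("degenerate data: both sample proportions are 0 or 1, standard error is zero",
         call. = FALSE)
  z <- (pe - ps + margin) / se
  crit <- stats::qnorm(1 - alpha)
  list(z = z, p_value = stats::pnorm(z, lower.tail = FALSE),
       non_inferior = z > crit, critical = crit,
       p_standard_hat = ps, p_new_hat = pe, se = se)
}
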