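# Inferential conventions: Spearman correlation with exact small-n
# p-values, one-way ANOVA with Tukey HSD, and the D'Agostino-Pearson
# normality gate.

#' Spearman rank correlation with exact small-sample p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties averaged). The
#' two-tailed p-value is exact by full permutation enumeration for
#' n <= `exact_max` (default 9) and uses the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} otherwise; the method used is
#' recorded in the result.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact_max largest n for exact permutation enumeration.
#' @return list with `rho`, `p`, `method` (`"exact"` or `"t"`), `n`.
#'   A constant input gives `rho = NA` with `method = "undefined"`.
#' @examples
#' spearman_cor(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearman_cor <- function(x, y, exact_max = 9) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, method = "undefined", n = n))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- e1071::permutations(n)
    cx <- rx - mean(rx)
    sums <- matrix(ry[perms], nrow(perms)) %*% cx
    rho_all <- sums / ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "t"
  }
  list(rho = rho, p = min(p, 1), method = method, n = n)
}

#' One-way ANOVA with Tukey's multiple-comparison test
#'
#' Classic (ordinary) one-way ANOVA across groups, followed by Tukey HSD
#' pairwise comparisons from the studentized range distribution with
#' Tukey-Kramer handling of unequal group sizes (via `stats::TukeyHSD`).
#' Degenerate inputs (zero within-group variance everywhere) are flagged:
#' identical groups give F = 0 and all pairwise p = 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups of >= 2
#'   values), or a data.frame with `value` and `group` columns.
#' @return an `anova_tukey` result: list with `F`, `p`, `df_between`,
#'   `df_within`, `tukey` (data.frame `comparison`, `diff`, `p_adj`),
#'   `degenerate`.
#' @examples
#' anova_tukey(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(8, 9, 10)))
#' @export
anova_tukey <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("value", "group") %in% names(groups))) {
      stopf("data.frame input needs `value` and `group` columns")
    }
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2) stopf("need >= 2 groups")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) stopf("every group needs >= 2 values")
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), sizes),
                                  levels = names(groups)))
  k <- length(groups)
  n <- nrow(df)
  pairs <- utils::combn(names(groups), 2)
  cmp <- paste(pairs[2, ], pairs[1, ], sep = "-")
  within_var <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                           numeric(1)))
  if (within_var < 1e-24) {
    means <- vapply(groups, mean, numeric(1))
    if (max(means) - min(means) < 1e-12) {
      tukey <- data.frame(comparison = cmp, diff = 0, p_adj = 1)
      return(structure(list(F = 0, p = 1, df_between = k - 1,
                            df_within = n - k, tukey = tukey,
                            degenerate = TRUE),
                       class = "anova_tukey"))
    }
    dif <- means[pairs[2, ]] - means[pairs[1, ]]
    tukey <- data.frame(comparison = cmp, diff = unname(dif),
                        p_adj = ifelse(abs(dif) > 1e-12, 0, 1))
    return(structure(list(F = Inf, p = 0, df_between = k - 1,
                          df_within = n - k, tukey = tukey,
                          degenerate = TRUE),
                     class = "anova_tukey"))
  }
  fit <- stats::aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  th <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(th), diff = th[, "diff"],
                      p_adj = th[, "p adj"], row.names = NULL)
  structure(list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
                 df_between = s[["Df"]][1], df_within = s[["Df"]][2],
                 tukey = tukey, degenerate = FALSE),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("<anova_tukey> F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p,
              if (x$degenerate) " (degenerate: zero within-group variance)"
              else ""))
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' D'Agostino-Pearson omnibus normality gate
#'
#' The omnibus K-squared statistic combines the z-transformed sample
#' skewness (D'Agostino) and kurtosis (Anscombe-Glynn) and is referred to
#' a chi-squared distribution with 2 df. A high p-value (> `alpha`,
#' default 0.05) recommends the parametric branch; otherwise the
#' nonparametric branch. The test needs n >= 8; below that the gate
#' abstains.
#'
#' @param values numeric sample.
#' @param alpha gate level (default 0.05).
#' @return list with `statistic` (K-squared), `p`, `z_skew`, `z_kurt`,
#'   `recommendation` (`"parametric"`, `"nonparametric"` or `"abstain"`),
#'   `n`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 8) {
    return(list(statistic = NA_real_, p = NA_real_,
                z_skew = NA_real_, z_kurt = NA_real_,
                recommendation = "abstain", n = n,
                message = sprintf("n = %d below the test's validity floor of 8", n)))
  }
  m2 <- mean((x - mean(x))^2)
  if (m2 < 1e-24) stopf("constant data: moments undefined")
  m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # D'Agostino (1970) skewness z
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  a <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / a + sqrt((y / a)^2 + 1))

  # Anscombe-Glynn (1983) kurtosis z
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a_k <- 6 + 8 / sqrt_beta1 * (2 / sqrt_beta1 +
                                 sqrt(1 + 4 / sqrt_beta1^2))
  z_kurt <- ((1 - 2 / (9 * a_k)) -
               ((1 - 2 / a_k) / (1 + xk * sqrt(2 / (a_k - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a_k))

  k2 <- z_skew^2 + z_kurt^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  list(statistic = k2, p = p, z_skew = z_skew, z_kurt = z_kurt,
       recommendation = if (p > alpha) "parametric" else "nonparametric",
       n = n)
}
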