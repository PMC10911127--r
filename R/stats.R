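# Normality-gated test selection and group-comparison reporting: all groups
# are tested for normality (D'Agostino-Pearson omnibus; Shapiro-Wilk when a
# group is too small for the moment-based test), then a parametric or
# nonparametric comparison is chosen, with a multiple-comparison-corrected
# post hoc for omnibus designs.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe & Glynn 1983) into K2 = Zs^2 + Zk^2, chi-squared with 2 df
#' under normality. Requires n >= 8 for the kurtosis transformation to be
#' defined.
#'
#' @param x Numeric vector (n >= 8).
#' @return An `htest`-like list: `statistic` (K2), `p.value`, `z_skew`,
#'   `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("zero variance")
  b1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2
  # skewness transformation
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  y <- ifelse(y == 0, 1e-30, y)
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transformation
  E <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - E) / sqrt(varb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  term1 <- 1 - 2 / (9 * A)
  denom <- 1 + xk * sqrt(2 / (A - 4))
  term2 <- sign(denom) * abs((1 - 2 / A) / abs(denom))^(1 / 3)
  z_kurt <- (term1 - term2) / sqrt(2 / (9 * A))
  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p.value = stats::pchisq(k2, 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, method = "D'Agostino-Pearson")
}

.group_normal <- function(x, alpha) {
  p <- if (length(x) < 8L) shapiro.test(x)$p.value
       else dagostino_pearson(x)$p.value
  list(p = p, normal = p > alpha,
       method = if (length(x) < 8L) "shapiro_wilk" else "dagostino_pearson")
}

#' Choose the comparison test from group normality
#'
#' Every group is tested for normality (D'Agostino-Pearson; Shapiro-Wilk
#' when n < 8). If all groups pass, the parametric test is selected
#' (Student's t for two groups, one-way ANOVA for more); otherwise the
#' nonparametric counterpart (Mann-Whitney, Kruskal-Wallis). With more than
#' two groups, multiple-comparison correction of the post hoc is enabled.
#'
#' @param groups Named list of numeric vectors (each n >= 3).
#' @param paired Paired two-group design.
#' @param normality_alpha Alpha for the normality gate (default 0.05).
#' @return An object of class `comparison_plan`.
#' @examples
#' set.seed(1)
#' plan <- select_test(list(a = rnorm(30), b = rnorm(30, 1)))
#' plan$chosen_test
#' @export
select_test <- function(groups, paired = FALSE, normality_alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- vapply(groups, length, 1L)
  if (any(ns < 3L))
    stop("each group needs n >= 3 (got ", min(ns), ")")
  norm <- lapply(groups, .group_normal, alpha = normality_alpha)
  all_normal <- all(vapply(norm, `[[`, TRUE, "normal"))
  k <- length(groups)
  chosen <- if (k == 2L) {
    if (all_normal) "t" else "mann_whitney"
  } else {
    if (all_normal) "anova" else "kruskal_wallis"
  }
  structure(list(groups = groups, paired = paired,
                 normality_alpha = normality_alpha,
                 normality = data.frame(
                   group = names(groups), n = ns,
                   p = vapply(norm, `[[`, 0, "p"),
                   method = vapply(norm, `[[`, "", "method"),
                   normal = vapply(norm, `[[`, TRUE, "normal"),
                   row.names = NULL),
                 chosen_test = chosen,
                 multiple_comparison = k > 2L),
            class = "comparison_plan")
}

#' @export
print.comparison_plan <- function(x, ...) {
  cat("comparison plan:", x$chosen_test,
      if (x$multiple_comparison) "(with multiple-comparison correction)" else "",
      "\n")
  print(x$normality)
  invisible(x)
}

#' Run the planned group comparison
#'
#' Executes the plan's chosen test; for omnibus tests a pairwise post hoc
#' with the configured correction is run, and medians/quartiles per group
#' are reported alongside.
#'
#' @param plan A [select_test()] result.
#' @param correction p-adjustment for the post hoc (default `"holm"`).
#' @return List: `test`, `statistic`, `p_value`, `posthoc` (pairwise
#'   adjusted p matrix, or `NULL`), `group_summary`.
#' @export
run_comparison <- function(plan, correction = "holm") {
  stopifnot(inherits(plan, "comparison_plan"))
  g <- plan$groups
  vars <- vapply(g, var, 0)
  if (any(vars == 0))
    stop("zero-variance group: ", names(g)[which(vars == 0)[1]])
  values <- unlist(g, use.names = FALSE)
  labels <- factor(rep(names(g), vapply(g, length, 1L)), levels = names(g))
  res <- switch(plan$chosen_test,
    t = {
      ht <- t.test(g[[1]], g[[2]], paired = plan$paired, var.equal = TRUE)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    mann_whitney = {
      ht <- if (plan$paired)
        wilcox.test(g[[1]], g[[2]], paired = TRUE, exact = FALSE)
      else wilcox.test(g[[1]], g[[2]], exact = FALSE)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    anova = {
      fit <- aov(values ~ labels)
      sm <- summary(fit)[[1]]
      list(statistic = sm[["F value"]][1], p_value = sm[["Pr(>F)"]][1])
    },
    kruskal_wallis = {
      ht <- kruskal.test(values, labels)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    })
  posthoc <- NULL
  if (plan$multiple_comparison) {
    posthoc <- if (plan$chosen_test == "anova")
      stats::pairwise.t.test(values, labels, p.adjust.method = correction)$p.value
    else
      stats::pairwise.wilcox.test(values, labels, p.adjust.method = correction,
                                  exact = FALSE)$p.value
  }
  summ <- do.call(rbind, lapply(names(g), function(nm) {
    q <- quantile(g[[nm]], c(0.25, 0.5, 0.75))
    data.frame(group = nm, n = length(g[[nm]]), q1 = q[[1]],
               median = q[[2]], q3 = q[[3]])
  }))
  list(test = plan$chosen_test, statistic = res$statistic,
       p_value = res$p_value, posthoc = posthoc, group_summary = summ)
}
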