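## Group statistics for the quantification pipeline: classical one-way ANOVA,
## Dunnett's many-to-one post-test (own critical-value computation), the
## Student-Newman-Keuls all-pairwise stepwise procedure, viability
## normalization and dose-response summarization.

# --- groups -----------------------------------------------------------------

as_groups <- function(groups, min_n = 2L) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list of numeric vectors or a value/group data frame")
  groups <- lapply(groups, function(v) as.numeric(v[is.finite(v)]))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < min_n))
    stop("every group needs n >= ", min_n, " (offending: ",
         paste(names(groups)[ns < min_n], collapse = ", "), ")")
  groups
}

group_moments <- function(groups) {
  ns <- vapply(groups, length, integer(1))
  ms <- vapply(groups, mean, numeric(1))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  k <- length(groups); N <- sum(ns)
  list(n = ns, mean = ms, ssw = ssw, k = k, N = N,
       df_within = N - k, mse = ssw / (N - k))
}

new_test_result <- function(method, statistic, p_value, alpha = NA_real_,
                            comparisons = NULL, df = NULL) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 alpha = alpha, comparisons = comparisons, df = df),
            class = "mt_test_result")
}

#' @export
print.mt_test_result <- function(x, ...) {
  cat(sprintf("<%s>", x$method))
  if (length(x$statistic) == 1L && !is.null(x$p_value) && length(x$p_value) == 1L)
    cat(sprintf(" statistic = %.4g, p = %.4g", x$statistic, x$p_value))
  cat("\n")
  if (!is.null(x$comparisons)) print(x$comparisons, digits = 4)
  invisible(x)
}

# --- one-way ANOVA ----------------------------------------------------------

#' Classical one-way ANOVA
#'
#' Equal-variance F test with (k - 1, N - k) degrees of freedom.
#'
#' @param groups named list of numeric vectors (each `n >= 2`) or a data frame
#'   with `value` and `group` columns.
#' @return an `mt_test_result` with the F statistic, p-value and df.
#' @export
one_way_anova <- function(groups) {
  groups <- as_groups(groups)
  if (length(groups) < 2L) stop("ANOVA needs >= 2 groups")
  gm <- group_moments(groups)
  if (gm$ssw <= 0)
    stop("degenerate-variance error: zero within-group variance in every group")
  grand <- sum(gm$n * gm$mean) / gm$N
  ssb <- sum(gm$n * (gm$mean - grand)^2)
  f <- (ssb / (gm$k - 1)) / gm$mse
  new_test_result("one_way_anova", statistic = c(F = f),
                  p_value = pf(f, gm$k - 1, gm$df_within, lower.tail = FALSE),
                  df = c(df1 = gm$k - 1, df2 = gm$df_within))
}

# --- Dunnett many-to-one ----------------------------------------------------

# Gauss-Hermite nodes/weights for the standard normal weight (probabilists'),
# and Gauss-Legendre nodes/weights on (0, 1), via Golub-Welsch.
gauss_hermite_prob <- function(n) {
  J <- diag(0, n)
  b <- sqrt(seq_len(n - 1))
  J[cbind(1:(n - 1), 2:n)] <- b
  J[cbind(2:n, 1:(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}

gauss_legendre01 <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = (e$values + 1) / 2, weights = e$vectors[1, ]^2)
}

.dunnett_cache <- new.env(parent = emptyenv())

# P(max_k |T_k| <= q) for the many-to-one comparison statistics with
# correlation rho_jk = lambda_j * lambda_k and pooled-variance df. Exact
# factor-analytic reduction: condition on the shared normal factor Z0
# (Gauss-Hermite) and the pooled SD chi factor (probability-integral
# transform + Gauss-Legendre).
dunnett_cdf <- function(q, lambdas, df, nz = 48L, ns = 32L) {
  gh <- gauss_hermite_prob(nz)
  gl <- gauss_legendre01(ns)
  s <- if (is.finite(df)) sqrt(qchisq(gl$nodes, df) / df) else rep(1, ns)
  gam <- sqrt(pmax(1 - lambdas^2, 1e-12))
  vapply(q, function(qq) {
    qs <- qq * s
    P <- matrix(1, ns, nz)
    for (k in seq_along(lambdas)) {
      lz <- lambdas[k] * gh$nodes
      A <- outer(qs, lz, "-") / gam[k]
      B <- outer(-qs, lz, "-") / gam[k]
      P <- P * (pnorm(A) - pnorm(B))
    }
    sum(gl$weights * as.vector(P %*% gh$weights))
  }, numeric(1))
}

# Two-sided Dunnett critical value at family-wise level alpha (cached).
dunnett_critical <- function(lambdas, df, alpha) {
  key <- paste(c(format(round(lambdas, 8)), df, alpha), collapse = "|")
  hit <- .dunnett_cache[[key]]
  if (!is.null(hit)) return(hit)
  crit <- uniroot(function(q) dunnett_cdf(q, lambdas, df) - (1 - alpha),
                  lower = 0.5, upper = 25, tol = 1e-7)$root
  assign(key, crit, envir = .dunnett_cache)
  crit
}

#' Dunnett's many-to-one post-test
#'
#' Compares each treatment group with the control using the pooled within-group
#' variance; the family-wise critical value comes from the exact equicorrelated
#' (factor-analytic) many-to-one multivariate-t distribution, computed by
#' deterministic numerical integration (no hard-coded tables, arbitrary group
#' counts and sizes). Adjusted p-values are `1 - P(max |T| <= |t_i|)`.
#'
#' @param groups named list / data frame as in [one_way_anova()].
#' @param control_label name of the control group.
#' @param alpha family-wise significance level.
#' @return an `mt_test_result` with one row per treatment comparison
#'   (`comparison`, `estimate`, `statistic`, `p_value`, `significant`) plus
#'   the critical value in `statistic`.
#' @export
dunnett <- function(groups, control_label, alpha = 0.05) {
  groups <- as_groups(groups)
  if (!control_label %in% names(groups))
    stop("control group '", control_label, "' not present")
  if (length(groups) < 2L) stop("Dunnett needs >= 1 treatment group")
  gm <- group_moments(groups)
  if (gm$ssw <= 0) stop("degenerate-variance error: zero within-group variance")
  trt <- setdiff(names(groups), control_label)
  n0 <- gm$n[[control_label]]
  ni <- gm$n[trt]
  est <- gm$mean[trt] - gm$mean[[control_label]]
  se <- sqrt(gm$mse * (1 / ni + 1 / n0))
  tstat <- est / se
  lambdas <- sqrt(ni / (ni + n0))
  crit <- dunnett_critical(lambdas, gm$df_within, alpha)
  padj <- pmin(pmax(1 - dunnett_cdf(abs(tstat), lambdas, gm$df_within), 0), 1)
  comp <- data.frame(comparison = paste(trt, "-", control_label),
                     group = trt, estimate = unname(est),
                     statistic = unname(tstat), p_value = unname(padj),
                     significant = unname(padj < alpha),
                     stringsAsFactors = FALSE)
  new_test_result("dunnett", statistic = c(critical_value = crit),
                  p_value = min(comp$p_value), alpha = alpha,
                  comparisons = comp, df = c(df = gm$df_within))
}

# --- Student-Newman-Keuls ---------------------------------------------------

#' Student-Newman-Keuls all-pairwise stepwise procedure
#'
#' Orders the group means and tests ranges with the studentized-range
#' distribution at span-dependent critical values, largest spans first;
#' a non-significant span absorbs (protects) all comparisons nested inside it.
#' Unbalanced designs use the harmonic mean group size.
#'
#' @param groups named list / data frame as in [one_way_anova()].
#' @param alpha per-step significance level.
#' @return an `mt_test_result` with all pairwise comparisons
#'   (`comparison`, `span`, `statistic` q, `p_value`, `significant`).
#' @export
snk <- function(groups, alpha = 0.05) {
  groups <- as_groups(groups)
  if (length(groups) < 2L) stop("SNK needs >= 2 groups")
  gm <- group_moments(groups)
  if (gm$ssw <= 0) stop("degenerate-variance error: zero within-group variance")
  ord <- order(gm$mean)
  ms <- gm$mean[ord]
  labs <- names(groups)[ord]
  k <- gm$k
  nh <- k / sum(1 / gm$n)                 # harmonic mean n
  se <- sqrt(gm$mse / nh)
  blocked <- matrix(FALSE, k, k)
  rows <- list()
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      q <- (ms[j] - ms[i]) / se
      pval <- ptukey(q, span, gm$df_within, lower.tail = FALSE)
      sig <- if (blocked[i, j]) FALSE else pval < alpha
      if (!sig) {
        for (a in i:j) for (b in a:j) blocked[a, b] <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste(labs[j], "-", labs[i]),
        span = span, statistic = unname(q), p_value = unname(pval),
        significant = sig, stringsAsFactors = FALSE)
    }
  }
  comp <- do.call(rbind, rows)
  new_test_result("snk", statistic = c(q_max = max(comp$statistic)),
                  p_value = min(comp$p_value), alpha = alpha,
                  comparisons = comp, df = c(df = gm$df_within))
}

#' Two-sample t-test as a test result
#'
#' Classical pooled-variance two-sample t-test (matching the equal-variance
#' ANOVA assumptions).
#'
#' @param x,y numeric vectors.
#' @param alpha significance level.
#' @param var_equal pool the variances (default TRUE).
#' @return an `mt_test_result`.
#' @export
two_group_t <- function(x, y, alpha = 0.05, var_equal = TRUE) {
  ht <- stats::t.test(x, y, var.equal = var_equal)
  new_test_result("two_sample_t", statistic = c(t = unname(ht$statistic)),
                  p_value = ht$p.value, alpha = alpha,
                  df = c(df = unname(ht$parameter)))
}

# --- viability --------------------------------------------------------------

#' Viability as percent of the untreated control
#'
#' Scales every group's values by `100 / mean(control)`, so the control group
#' mean is exactly 100% by construction; scale-invariant in the raw
#' absorbances.
#'
#' @param groups named list / data frame of absorbances.
#' @param control_label control (untreated) group name.
#' @return object of class `viability_result`: data frame with `group`,
#'   `mean_percent`, `sem`, `n`; the control group identity is kept as an
#'   attribute.
#' @export
viability_percent <- function(groups, control_label) {
  groups <- as_groups(groups, min_n = 1L)
  if (!control_label %in% names(groups))
    stop("control group '", control_label, "' not present")
  cm <- mean(groups[[control_label]])
  if (!is.finite(cm) || cm <= 0) stop("control mean must be > 0")
  scaled <- lapply(groups, function(v) 100 * v / cm)
  out <- data.frame(
    group = names(groups),
    mean_percent = vapply(scaled, mean, numeric(1)),
    sem = vapply(scaled, function(v) sd(v) / sqrt(length(v)), numeric(1)),
    n = vapply(scaled, length, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "control") <- control_label
  attr(out, "values") <- scaled
  class(out) <- c("viability_result", "data.frame")
  out
}

# --- dose-response summary --------------------------------------------------

classify_shape <- function(flags) {
  if (!any(flags)) return("flat")
  r <- rle(flags)
  n_runs <- sum(r$values)
  if (n_runs == 1L && flags[length(flags)]) return("monotone")
  # >= 2 separated runs, or a single interior peak: non-monotone
  "bimodal"
}

#' Summarize a dose-response plate
#'
#' Normalizes the plate ([icw_normalize()] unless a `normalized_fau` column is
#' already present), computes per-concentration mean and SEM of the normalized
#' measurement, flags each concentration against the vehicle group with
#' [dunnett()], and classifies the flag pattern: `"flat"` (nothing flagged),
#' `"monotone"` (one flagged run ending at the top concentration) or
#' `"bimodal"` (two or more separated runs, or a single interior run -- i.e.
#' any non-monotone pattern).
#'
#' @param plate a plate table (`condition`, `concentration_M`, `signal_afu`,
#'   `hoechst_afu`).
#' @param control_label vehicle group condition label.
#' @param alpha family-wise level for the Dunnett flags.
#' @param measurement column holding the per-well measurement after
#'   normalization.
#' @return object of class `dose_response_summary`: list with `table`
#'   (per-concentration `condition`, `concentration_M`, `mean`, `sem`, `n`,
#'   `significant`), `shape`, `flagged_concentrations` and the Dunnett
#'   `test` result.
#' @export
dose_response_summary <- function(plate, control_label = "vehicle",
                                  alpha = 0.05, measurement = "normalized_fau") {
  stopifnot(is.data.frame(plate))
  if (!measurement %in% names(plate)) plate <- icw_normalize(plate)
  if (!control_label %in% plate$condition)
    stop("vehicle group '", control_label, "' not present")
  conc <- tapply(plate$concentration_M, plate$condition, unique)
  if (length(conc) < 4L)
    stop("need the vehicle plus >= 3 concentrations")
  ord <- names(sort(vapply(conc, min, numeric(1))))
  ord <- c(control_label, setdiff(ord, control_label))
  groups <- split(plate[[measurement]], plate$condition)[ord]
  dn <- dunnett(groups, control_label, alpha)
  tab <- data.frame(
    condition = ord,
    concentration_M = vapply(conc[ord], min, numeric(1)),
    mean = vapply(groups, mean, numeric(1)),
    sem = vapply(groups, function(v) sd(v) / sqrt(length(v)), numeric(1)),
    n = vapply(groups, length, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  tab$significant <- c(NA, dn$comparisons$significant[
    match(setdiff(ord, control_label), dn$comparisons$group)])
  flags <- tab$significant[-1]
  structure(list(table = tab, shape = classify_shape(flags),
                 flagged_concentrations = tab$concentration_M[-1][flags],
                 test = dn, alpha = alpha),
            class = "dose_response_summary")
}

#' @export
print.dose_response_summary <- function(x, ...) {
  cat(sprintf("<dose_response_summary> shape: %s; flagged: %s\n", x$shape,
              if (length(x$flagged_concentrations))
                paste(format(x$flagged_concentrations, digits = 3),
                      collapse = ", ") else "none"))
  print(x$table, digits = 4)
  invisible(x)
}
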