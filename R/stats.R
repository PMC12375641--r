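#' Friedman rank-sum test
#'
#' Omnibus test for k related conditions over n blocks (patients). Values
#' are ranked within each block (midranks on ties) and the tie-corrected
#' chi-square statistic
#' \deqn{\chi^2_F = 12 \sum_j (R_j - n(k+1)/2)^2 /
#'       [n k (k+1) - \sum_{i,g}(t^3 - t)/(k-1)]}
#' is referred to a chi-square distribution with k - 1 degrees of freedom.
#'
#' @param data numeric matrix, rows = blocks (>= 2), columns = conditions
#'   (>= 2); no missing cells.
#' @return list with `statistic`, `df`, `p_value`, `mean_ranks`.
#' @export
friedman_test <- function(data) {
  data <- as.matrix(data)
  if (anyNA(data))
    stop("missing cells: the omnibus test needs a complete block matrix ",
         "(drop incomplete blocks first)")
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) stop("need >= 2 blocks and >= 2 conditions")
  r <- t(apply(data, 1, rank))
  rj <- colSums(r)
  tie_term <- sum(apply(data, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  if (denom <= 0) {                      # every block fully tied
    stat <- 0
  } else {
    stat <- 12 * sum((rj - n * (k + 1) / 2)^2) / denom
  }
  df <- k - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       mean_ranks = rj / n)
}

#' Star significance labels
#'
#' The conventional tiering: `****` p < 0.0001, `***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05, otherwise `ns` (strict inequalities; p = 0.05 is
#' `ns`).
#'
#' @param p probability (vectorised), in `[0, 1]`.
#' @return character vector of labels.
#' @export
star_label <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p must be within [0, 1]")
  vapply(p, function(pi) {
    if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

# Monte-Carlo reference for the two-sided many-to-one max-|t| statistic:
# q equicorrelated (rho = 0.5) t variates with nu df and a shared
# chi-square denominator (the classical Dunnett construction). Returns the
# R sampled max-|t| values, deterministic per seed.
dunnett_reference <- function(q, nu, n_mc = 2e5, seed = 1L, rho = 0.5) {
  rng <- local_rng(seed)
  z0 <- rng$rnorm(n_mc)
  w <- sqrt(stats::qchisq(rng$runif(n_mc), df = nu) / nu)
  mx <- rep(-Inf, n_mc)
  for (j in seq_len(q)) {
    tj <- abs(sqrt(rho) * z0 + sqrt(1 - rho) * rng$rnorm(n_mc)) / w
    mx <- pmax(mx, tj)
  }
  mx
}

#' Dunnett-style post-hoc comparisons on a block matrix
#'
#' Paired-difference t statistics for each requested condition pair, with a
#' family-wise adjustment against the equicorrelated (rho = 0.5)
#' multivariate-t max-|t| reference distribution, evaluated by seeded
#' Monte-Carlo integration (no critical-value tables). A family of one
#' reduces exactly to the raw paired t test. `method = "bonferroni"` gives
#' the conservative fallback.
#'
#' @param data numeric matrix, rows = blocks, named columns = conditions.
#' @param pairs list of length-2 character vectors naming condition pairs;
#'   default: every other condition versus `control`.
#' @param control control condition name used when `pairs` is NULL.
#' @param method `"mvt"` (default) or `"bonferroni"`.
#' @param n_mc Monte-Carlo draws for the reference distribution.
#' @param seed seed for the reference draw.
#' @return `data.frame` with pair, estimate (mean difference a - b),
#'   t value, raw_p, adjusted_p, stars.
#' @export
dunnett_posthoc <- function(data, pairs = NULL, control = colnames(data)[1],
                            method = c("mvt", "bonferroni"), n_mc = 2e5,
                            seed = 1L) {
  data <- as.matrix(data)
  method <- match.arg(method)
  if (is.null(colnames(data)))
    colnames(data) <- paste0("C", seq_len(ncol(data)))
  if (is.null(pairs)) {
    if (!control %in% colnames(data))
      stop(sprintf("control condition '%s' not found", control))
    pairs <- lapply(setdiff(colnames(data), control),
                    function(tr) c(tr, control))
  }
  bad <- !vapply(pairs, function(pr) all(pr %in% colnames(data)), logical(1))
  if (any(bad))
    stop(sprintf("pair references unknown condition(s): %s",
                 paste(unlist(pairs[bad]), collapse = ", ")))
  n <- nrow(data); q <- length(pairs); nu <- n - 1
  if (n < 3) stop("need >= 3 blocks for a paired t comparison")
  res <- lapply(pairs, function(pr) {
    d <- data[, pr[1]] - data[, pr[2]]
    sd_d <- stats::sd(d)
    tval <- if (sd_d == 0) {
      if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else mean(d) / (sd_d / sqrt(n))
    data.frame(pair = paste(pr[1], "vs", pr[2]), estimate = mean(d),
               t = tval, raw_p = 2 * stats::pt(-abs(tval), df = nu),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (q == 1L) {
    res$adjusted_p <- res$raw_p
  } else if (method == "bonferroni") {
    res$adjusted_p <- pmin(1, q * res$raw_p)
  } else {
    ref <- dunnett_reference(q, nu, n_mc = n_mc, seed = seed)
    res$adjusted_p <- vapply(res$t, function(t0) {
      if (!is.finite(t0)) return(0)
      mean(ref >= abs(t0))
    }, numeric(1))
    res$adjusted_p <- pmax(res$adjusted_p, res$raw_p)   # adjustment never helps
  }
  res$stars <- star_label(res$adjusted_p)
  res
}

#' Family-wise critical value of the Dunnett max-|t| statistic
#'
#' Quantile of the same Monte-Carlo reference used by [dunnett_posthoc()];
#' any |t| above it has adjusted p below `alpha`.
#'
#' @param q number of comparisons in the family.
#' @param nu degrees of freedom (blocks - 1).
#' @param alpha family-wise error level.
#' @inheritParams dunnett_posthoc
#' @return critical |t| value.
#' @export
dunnett_critical <- function(q, nu, alpha = 0.05, n_mc = 2e5, seed = 1L) {
  stats::quantile(dunnett_reference(q, nu, n_mc = n_mc, seed = seed),
                  probs = 1 - alpha, names = FALSE, type = 8)
}

#' Omnibus-then-post-hoc comparison of a cohort metric table
#'
#' For every metric: the Friedman omnibus over the complete patient x
#' condition block matrix, then the Dunnett-style post-hoc on the requested
#' pairs. Post-hoc results are computed even when the omnibus is not
#' significant, flagged via `omnibus_significant`.
#'
#' @param metrics long-format `data.frame` with columns `patient`,
#'   `condition`, `metric`, `value` (e.g. from [compute_cohort_metrics()]).
#' @param pairs,control,method,n_mc,seed passed to [dunnett_posthoc()].
#' @param alpha omnibus significance level for the flag.
#' @return named list (one entry per metric) of `comparison_result` objects:
#'   `friedman_stat`, `friedman_p`, `omnibus_significant`, `posthoc`.
#' @export
compare_cohort <- function(metrics, pairs = NULL, control = "AAA",
                           alpha = 0.05, method = "mvt", n_mc = 2e5,
                           seed = 1L) {
  need <- c("patient", "condition", "metric", "value")
  if (!all(need %in% names(metrics)))
    stop("`metrics` must have columns patient, condition, metric, value")
  out <- list()
  for (m in unique(metrics$metric)) {
    sub <- metrics[metrics$metric == m, ]
    mat <- tapply(sub$value, list(sub$patient, sub$condition), mean)
    mat <- mat[, unique(sub$condition), drop = FALSE]     # preserve order
    fr <- friedman_test(mat)
    ph <- dunnett_posthoc(mat, pairs = pairs, control = control,
                          method = method, n_mc = n_mc, seed = seed)
    out[[m]] <- structure(list(metric = m, friedman_stat = fr$statistic,
                               friedman_p = fr$p_value,
                               omnibus_significant = fr$p_value < alpha,
                               posthoc = ph),
                          class = "comparison_result")
  }
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: Friedman chi2 = %.3f, p = %.4g%s\n",
              x$metric, x$friedman_stat, x$friedman_p,
              if (x$omnibus_significant) "" else " (omnibus ns)"))
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}
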