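#' Maximum-likelihood fit of a reference family to transcript counts
#'
#' Fits one of the five reference families used for per-cell transcript
#' distributions. Normal and Poisson use their closed-form MLEs (the normal
#' MLE uses the population standard deviation); gamma, logistic and Weibull
#' are maximized numerically via [MASS::fitdistr()] at relative tolerance
#' 1e-8. The continuous families are fitted to integer counts as-is.
#'
#' Zeros break the gamma and Weibull likelihoods (positive support), so zero
#' counts are replaced by `zero_adjust` with a warning before fitting those
#' two families.
#'
#' @param counts numeric vector of non-negative counts; at least 5
#'   observations for the numerically optimized families (gamma, logistic,
#'   weibull), at least 2 for the closed forms.
#' @param family `"normal"`, `"gamma"`, `"logistic"`, `"weibull"` or
#'   `"poisson"`.
#' @param zero_adjust replacement value for zeros under gamma/weibull.
#' @return An object of class `fit_result`: `family`, named `params` vector
#'   (normal: mean, sd; gamma: shape, rate; logistic: location, scale;
#'   weibull: shape, scale; poisson: lambda), `loglik`, `n`.
#' @export
fit_mle <- function(counts, family, zero_adjust = 0.5) {
  family <- match.arg(family,
    c("normal", "gamma", "logistic", "weibull", "poisson"))
  x <- as.numeric(counts)
  floor_n <- if (family %in% c("normal", "poisson")) 2L else 5L
  if (length(x) < floor_n)
    stop("need at least ", floor_n, " observations for the ", family, " fit")
  if (any(!is.finite(x)) || any(x < 0)) stop("counts must be finite and >= 0")
  if (family %in% c("gamma", "weibull") && any(x == 0)) {
    warning("replacing ", sum(x == 0), " zero count(s) by ", zero_adjust,
            " for the ", family, " fit (positive support)")
    x[x == 0] <- zero_adjust
  }
  n <- length(x)
  if (family == "normal") {
    m <- mean(x); s <- sqrt(mean((x - m)^2))
    if (s <= 0) stop("all-identical sample: normal scale MLE degenerate")
    params <- c(mean = m, sd = s)
    ll <- sum(dnorm(x, m, s, log = TRUE))
  } else if (family == "poisson") {
    lam <- mean(x)
    if (lam <= 0) stop("all-zero sample: poisson rate MLE degenerate")
    params <- c(lambda = lam)
    ll <- sum(dpois(round(x), lam, log = TRUE))
  } else {
    if (max(x) == min(x))
      stop("all-identical sample: scale parameter MLE degenerate")
    dens <- c(gamma = "gamma", logistic = "logistic", weibull = "weibull")
    # optimizer excursions into invalid parameter space produce harmless NaN
    # warnings from the density functions; the converged fit is what matters
    fit <- suppressWarnings(
      MASS::fitdistr(x, dens[[family]],
                     control = list(reltol = 1e-8, maxit = 5000)))
    params <- fit$estimate
    ll <- as.numeric(fit$loglik)
    if (any(!is.finite(params))) stop("MLE did not converge for ", family)
  }
  structure(list(family = family, params = params, loglik = ll, n = n),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s MLE (n = %d): %s; loglik = %.3f\n", x$family, x$n,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "), x$loglik))
  invisible(x)
}

# CDF of a fitted family as a function of q.
fitted_cdf <- function(fit) {
  p <- fit$params
  switch(fit$family,
    normal   = function(q) pnorm(q, p[["mean"]], p[["sd"]]),
    gamma    = function(q) pgamma(q, shape = p[["shape"]], rate = p[["rate"]]),
    logistic = function(q) plogis(q, p[["location"]], p[["scale"]]),
    weibull  = function(q) pweibull(q, shape = p[["shape"]], scale = p[["scale"]]),
    poisson  = function(q) ppois(q, p[["lambda"]]))
}

# Exact sup|ECDF - F| for integer data against a step CDF: both functions
# are constant between integers, so the sup is attained on the integer grid
# (extended one atom below the sample minimum, where ECDF is still 0).
# p-value from the asymptotic Kolmogorov survival function.
ks_step_discrete <- function(x, cdf) {
  n <- length(x)
  grid <- seq(min(x) - 1, max(x))
  ec <- ecdf(x)(grid)
  D <- max(abs(ec - cdf(grid)))
  list(D = D, p = kolmogorov_sf(sqrt(n) * D))
}

# Q(t) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2), the asymptotic null
# survival function of sqrt(n) * D.
kolmogorov_sf <- function(t) {
  if (t < 1e-8) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

rand_fitted <- function(fit, n) {
  p <- fit$params
  switch(fit$family,
    normal   = rnorm(n, p[["mean"]], p[["sd"]]),
    gamma    = rgamma(n, shape = p[["shape"]], rate = p[["rate"]]),
    logistic = rlogis(n, p[["location"]], p[["scale"]]),
    weibull  = rweibull(n, shape = p[["shape"]], scale = p[["scale"]]),
    poisson  = rpois(n, p[["lambda"]]))
}

#' One-sample Kolmogorov-Smirnov goodness of fit
#'
#' Tests the sample against the fitted CDF with the one-sample KS statistic
#' `D = sup |ECDF - F|` (evaluated at and just below each sample point) and
#' the asymptotic Kolmogorov p-value, treating the fitted parameters as
#' known. Estimating the parameters from the same sample makes this
#' anti-conservative (p-values too large); a parametric bootstrap
#' (`bootstrap = TRUE`, refitting each replicate) provides the corrected
#' p-value.
#'
#' For the discrete Poisson family the fitted CDF is a right-continuous
#' step, and `D` is computed against it exactly — the supremum of
#' `|ECDF - F|` over the integers, where both functions jump at the same
#' atoms. Feeding tied integer data through a continuous-sample KS routine
#' instead would bound `D` below by the largest point mass and reject even a
#' perfectly Poisson sample at small rates; the exact-step statistic is used
#' with the same asymptotic null (conservative for discrete data, which is
#' documented).
#'
#' @param counts the sample the fit was computed on.
#' @param fit a [fit_mle()] result.
#' @param alpha rejection level.
#' @param bootstrap use a parametric-bootstrap p-value instead of the
#'   asymptotic one.
#' @param n_boot bootstrap replicates.
#' @return An object of class `ks_result`: `family`, `D`, `p_value`,
#'   `rejected` (`p_value < alpha`), `alpha`, `n`.
#' @export
ks_gof <- function(counts, fit, alpha = 0.05, bootstrap = FALSE,
                   n_boot = 199L) {
  stopifnot(inherits(fit, "fit_result"))
  x <- as.numeric(counts)
  if (length(x) == 0L) stop("empty sample")
  cdf <- fitted_cdf(fit)
  if (fit$family == "poisson") {
    ks <- ks_step_discrete(x, cdf)
    D <- ks$D; p <- ks$p
  } else {
    kt <- suppressWarnings(ks.test(x, cdf, exact = FALSE))
    D <- unname(kt$statistic)
    p <- unname(kt$p.value)
  }
  if (bootstrap) {
    exceed <- 0L
    for (b in seq_len(n_boot)) {
      xb <- rand_fitted(fit, length(x))
      if (fit$family %in% c("gamma", "weibull")) xb <- pmax(xb, 1e-8)
      fb <- try(suppressWarnings(fit_mle(xb, fit$family)), silent = TRUE)
      if (inherits(fb, "try-error")) next
      Db <- if (fit$family == "poisson")
        ks_step_discrete(xb, fitted_cdf(fb))$D
      else unname(suppressWarnings(
        ks.test(xb, fitted_cdf(fb), exact = FALSE))$statistic)
      if (Db >= D) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_boot)
  }
  structure(list(family = fit$family, D = D, p_value = p,
                 rejected = p < alpha, alpha = alpha, n = length(x)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("KS vs %s: D = %.4f, p = %.4g -> %s at alpha = %g\n",
              x$family, x$D, x$p_value,
              if (x$rejected) "rejected" else "not rejected", x$alpha))
  invisible(x)
}

#' Per-gene model selection over the five reference families
#'
#' Fits all five families to each gene's per-cell counts, KS-tests each fit,
#' and reports which families are not rejected — the verdict identifying the
#' distribution(s) compatible with each gene's transcript noise. No
#' multiple-testing correction is applied by default, matching the one-test-
#' per-family presentation this models; `holm = TRUE` applies a Holm
#' correction across the families within each gene.
#'
#' @param per_gene_counts named list mapping gene to its count vector.
#' @param alpha rejection level.
#' @param min_n minimum counts per gene (smaller genes are an error).
#' @param holm apply Holm correction within each gene.
#' @param bootstrap,n_boot passed to [ks_gof()].
#' @return `list(table = data.frame(gene, family, <params>, D, p_value,
#'   rejected), verdicts = named character vector listing the non-rejected
#'   families per gene)`.
#' @export
model_selection_table <- function(per_gene_counts, alpha = 0.05, min_n = 20L,
                                  holm = FALSE, bootstrap = FALSE,
                                  n_boot = 199L) {
  families <- c("normal", "gamma", "logistic", "weibull", "poisson")
  rows <- list(); verdicts <- character(0)
  for (gene in names(per_gene_counts)) {
    x <- per_gene_counts[[gene]]
    if (length(x) < min_n)
      stop("gene '", gene, "' has fewer than ", min_n, " counts")
    res <- lapply(families, function(fam) {
      fit <- fit_mle(x, fam)
      ks <- ks_gof(x, fit, alpha = alpha, bootstrap = bootstrap,
                   n_boot = n_boot)
      list(fit = fit, ks = ks)
    })
    p <- vapply(res, function(r) r$ks$p_value, 0)
    if (holm) p <- stats::p.adjust(p, "holm")
    rej <- p < alpha
    for (k in seq_along(families)) {
      f <- res[[k]]$fit
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, family = families[k],
        param1 = f$params[1],
        param2 = if (length(f$params) > 1) f$params[2] else NA_real_,
        loglik = f$loglik, D = res[[k]]$ks$D, p_value = p[k],
        rejected = rej[k])
    }
    verdicts[gene] <- if (any(!rej))
      paste(families[!rej], collapse = ", ") else "none"
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), family = character(0),
               param1 = numeric(0), param2 = numeric(0), loglik = numeric(0),
               D = numeric(0), p_value = numeric(0), rejected = logical(0))
  rownames(tab) <- NULL
  list(table = tab, verdicts = verdicts)
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each sample, `dCt = ct_target - ct_reference`; `ddCt` subtracts the
#' calibrator group's mean `dCt`; relative expression is
#' `efficiency^(-ddCt)`. The calibrator group is thereby self-normalized:
#' its relative expressions have geometric mean 1.
#'
#' @param ct_table data frame with columns `sample_id`, `group` (`"test"` or
#'   `"calibrator"`), `ct_target`, `ct_reference`; Ct values finite and
#'   positive.
#' @param efficiency amplification efficiency per cycle (2 = perfect
#'   doubling).
#' @return `list(per_sample = data.frame(sample_id, group, dct, ddct,
#'   rel_expr), group_summary = data.frame(group, mean, sd))`.
#' @export
delta_delta_ct <- function(ct_table, efficiency = 2.0) {
  need <- c("sample_id", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(ct_table)))
    stop("ct_table needs columns: ", paste(need, collapse = ", "))
  ct <- ct_table
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference)) ||
      any(ct$ct_target <= 0) || any(ct$ct_reference <= 0))
    stop("Ct values must be finite and positive")
  if (!any(ct$group == "calibrator")) stop("no calibrator rows")
  dct <- ct$ct_target - ct$ct_reference
  ddct <- dct - mean(dct[ct$group == "calibrator"])
  rel <- efficiency^(-ddct)
  per_sample <- data.frame(sample_id = ct$sample_id, group = ct$group,
                           dct = dct, ddct = ddct, rel_expr = rel)
  gs <- aggregate(rel_expr ~ group, per_sample,
                  function(v) c(mean = mean(v), sd = sd(v)))
  group_summary <- data.frame(group = gs$group,
                              mean = gs$rel_expr[, "mean"],
                              sd = gs$rel_expr[, "sd"])
  list(per_sample = per_sample, group_summary = group_summary)
}
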