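#' Specify a per-location linear model
#'
#' The model for location k is
#' `M_k = a_k + b_kG G + b_kT T + b_kW W + b_kB B (+ b_kS S) + e_k`,
#' where G is sex (female=0, male=1), T the Tanner stage, W the weight
#' category (normal-weight=0, obese=1), B the white-blood-cell count and,
#' in the second model, S the additive risk-allele dose (TT=0, TC=1,
#' CC=2). The contrast names the single coefficient whose moderated
#' t-statistic ranks locations.
#'
#' @param contrast Name of the coefficient of interest (`"W"` for the
#'   weight model, `"S"` for the genotype model).
#' @param covariates Design columns in order; `S` is included by default
#'   whenever it is the contrast.
#' @param robust Fit by Huber M-estimation (default) or plain OLS.
#' @param max_iter Maximum IRLS iterations. Default 10000.
#' @param huber_c Huber tuning constant. Default 1.345 (95% Gaussian
#'   efficiency).
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @return A `model_spec` list.
#' @export
model_spec <- function(contrast = "W",
                       covariates = if (contrast == "S") c("G", "T", "W", "B", "S")
                                    else c("G", "T", "W", "B"),
                       robust = TRUE,
                       max_iter = 10000,
                       huber_c = 1.345,
                       tol = 1e-8) {
  if (!contrast %in% covariates) {
    abort(sprintf("Contrast '%s' is not among the design covariates (%s).",
                  contrast, paste(covariates, collapse = ", ")))
  }
  if (max_iter < 1) abort("`max_iter` must be at least 1.")
  structure(
    list(contrast = contrast, covariates = covariates, robust = robust,
         max_iter = as.integer(max_iter), huber_c = huber_c, tol = tol),
    class = "model_spec"
  )
}

#' Build the design matrix for a covariate table
#'
#' Columns are an intercept followed by the spec's covariates; samples
#' with any missing covariate are dropped (and recorded in the
#' `"dropped_samples"` attribute). A rank-deficient design — e.g. a
#' single-sex cohort making the G column constant — raises an error naming
#' the collinear columns.
#'
#' @param covariates Covariate tibble with `sample_id` plus the model
#'   columns.
#' @param spec A [model_spec()].
#' @return Numeric design matrix with sample IDs as rownames.
#' @export
build_design <- function(covariates, spec = model_spec()) {
  miss <- setdiff(spec$covariates, names(covariates))
  if (length(miss) > 0) {
    abort(sprintf("Covariate table lacks column(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  cc <- complete.cases(covariates[, spec$covariates])
  dropped <- covariates$sample_id[!cc]
  if (length(dropped) > 0) {
    inform(sprintf("Dropping %d sample(s) with missing covariates: %s",
                   length(dropped),
                   paste(utils::head(dropped, 5), collapse = ", ")))
  }
  kept <- covariates[cc, , drop = FALSE]
  X <- cbind(
    `(Intercept)` = 1,
    as.matrix(kept[, spec$covariates, drop = FALSE])
  )
  storage.mode(X) <- "double"
  rownames(X) <- kept$sample_id
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("Design is rank-deficient; collinear column(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  attr(X, "dropped_samples") <- dropped
  X
}

# Gaussian consistency factor for the Huber-weighted residual sum of
# squares: E[min(1, c/|z|) z^2] = 2*pnorm(c) - 1 for standard normal z.
huber_kappa <- function(c) 2 * pnorm(c) - 1

#' Robust (or OLS) fit of one location
#'
#' Huber M-estimation by iteratively reweighted least squares: weights
#' `min(1, c*s/|r|)` with the scale s re-estimated each iteration as the
#' rescaled MAD of the residuals (`median|r| / 0.6745`), iterated until
#' the largest coefficient change is below `tol` or `max_iter` is
#' reached. The residual variance is the weighted residual sum of squares
#' over `(n - p)`, divided by the Gaussian consistency factor
#' `2*pnorm(c) - 1` so that it estimates the error variance without bias
#' under clean Gaussian data. With `robust = FALSE` the fit is exact OLS.
#'
#' @param y Numeric response vector (M-values of one location).
#' @param X Design matrix from [build_design()] (rows match `y`).
#' @param spec A [model_spec()].
#' @return List with `coefficients`, `sigma2`, `df` (`n - p`),
#'   `se_unscaled` (per-coefficient unscaled standard-error factors, from
#'   the weighted cross-product for robust fits), `weights` and
#'   `converged` (non-convergence is flagged, never an error).
#' @export
robust_fit <- function(y, X, spec = model_spec()) {
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) abort("`y` and `X` have mismatched rows.")
  if (n <= p) abort("Need more samples than design columns.")
  fit <- fit_one(y, X, spec)
  fit
}

fit_one <- function(y, X, spec) {
  n <- length(y)
  p <- ncol(X)
  df <- n - p
  qrX <- qr(X)
  b <- qr.coef(qrX, y)
  converged <- TRUE
  w <- rep(1, n)

  if (spec$robust) {
    converged <- FALSE
    for (it in seq_len(spec$max_iter)) {
      r <- y - drop(X %*% b)
      s <- median(abs(r)) / 0.6745
      if (s < 1e-10) { converged <- TRUE; w <- rep(1, n); break }
      w <- pmin(1, spec$huber_c * s / abs(r))
      w[!is.finite(w)] <- 1
      sw <- sqrt(w)
      Xw <- X * sw
      bnew <- tryCatch(
        drop(solve(crossprod(Xw), crossprod(Xw, y * sw) * 1)),
        error = function(e) qr.coef(qr(Xw), y * sw)
      )
      delta <- max(abs(bnew - b))
      b <- bnew
      if (delta < spec$tol) { converged <- TRUE; break }
    }
    r <- y - drop(X %*% b)
    sigma2 <- sum(w * r^2) / (df * huber_kappa(spec$huber_c))
    xtwx <- crossprod(X * sqrt(w))
  } else {
    r <- y - drop(X %*% b)
    sigma2 <- sum(r^2) / df
    xtwx <- crossprod(X)
  }
  se_unscaled <- sqrt(diag(solve(xtwx)))
  names(b) <- names(se_unscaled) <- colnames(X)
  list(
    coefficients = b, sigma2 = sigma2, df = df,
    se_unscaled = se_unscaled, weights = w, converged = converged
  )
}

#' Fit the per-location linear model across a matrix
#'
#' Runs [robust_fit()] (or a vectorized OLS when `robust = FALSE`) for
#' every row of the location-by-sample M-value matrix.
#'
#' @param m Numeric matrix (locations x samples), no missing values.
#' @param covariates Covariate tibble (see [build_design()]).
#' @param spec A [model_spec()].
#' @return A `meth_fit` object; see [tidy.meth_fit()] and
#'   [ebayes_moderate()].
#' @export
fit_locations <- function(m, covariates, spec = model_spec()) {
  if (anyNA(m)) abort("`m` must not contain missing values; run QC first.")
  X <- build_design(covariates, spec)
  common <- intersect(colnames(m), rownames(X))
  if (length(common) == 0) abort("No samples shared between `m` and the design.")
  m <- m[, common, drop = FALSE]
  X <- X[common, , drop = FALSE]
  n <- ncol(m)
  p <- ncol(X)
  if (n <= p) abort("Need more samples than design columns.")
  L <- nrow(m)

  if (!spec$robust) {
    qrX <- qr(X)
    B <- qr.coef(qrX, t(m))                      # p x L
    res <- t(m) - X %*% B
    sigma2 <- colSums(res^2) / (n - p)
    u <- sqrt(diag(solve(crossprod(X))))
    coef_tbl <- tibble::as_tibble(t(B))
    tbl <- tibble::tibble(
      location_id = rownames(m),
      !!!coef_tbl,
      sigma2 = sigma2,
      df = rep(n - p, L),
      se_unscaled = rep(unname(u[spec$contrast]), L),
      converged = TRUE
    )
  } else {
    fits <- vector("list", L)
    for (i in seq_len(L)) fits[[i]] <- fit_one(m[i, ], X, spec)
    coef_mat <- t(vapply(fits, `[[`, numeric(p), "coefficients"))
    colnames(coef_mat) <- colnames(X)
    tbl <- tibble::tibble(
      location_id = rownames(m),
      !!!tibble::as_tibble(coef_mat),
      sigma2 = vapply(fits, `[[`, numeric(1), "sigma2"),
      df = vapply(fits, `[[`, numeric(1), "df"),
      se_unscaled = vapply(fits, function(f) unname(f$se_unscaled[spec$contrast]),
                           numeric(1)),
      converged = vapply(fits, `[[`, logical(1), "converged")
    )
  }
  tbl$coefficient <- tbl[[spec$contrast]]
  tbl[] <- lapply(tbl, function(col) if (is.numeric(col)) unname(col) else col)
  structure(
    list(table = tbl, spec = spec, design = X, prior = NULL),
    class = "meth_fit"
  )
}

# Invert the trigamma function by Newton iteration (monotone decreasing
# on (0, Inf), so convergence is global from the asymptotic start 1/y).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of per-location variances
#'
#' Shrinks each location's residual variance toward a common prior
#' estimated across locations, and recomputes the contrast's t-statistic
#' against the shrunken ("moderated") variance with `d0 + d_k` degrees of
#' freedom. The prior `(d0, s0^2)` — a scaled inverse chi-square on the
#' true variances, equivalently a scaled F on the observed ones — is
#' estimated by matching moments of `log(s_k^2)`: the excess of the
#' empirical variance of `log(s_k^2)` over its sampling component
#' `trigamma(d_k/2)` identifies `trigamma(d0/2)`, inverted numerically;
#' the mean identifies `s0^2`. When the empirical spread falls at or below
#' the sampling floor, `d0 = Inf` is returned and every moderated variance
#' equals `s0^2` (normal reference distribution).
#'
#' @param fit A `meth_fit` from [fit_locations()].
#' @param d0,s0_2 Optional fixed prior overriding the moment-matching
#'   estimate. `d0 = 0` recovers the classical per-location t-statistic;
#'   `d0 = Inf` uses the common variance `s0_2` everywhere.
#' @return The `meth_fit` with columns `s2_moderated`, `t`, `p_value`
#'   added to its table and `prior = list(d0, s0_2)` filled in.
#' @export
ebayes_moderate <- function(fit, d0 = NULL, s0_2 = NULL) {
  stopifnot(inherits(fit, "meth_fit"))
  tbl <- fit$table
  s2 <- tbl$sigma2
  d <- tbl$df
  if (is.null(d0) || is.null(s0_2)) {
    # exact and near-zero variances (e.g. perfectly fitted locations) carry
    # no information about the prior and would blow up the log moments
    use <- is.finite(s2) & s2 > 1e-10
    if (sum(use) < 2) {
      abort("Need at least 2 locations with finite positive residual variance.")
    }
    z <- log(s2[use])
    e <- z - digamma(d[use] / 2) + log(d[use] / 2)
    emean <- mean(e)
    v <- var(e) - mean(trigamma(d[use] / 2))
    if (is.finite(v) && v > 0) {
      d0 <- 2 * trigamma_inverse(v)
      s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # no excess spread beyond chi-square sampling noise: variances are
      # exchangeable and the prior is the plain average
      d0 <- Inf
      s0_2 <- mean(s2[use])
    }
  }

  s2_mod <- if (is.finite(d0)) (d0 * s0_2 + d * s2) / (d0 + d) else rep(s0_2, length(s2))
  t_mod <- tbl$coefficient / (tbl$se_unscaled * sqrt(s2_mod))
  df_total <- d0 + d
  p <- 2 * pt(-abs(t_mod), df = df_total)

  tbl$s2_moderated <- s2_mod
  tbl$t <- t_mod
  tbl$p_value <- p
  fit$table <- tbl
  fit$prior <- list(d0 = d0, s0_2 = s0_2)
  fit
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values controlling the false discovery rate:
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)` over the ascending order,
#' returned in the original order. Delegates to
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Vector of adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Fit, moderate and adjust in one call
#'
#' Convenience chain [fit_locations()] |> [ebayes_moderate()] plus
#' [bh_adjust()] on the raw p-values (`p_adjusted` column).
#'
#' @inheritParams fit_locations
#' @return A `meth_fit` with the complete statistics table.
#' @examples
#' sim <- simulate_cohort(sim_config(n_probes = 100, n_samples = 24, seed = 3))
#' m <- quantile_normalize(beta_to_m(sim$cohort$beta))
#' fit <- diff_methylation(m, sim$cohort$covariates, model_spec("W"))
#' glance(fit)
#' @export
diff_methylation <- function(m, covariates, spec = model_spec()) {
  fit <- ebayes_moderate(fit_locations(m, covariates, spec))
  fit$table$p_adjusted <- bh_adjust(fit$table$p_value)
  fit
}

#' Top-ranked locations of a fitted model
#'
#' The top `k` rows by ascending raw p-value for the contrast (ties break
#' to ascending location ID), carrying the result-table schema: gene,
#' genomic position, CpG-density (HIL) class, coefficient, raw and
#' adjusted p-values.
#'
#' @param fit A `meth_fit` from [diff_methylation()].
#' @param locations Optional location table from [collapse_islands()];
#'   when supplied, gene and genomic columns are joined in.
#' @param k Number of rows to keep. Default 15.
#' @return A `ranked_table` tibble (attributes: `contrast`, `k`).
#' @export
rank_top <- function(fit, locations = NULL, k = 15) {
  stopifnot(inherits(fit, "meth_fit"))
  if (k < 1) abort("`k` must be at least 1.")
  tbl <- fit$table
  if (!"p_value" %in% names(tbl)) {
    abort("Fit has no p-values; run `ebayes_moderate()` / `diff_methylation()` first.")
  }
  if (nrow(tbl) == 0) abort("Fit table is empty.")
  if (k > nrow(tbl)) {
    warn(sprintf("k = %d exceeds the %d available rows; returning all.",
                 k, nrow(tbl)))
    k <- nrow(tbl)
  }
  out <- tbl |>
    dplyr::arrange(.data$p_value, .data$location_id) |>
    dplyr::slice_head(n = k) |>
    dplyr::select("location_id", "coefficient", "t",
                  "p_value", "p_adjusted", "converged")
  if (!is.null(locations)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(locations, "location_id", "kind", "chromosome",
                    "start", "end", "hil_class", "closest_tss_gene",
                    "distance_to_tss"),
      by = "location_id"
    ) |>
      dplyr::rename(gene = "closest_tss_gene")
  }
  structure(out,
            class = c("ranked_table", class(out)),
            contrast = fit$spec$contrast, k = k)
}

#' Tidy a fitted methylation model
#'
#' @param x A `meth_fit`.
#' @param ... Unused.
#' @return The per-location statistics tibble.
#' @method tidy meth_fit
#' @export
tidy.meth_fit <- function(x, ...) x$table

#' One-row summary of a fitted methylation model
#'
#' @param x A `meth_fit`.
#' @param ... Unused.
#' @return One-row tibble: number of locations, contrast, robust flag,
#'   convergence count, and the empirical-Bayes prior (`d0`, `s0_2`) when
#'   moderation has run.
#' @method glance meth_fit
#' @export
glance.meth_fit <- function(x, ...) {
  tibble::tibble(
    n_locations = nrow(x$table),
    contrast = x$spec$contrast,
    robust = x$spec$robust,
    n_converged = sum(x$table$converged),
    d0 = x$prior$d0 %||% NA_real_,
    s0_2 = x$prior$s0_2 %||% NA_real_
  )
}

#' @export
print.meth_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<meth_fit> %d locations, contrast %s (%s)%s\n",
    g$n_locations, g$contrast,
    if (g$robust) "robust" else "OLS",
    if (!is.na(g$d0)) sprintf(", prior d0 = %.3g, s0^2 = %.3g", g$d0, g$s0_2)
    else " (not yet moderated)"
  ))
  invisible(x)
}

#' Volcano plot of a fitted model
#'
#' Contrast coefficient against -log10 raw p-value per location.
#'
#' @param object A `meth_fit` with p-values.
#' @param alpha Adjusted-p significance threshold used for colouring.
#'   Default 0.05.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meth_fit
#' @export
autoplot.meth_fit <- function(object, alpha = 0.05, ...) {
  tbl <- object$table
  if (!"p_value" %in% names(tbl)) abort("Fit has no p-values yet.")
  tbl$significant <- if ("p_adjusted" %in% names(tbl)) {
    tbl$p_adjusted < alpha
  } else FALSE
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$coefficient,
                                    y = -log10(.data$p_value),
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = sprintf("Coefficient (%s contrast, M-value units)",
                  object$spec$contrast),
      y = expression(-log[10] ~ "raw p"),
      colour = sprintf("adj. p < %g", alpha)
    ) +
    ggplot2::theme_minimal()
}
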