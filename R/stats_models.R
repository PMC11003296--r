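# Inferential layer: standardized multiple regression with partial
# correlations, mixed-effects models across participants, Welch's t,
# variance inflation factors, Bonferroni correction, intercept-free
# summation regression, and AIC/BIC model comparison.

#' Standardized multiple regression with partial correlations
#'
#' Ordinary least squares on z-scored predictors (the response is left on
#' its transformed scale). For each predictor the output reports the
#' standardized coefficient beta, the partial correlation r between response
#' and predictor given the remaining predictors, the two-sided t-test
#' p-value, and the variance inflation factor.
#'
#' @param data data frame.
#' @param response name of the response column.
#' @param predictors character vector of predictor columns.
#' @param intercept include an intercept (default TRUE).
#' @param standardize z-score predictors before fitting (default TRUE; set
#'   to FALSE when predictors are pre-standardized).
#' @param label model label carried into reports.
#' @return object of class `phos_fit`: list with `terms` tibble (`term`,
#'   `beta`, `r`, `p`), `n`, `aic`, `bic`, `vif`, `sigma`, `intercept`,
#'   `random`, `model`.
#' @export
ols_standardized <- function(data, response, predictors, intercept = TRUE,
                             standardize = TRUE, label = response) {
  df <- prepare_design(data, response, predictors, standardize)
  k <- length(predictors) + as.integer(intercept)
  if (nrow(df) <= k + 1) stop("too few observations for the design", call. = FALSE)
  check_rank(df, predictors, intercept)
  fml <- fit_formula(response, predictors, intercept)
  fit <- lm(fml, data = df)
  sm <- summary(fit)$coefficients
  rows <- lapply(predictors, function(p) {
    pc <- partial_correlation(
      df[[response]], df[[p]],
      df[predictors[predictors != p]]
    )
    tibble::tibble(
      term = p,
      beta = unname(coef(fit)[p]),
      se = sm[p, "Std. Error"],
      r = pc$r,
      p = sm[p, "Pr(>|t|)"]
    )
  })
  new_phos_fit(
    label = label, response = response,
    terms = dplyr::bind_rows(rows),
    n = nrow(df), aic = AIC(fit), bic = BIC(fit),
    vif = if (length(predictors) >= 2) vif(df[predictors]) else NULL,
    intercept = intercept, random = "none", model = fit
  )
}

#' Partial correlation between y and x controlling for Z
#'
#' Pearson correlation between the residuals of `y ~ Z` and `x ~ Z`
#' (with intercepts). With empty `Z` this is the plain Pearson correlation.
#' The p-value uses the t transform with `n - ncol(Z) - 2` degrees of
#' freedom.
#'
#' @param y,x numeric vectors.
#' @param Z data frame / matrix of control variables (may have 0 columns).
#' @return list with `r`, `p`, `df`.
#' @export
partial_correlation <- function(y, x, Z = NULL) {
  if (is.null(Z)) Z <- data.frame(row.names = seq_along(y))
  Z <- as.data.frame(Z)
  n <- length(y)
  q <- ncol(Z)
  if (n <= q + 2) stop("too few observations for partial correlation", call. = FALSE)
  if (q == 0) {
    ry <- y - mean(y)
    rx <- x - mean(x)
  } else {
    zm <- as.matrix(Z)
    qr_z <- qr(cbind(1, zm))
    if (qr(cbind(1, zm, x))$rank <= qr_z$rank) {
      stop("x lies in the span of Z: partial correlation undefined",
           call. = FALSE)
    }
    ry <- qr.resid(qr_z, y)
    rx <- qr.resid(qr_z, x)
  }
  if (sd(ry) == 0 || sd(rx) == 0) {
    stop("zero residual variance: partial correlation undefined", call. = FALSE)
  }
  r <- sum(ry * rx) / sqrt(sum(ry^2) * sum(rx^2))
  df <- n - q - 2
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df), df = df)
}

#' Linear mixed-effects regression with a random participant intercept
#'
#' Random-intercept model fit by REML, with Satterthwaite p-values for the
#' fixed effects. Partial correlations are computed by fixed-effects
#' residualization: the response minus the predicted random intercepts is
#' partial-correlated with each predictor given the others. A singular fit
#' falls back to the pooled regression with `random = "pooled_fallback"`.
#'
#' @inheritParams ols_standardized
#' @param group name of the grouping column (participants).
#' @return `phos_fit` object.
#' @export
mixed_effects <- function(data, response, predictors, group,
                          standardize = TRUE, intercept = TRUE,
                          label = response) {
  df <- prepare_design(data, response, predictors, standardize,
                       extra = group)
  if (length(unique(df[[group]])) < 2) {
    fit <- ols_standardized(df, response, predictors,
                            intercept = intercept, standardize = FALSE,
                            label = label)
    fit$random <- "single_group_pooled"
    return(fit)
  }
  check_rank(df, predictors, intercept)
  fml <- stats::as.formula(paste(
    response, "~", if (intercept) "" else "0 +",
    paste(predictors, collapse = " + "),
    "+ (1 |", group, ")"
  ))
  fit <- suppressMessages(lmerTest::lmer(fml, data = df, REML = TRUE))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warning("singular mixed-model fit; falling back to pooled regression",
            call. = FALSE)
    out <- ols_standardized(df, response, predictors, intercept = intercept,
                            standardize = FALSE, label = label)
    out$random <- "pooled_fallback"
    return(out)
  }
  sm <- stats::coef(summary(fit))
  # residualize out the estimated random intercepts
  ranef_b <- lme4::ranef(fit)[[group]][, "(Intercept)"]
  grp_idx <- match(as.character(df[[group]]),
                   rownames(lme4::ranef(fit)[[group]]))
  y_star <- df[[response]] - ranef_b[grp_idx]
  rows <- lapply(predictors, function(p) {
    pc <- partial_correlation(
      y_star, df[[p]], df[predictors[predictors != p]]
    )
    tibble::tibble(
      term = p,
      beta = sm[p, "Estimate"],
      se = sm[p, "Std. Error"],
      r = pc$r,
      p = sm[p, "Pr(>|t|)"]
    )
  })
  ml_fit <- stats::update(fit, REML = FALSE)
  new_phos_fit(
    label = label, response = response,
    terms = dplyr::bind_rows(rows),
    n = nrow(df), aic = AIC(ml_fit), bic = BIC(ml_fit),
    vif = if (length(predictors) >= 2) vif(df[predictors]) else NULL,
    intercept = intercept, random = paste0("(1|", group, ")"), model = fit
  )
}

#' Welch's unequal-variance t-test
#'
#' @param group_a,group_b numeric vectors (each n >= 2).
#' @return list with `t`, `df`, `p`. Two constant, equal groups return
#'   t = 0, p = 1 by convention.
#' @export
welch_t <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1))
    }
    return(list(t = Inf * sign(mean(group_a) - mean(group_b)),
                df = length(group_a) + length(group_b) - 2, p = 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j is from regressing predictor j on
#' the remaining predictors (with intercept). Perfectly collinear columns
#' report `Inf`.
#'
#' @param X data frame or matrix of predictors (>= 2 columns).
#' @return named numeric vector.
#' @export
vif <- function(X) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 2)
  vapply(names(X), function(j) {
    fit <- lm(stats::reformulate(names(X)[names(X) != j], response = j),
              data = X)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Bonferroni correction with significance stars
#'
#' @param pvals numeric vector of raw p-values.
#' @param m family size (>= number of p-values; defaults to the count).
#' @return tibble: `p`, `p_adj` (= min(1, p * m)), `stars`
#'   (`***` p < .001, `**` p < .01, `*` p < .05 on the adjusted scale),
#'   `significant` at alpha = .05.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  stopifnot(m >= length(pvals))
  p_adj <- p.adjust(pvals, method = "bonferroni", n = m)
  tibble::tibble(
    p = pvals,
    p_adj = p_adj,
    stars = dplyr::case_when(
      p_adj < .001 ~ "***",
      p_adj < .01 ~ "**",
      p_adj < .05 ~ "*",
      TRUE ~ ""
    ),
    significant = p_adj < .05
  )
}

#' Compare along-axon vs between-axon model families by AIC/BIC
#'
#' Fits two models of the same response on the same sample and compares
#' their information criteria computed from the Gaussian maximum-likelihood
#' fit (ML, not REML, so models with different fixed effects are
#' comparable). Evidence bands: a difference below 2 means no clear
#' preference; 2 to 7 (AIC) / 2 to 6 (BIC), some evidence against the higher
#' score; beyond that, strong evidence.
#'
#' @param data data frame.
#' @param response response column.
#' @param predictors_a,predictors_b predictor sets of model A (along-axon
#'   family) and model B (between-axon family).
#' @param group optional grouping column; when given, both models are random
#'   intercept mixed models, otherwise OLS.
#' @param standardize z-score predictors before fitting.
#' @return object of class `phos_model_comparison`: `fit_a`, `fit_b`,
#'   `delta_aic` (= AIC_A - AIC_B), `delta_bic`, `preferred`, `verdict`.
#' @export
compare_models <- function(data, response, predictors_a, predictors_b,
                           group = NULL, standardize = TRUE) {
  df <- prepare_design(
    data, response, union(predictors_a, predictors_b),
    standardize = standardize, extra = group
  )
  fit_one <- function(preds, lbl) {
    if (is.null(group)) {
      ols_standardized(df, response, preds, standardize = FALSE, label = lbl)
    } else {
      fml <- stats::as.formula(paste(
        response, "~", paste(preds, collapse = " + "),
        "+ (1 |", group, ")"
      ))
      m <- suppressMessages(lme4::lmer(fml, data = df, REML = FALSE))
      new_phos_fit(
        label = lbl, response = response,
        terms = tibble::tibble(
          term = preds,
          beta = lme4::fixef(m)[preds],
          se = NA_real_, r = NA_real_, p = NA_real_
        ),
        n = nrow(df), aic = AIC(m), bic = BIC(m), vif = NULL,
        intercept = TRUE, random = paste0("(1|", group, ")"), model = m
      )
    }
  }
  fit_a <- fit_one(predictors_a, "model_A")
  fit_b <- fit_one(predictors_b, "model_B")
  if (fit_a$n != fit_b$n) {
    stop("models were fit on different sample sizes", call. = FALSE)
  }
  delta_aic <- fit_a$aic - fit_b$aic
  delta_bic <- fit_a$bic - fit_b$bic
  structure(
    list(
      fit_a = fit_a, fit_b = fit_b,
      delta_aic = delta_aic, delta_bic = delta_bic,
      preferred = if (abs(delta_aic) < 2) "none" else if (delta_aic > 0) "B" else "A",
      verdict = evidence_verdict(delta_aic, delta_bic)
    ),
    class = "phos_model_comparison"
  )
}

evidence_verdict <- function(delta_aic, delta_bic) {
  band <- function(d, hi) {
    a <- abs(d)
    if (a < 2) "no preference" else if (a < hi) "some evidence" else "strong evidence"
  }
  c(aic = band(delta_aic, 7), bic = band(delta_bic, 6))
}

#' @export
print.phos_model_comparison <- function(x, ...) {
  cat(sprintf(
    "<model comparison> AIC: A = %.3f, B = %.3f (dAIC = %.3f)\n",
    x$fit_a$aic, x$fit_b$aic, x$delta_aic
  ))
  cat(sprintf(
    "                   BIC: A = %.3f, B = %.3f (dBIC = %.3f)\n",
    x$fit_a$bic, x$fit_b$bic, x$delta_bic
  ))
  cat(sprintf("  preferred: %s (%s / %s)\n", x$preferred,
              x$verdict[["aic"]], x$verdict[["bic"]]))
  invisible(x)
}

#' No-intercept summation regression of paired on summed single descriptors
#'
#' For each paired-electrode data point, the two constituent single-electrode
#' data points are matched (same participant and electrode, frequency fixed
#' at the paired condition's 20 Hz, amplitude closest to the paired
#' amplitude) and their descriptor values summed. Each paired descriptor is
#' then regressed through the origin on the corresponding summed single
#' descriptor: the slope is the summation gain (1 = perfect additivity,
#' 0.5 = averaging). Descriptors are taken on the normalized, untransformed
#' scale so the gain is directly interpretable.
#'
#' @param paired_points paired-electrode data points (normalized,
#'   untransformed descriptors; `electrodes` key like `"A1+B2"`).
#' @param single_points single-electrode data points on the same scale.
#' @return list: `fits` tibble (`descriptor`, `beta`, `r`, `p`, `n`),
#'   `matched` (per-pair predictor/response table), `unmatched` (log of
#'   paired points lacking a single-electrode counterpart).
#' @export
summation_regression <- function(paired_points, single_points) {
  stopifnot(nrow(paired_points) > 0)
  parts <- strsplit(paired_points$electrodes, "+", fixed = TRUE)
  rows <- vector("list", nrow(paired_points))
  unmatched <- character()
  for (i in seq_len(nrow(paired_points))) {
    pp <- paired_points[i, ]
    singles <- lapply(parts[[i]], function(e) {
      cand <- single_points[
        single_points$participant == pp$participant &
          single_points$electrodes == e &
          abs(single_points$frequency_hz - pp$frequency_hz) < 1e-9,
      ]
      if (!nrow(cand)) return(NULL)
      cand[order(abs(cand$amplitude_x_th - pp$amplitude_x_th),
                 cand$amplitude_x_th), ][1, ]
    })
    if (any(vapply(singles, is.null, logical(1)))) {
      unmatched <- c(unmatched, pp$electrodes[[1]])
      next
    }
    sums <- colSums(dplyr::bind_rows(singles)[, DESCRIPTOR_COLS])
    row <- tibble::tibble(
      participant = pp$participant, electrodes = pp$electrodes,
      amplitude_x_th = pp$amplitude_x_th
    )
    for (d in DESCRIPTOR_COLS) {
      row[[paste0("paired_", d)]] <- pp[[d]]
      row[[paste0("single_sum_", d)]] <- sums[[d]]
    }
    rows[[i]] <- row
  }
  matched <- dplyr::bind_rows(rows)
  if (!nrow(matched)) stop("no paired point could be matched", call. = FALSE)
  fits <- lapply(DESCRIPTOR_COLS, function(d) {
    y <- matched[[paste0("paired_", d)]]
    x <- matched[[paste0("single_sum_", d)]]
    fit <- lm(y ~ 0 + x)
    sm <- summary(fit)$coefficients
    tibble::tibble(
      descriptor = d,
      beta = unname(coef(fit)[["x"]]),
      r = cor(x, y),
      p = sm["x", "Pr(>|t|)"],
      n = length(y)
    )
  })
  list(
    fits = dplyr::bind_rows(fits),
    matched = matched,
    unmatched = unmatched
  )
}

# ---- FitResult plumbing ----

new_phos_fit <- function(label, response, terms, n, aic, bic, vif,
                         intercept, random, model) {
  structure(
    list(
      label = label, response = response, terms = terms, n = n,
      aic = aic, bic = bic, vif = vif, intercept = intercept,
      random = random, model = model
    ),
    class = "phos_fit"
  )
}

#' @export
print.phos_fit <- function(x, ...) {
  cat(sprintf(
    "<phos_fit> %s ~ %s (n = %d, %s)\n", x$response,
    paste(x$terms$term, collapse = " + "), x$n,
    if (identical(x$random, "none")) "OLS" else paste("random:", x$random)
  ))
  print(as.data.frame(x$terms), row.names = FALSE)
  cat(sprintf("  AIC %.3f  BIC %.3f\n", x$aic, x$bic))
  invisible(x)
}

#' Tidy a fit into a report row set with Bonferroni stars
#'
#' @param fit `phos_fit` object.
#' @param m Bonferroni family size (default: number of terms).
#' @return tibble with `model`, `response`, `term`, `beta`, `r`, `p`,
#'   `p_adj`, `stars`, `vif`, `n`.
#' @export
tidy_fit <- function(fit, m = nrow(fit$terms)) {
  stopifnot(inherits(fit, "phos_fit"))
  bf <- bonferroni(fit$terms$p, m = m)
  tibble::tibble(
    model = fit$label,
    response = fit$response,
    term = fit$terms$term,
    beta = fit$terms$beta,
    r = fit$terms$r,
    p = fit$terms$p,
    p_adj = bf$p_adj,
    stars = bf$stars,
    vif = if (is.null(fit$vif)) NA_real_ else unname(fit$vif[fit$terms$term]),
    n = fit$n
  )
}

# ---- internal helpers ----

prepare_design <- function(data, response, predictors, standardize,
                           extra = NULL) {
  cols <- c(response, predictors, extra)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("column(s) not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(data[, cols, drop = FALSE])
  df <- df[complete.cases(df), , drop = FALSE]
  if (standardize) {
    for (p in predictors) {
      s <- sd(df[[p]])
      if (!is.finite(s) || s == 0) {
        stop("zero-variance predictor: ", p, call. = FALSE)
      }
      df[[p]] <- (df[[p]] - mean(df[[p]])) / s
    }
  }
  df
}

check_rank <- function(df, predictors, intercept) {
  X <- as.matrix(df[, predictors, drop = FALSE])
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
}

fit_formula <- function(response, predictors, intercept) {
  stats::as.formula(paste(
    response, "~", if (intercept) "" else "0 +",
    paste(predictors, collapse = " + ")
  ))
}
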