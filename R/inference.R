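## Mixed-model layer: linear and generalized linear mixed models with a
## single random intercept (lme4 backend), AICc stepwise selection,
## CI-based informativeness, Nakagawa marginal/conditional R-squared, and
## the resource-selection-function front end.

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters (fixed effects + variance
#'   components).
#' @param n Number of observations.
#' @return AICc (Inf when `n <= k + 1`, where the correction blows up).
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

## Assemble the common fit container from a merMod.
as_model_fit <- function(fit, family, reference_level = NA_character_) {
  sm <- summary(fit)
  co <- sm$coefficients
  z <- qnorm(0.975)
  coefs <- tibble::tibble(
    term = rownames(co), estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    ci_low = co[, "Estimate"] - z * co[, "Std. Error"],
    ci_high = co[, "Estimate"] + z * co[, "Std. Error"])
  vc <- lme4::VarCorr(fit)
  sigma2_b <- as.numeric(vc[[1]][1, 1])
  sigma2_resid <- if (family == "gaussian") stats::sigma(fit)^2 else NA_real_
  ll <- as.numeric(logLik(fit))
  n <- stats::nobs(fit)
  k <- nrow(co) + 1L + (family == "gaussian")  # + RE variance (+ residual)
  structure(list(fit = fit, family = family, coefficients = coefs,
                 random_intercept_variance = sigma2_b,
                 residual_variance = sigma2_resid,
                 log_likelihood = ll, n_obs = n, k_params = k,
                 aicc = aicc(ll, k, n),
                 reference_level = reference_level),
            class = "owl_model_fit")
}

#' @exportS3Method base::print
print.owl_model_fit <- function(x, ...) {
  cat("<owl_model_fit> family =", x$family,
      " n =", x$n_obs, " k =", x$k_params,
      sprintf(" AICc = %.2f\n", x$aicc))
  df <- as.data.frame(x$coefficients)
  df[, -1] <- round(df[, -1], 4)
  print(df, row.names = FALSE)
  cat(sprintf("random intercept variance = %.4f", x$random_intercept_variance))
  if (x$family == "gaussian") {
    cat(sprintf(", residual variance = %.4f", x$residual_variance))
  }
  cat("\n")
  invisible(x)
}

## Abort with the names of aliased columns when the fixed-effect design is
## rank deficient.
check_full_rank <- function(formula, data) {
  X <- model.matrix(lme4::nobars(formula), data)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

with_random_intercept <- function(formula, group) {
  as.formula(paste(deparse(formula, width.cutoff = 500L), "+ (1 |", group, ")"),
             env = environment(formula))
}

#' Linear mixed model with one random intercept
#'
#' REML fit (by default) of a Gaussian response with a single Gaussian
#' random intercept; Wald 95% confidence intervals.
#'
#' @param data Data frame.
#' @param formula Fixed-effects formula, e.g. `log_dist ~ sex * hour`.
#' @param group Name of the random-intercept grouping column (owl id).
#' @param reml Use REML (`TRUE`) or ML (`FALSE`; required when comparing
#'   models differing in fixed effects, as in stepwise selection).
#' @return An `owl_model_fit`.
#' @export
fit_lmm <- function(data, formula, group, reml = TRUE) {
  resp <- eval(formula[[2]], data)
  if (!is.numeric(resp)) stop("response must be numeric for a LMM")
  if (nrow(data) < 2) stop("need at least 2 observations")
  if (length(unique(data[[group]])) < 2) {
    stop("need >= 2 groups to estimate the random-intercept variance")
  }
  check_full_rank(formula, data)
  fit <- lme4::lmer(with_random_intercept(formula, group), data = data,
                    REML = reml,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  as_model_fit(fit, "gaussian")
}

## Conservative complete-separation screen: a factor level whose binary
## response is constant yields an infinite coefficient.
check_separation <- function(formula, data, resp) {
  vars <- all.vars(lme4::nobars(formula)[[3]])
  for (v in vars) {
    col <- data[[v]]
    if (is.character(col) || is.factor(col)) {
      m <- tapply(resp, col, mean)
      m <- m[!is.na(m)]
      if (any(m == 0 | m == 1)) {
        bad <- names(m)[m == 0 | m == 1]
        stop("complete separation: response is constant within '", v,
             "' level(s) ", paste(bad, collapse = ", "))
      }
    }
  }
  invisible(TRUE)
}

#' Generalized linear mixed model with one random intercept
#'
#' Maximum likelihood via adaptive Gauss-Hermite quadrature (default 15
#' nodes) over a single Gaussian random intercept; Wald 95% confidence
#' intervals on the link scale.
#'
#' @inheritParams fit_lmm
#' @param family `"binomial"` (logit link) or `"poisson"` (log link).
#' @param nagq Number of adaptive quadrature nodes (1 = Laplace).
#' @param check_sep Run the complete-separation pre-check (binomial only).
#'   [fit_rsf()] disables it: a land-cover class observed on only one side
#'   of the used/available design is reported as an unstable coefficient
#'   rather than an error.
#' @return An `owl_model_fit`.
#' @export
fit_glmm <- function(data, formula, family = c("binomial", "poisson"),
                     group, nagq = 15L, check_sep = TRUE) {
  family <- match.arg(family)
  resp <- eval(formula[[2]], data)
  if (family == "poisson") {
    if (any(resp < 0) || any(resp != round(resp))) {
      stop("Poisson GLMM requires a non-negative integer response")
    }
  } else if (check_sep) {
    check_separation(formula, data, resp)
  }
  check_full_rank(formula, data)
  fam <- if (family == "binomial") stats::binomial("logit") else stats::poisson("log")
  fit <- lme4::glmer(with_random_intercept(formula, group), data = data,
                     family = fam, nAGQ = as.integer(nagq),
                     control = lme4::glmerControl(check.conv.singular = "ignore",
                                                  calc.derivs = FALSE))
  out <- as_model_fit(fit, family)
  if (family == "poisson" && nagq > 1) {
    ## lme4 reports the AGQ fit's -deviance/2 (relative to the saturated
    ## model); add the saturated log-likelihood so values are comparable
    ## across nAGQ and with plain GLMs
    out$log_likelihood <- out$log_likelihood + sum(stats::dpois(resp, resp, log = TRUE))
    out$aicc <- aicc(out$log_likelihood, out$k_params, out$n_obs)
  }
  out
}

#' Fit a logistic resource selection function
#'
#' Mixed-effects logistic regression of used (1) versus available (0)
#' positions: land-cover class dummy-coded against the reference level
#' (cereal), standardized distance to field edges (and optionally to
#' roads), an optional habitat x nest-distance interaction, and the
#' individual as random intercept.
#'
#' @param table A used/available tibble from [used_available_table()].
#' @param reference Reference land-cover class.
#' @param include_road Include standardized distance to roads.
#' @param include_nest_interaction Add standardized nest distance and its
#'   interaction with land cover.
#' @param nagq Quadrature nodes (1 = Laplace, the default for these large
#'   designs; raise it for small tables).
#' @return An `owl_model_fit` with extra fields: `reference_level`,
#'   `scaling` (means/sds used for the z-scores), `design_ratio`
#'   (available:used), `unstable_classes`.
#' @export
fit_rsf <- function(table, reference = "cereal", include_road = TRUE,
                    include_nest_interaction = FALSE, nagq = 1L) {
  stopifnot(all(c("id", "used", "x_m", "y_m", "land_cover",
                  "dist_edge_m", "dist_nest_m") %in% names(table)))
  n_used <- sum(table$used == 1); n_avail <- sum(table$used == 0)
  if (n_used == 0) stop("table contains no used rows")
  if (n_avail == 0) stop("table contains no available rows")
  per_ind <- table(table$id, table$used)
  if (any(per_ind == 0)) {
    stop("every individual needs both used and available rows")
  }
  ## classes seen on only one side of the design give unstable coefficients
  cls_used <- unique(table$land_cover[table$used == 1])
  cls_avail <- unique(table$land_cover[table$used == 0])
  unstable <- union(setdiff(cls_used, cls_avail), setdiff(cls_avail, cls_used))
  if (length(unstable)) {
    warning("land-cover class(es) present only in used or only in available ",
            "rows; coefficient(s) unstable: ", paste(unstable, collapse = ", "))
  }
  d <- table
  if (!reference %in% d$land_cover) {
    stop("reference class '", reference, "' absent from the table")
  }
  d$land_cover <- stats::relevel(factor(d$land_cover), ref = reference)
  scaling <- list(
    dist_edge = c(mean = mean(d$dist_edge_m), sd = sd(d$dist_edge_m)),
    dist_road = c(mean = mean(d$dist_road_m), sd = sd(d$dist_road_m)),
    dist_nest = c(mean = mean(d$dist_nest_m), sd = sd(d$dist_nest_m)))
  d$dist_edge_s <- (d$dist_edge_m - scaling$dist_edge["mean"]) / scaling$dist_edge["sd"]
  d$dist_road_s <- (d$dist_road_m - scaling$dist_road["mean"]) / scaling$dist_road["sd"]
  d$dist_nest_s <- (d$dist_nest_m - scaling$dist_nest["mean"]) / scaling$dist_nest["sd"]
  rhs <- "land_cover + dist_edge_s"
  if (include_road) rhs <- paste(rhs, "+ dist_road_s")
  if (include_nest_interaction) {
    rhs <- paste(rhs, "+ dist_nest_s + land_cover:dist_nest_s")
  }
  f <- as.formula(paste("used ~", rhs))
  out <- fit_glmm(d, f, family = "binomial", group = "id", nagq = nagq,
                  check_sep = FALSE)
  out$reference_level <- reference
  out$scaling <- scaling
  out$design_ratio <- n_avail / n_used
  out$unstable_classes <- unstable
  out$classes <- levels(d$land_cover)
  out
}

#' Relative probability of use per land-cover class
#'
#' Predicted probability that a position of a given class is a used (owl)
#' rather than available (random-walk) position, evaluated at the mean
#' distance covariates (z-scores of 0) and a random effect of 0. Under a
#' used:available design ratio of 1:R the no-selection reference value is
#' `1/(1+R)` — the study's dashed 0.1 line for R = 10; classes above it are
#' selected, below it avoided.
#'
#' @param fit An RSF `owl_model_fit` from [fit_rsf()].
#' @param classes Classes to evaluate (default: all classes in the fit).
#' @param drop_unstable Exclude classes whose coefficient was flagged
#'   unstable (present only in used or only in available rows); their
#'   predicted probabilities are degenerate (0 or 1 in the limit).
#' @return Tibble `class, rel_prob`, with attribute `null_line`.
#' @export
relative_probability_of_use <- function(fit, classes = NULL,
                                        drop_unstable = TRUE) {
  stopifnot(inherits(fit, "owl_model_fit"))
  if (is.null(fit$classes)) stop("not a resource selection fit")
  if (is.null(classes)) {
    classes <- fit$classes
    if (drop_unstable) classes <- setdiff(classes, fit$unstable_classes)
  }
  missing_cls <- setdiff(classes, fit$classes)
  if (length(missing_cls)) {
    stop("class(es) absent from the fit: ", paste(missing_cls, collapse = ", "))
  }
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  b0 <- est[["(Intercept)"]]
  eta <- vapply(classes, function(cl) {
    if (cl == fit$reference_level) b0 else b0 + est[[paste0("land_cover", cl)]]
  }, numeric(1))
  out <- tibble::tibble(class = classes, rel_prob = unname(plogis(eta)))
  attr(out, "null_line") <- 1 / (1 + fit$design_ratio)
  out
}

#' Backward stepwise selection on AICc
#'
#' Starting from the full model, repeatedly deletes the single term whose
#' removal lowers AICc the most, respecting marginality (main effects are
#' kept while their interaction remains), and stops when no deletion
#' lowers AICc. Gaussian models are compared on ML fits (REML
#' likelihoods are not comparable across fixed-effect structures). When
#' two deletions tie exactly, the term appearing later in the formula is
#' dropped. Candidates whose AICc correction is undefined (`n <= k + 1`)
#' are skipped with a warning.
#'
#' @param data Data frame.
#' @param full_formula Fixed-effects formula of the full model.
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param group Random-intercept grouping column.
#' @param nagq Quadrature nodes for GLMM fits.
#' @return List: `best` (`owl_model_fit`), `best_formula`, and `table`
#'   comparing best / full / intercept-only models (AICc, log-likelihood,
#'   k, marginal and conditional R-squared).
#' @export
aicc_stepwise <- function(data, full_formula, family = "gaussian", group,
                          nagq = 15L) {
  fitter <- function(f) {
    if (family == "gaussian") fit_lmm(data, f, group, reml = FALSE)
    else fit_glmm(data, f, family = family, group = group, nagq = nagq)
  }
  current_f <- full_formula
  current <- fitter(current_f)
  full <- current
  repeat {
    cands <- stats::drop.scope(current_f)
    if (length(cands) == 0) break
    scores <- rep(NA_real_, length(cands))
    for (i in seq_along(cands)) {
      red_f <- update.formula(current_f, paste(". ~ . -", cands[i]))
      red <- try(fitter(red_f), silent = TRUE)
      if (inherits(red, "try-error")) next
      if (!is.finite(red$aicc)) {
        warning("candidate '", cands[i], "' skipped: n <= k + 1")
        next
      }
      scores[i] <- red$aicc
    }
    if (all(is.na(scores)) || min(scores, na.rm = TRUE) >= current$aicc) break
    best_score <- min(scores, na.rm = TRUE)
    tied <- which(!is.na(scores) & scores == best_score)
    drop_term <- cands[max(tied)]  # later term in formula order on ties
    current_f <- update.formula(current_f, paste(". ~ . -", drop_term))
    current <- fitter(current_f)
  }
  null_f <- update.formula(full_formula, ". ~ 1")
  null_fit <- fitter(null_f)
  row <- function(name, f, fit) {
    r2 <- nakagawa_r2(fit)
    tibble::tibble(model = name,
                   formula = deparse(lme4::nobars(f), width.cutoff = 500L),
                   aicc = fit$aicc, log_likelihood = fit$log_likelihood,
                   k = fit$k_params, r2_marginal = r2$R2_marginal,
                   r2_conditional = r2$R2_conditional)
  }
  list(best = current, best_formula = current_f,
       table = rbind(row("best", current_f, current),
                     row("full", full_formula, full),
                     row("intercept_only", null_f, null_fit)))
}

#' Nakagawa marginal and conditional R-squared
#'
#' `R2m = var_f / (var_f + var_b + var_d)` and
#' `R2c = (var_f + var_b) / (var_f + var_b + var_d)`, where `var_f` is the
#' variance of the fixed-effect linear predictor, `var_b` the
#' random-intercept variance, and `var_d` the distribution-specific
#' variance: the residual variance (Gaussian), `pi^2/3` (logit), or the
#' trigamma of the expected count at the model intercept (Poisson log
#' link, trigamma method).
#'
#' @param fit An `owl_model_fit`.
#' @return List `R2_marginal`, `R2_conditional`.
#' @export
nakagawa_r2 <- function(fit) {
  if (!inherits(fit, "owl_model_fit")) stop("nakagawa_r2 needs a fitted model")
  mm <- model.matrix(fit$fit)
  beta <- lme4::fixef(fit$fit)
  var_f <- if (length(beta) > 1) var(as.numeric(mm %*% beta)) else 0
  var_b <- fit$random_intercept_variance
  var_d <- switch(fit$family,
    gaussian = fit$residual_variance,
    binomial = pi^2 / 3,
    poisson = {
      lambda <- exp(unname(beta["(Intercept)"]) + 0.5 * var_b)
      trigamma(lambda)
    })
  tot <- var_f + var_b + var_d
  list(R2_marginal = var_f / tot, R2_conditional = (var_f + var_b) / tot)
}

#' Flag informative model terms
#'
#' A term is informative when its 95% confidence interval excludes zero
#' (boundary inclusive intervals count as uninformative).
#'
#' @param fit An `owl_model_fit`.
#' @return Tibble `term, informative`.
#' @export
informative_flags <- function(fit) {
  if (!inherits(fit, "owl_model_fit")) stop("informative_flags needs a model fit")
  co <- fit$coefficients
  tibble::tibble(term = co$term,
                 informative = co$ci_low > 0 | co$ci_high < 0)
}

#' Screen fixed effects for collinearity
#'
#' Pearson correlations between all pairs of numeric covariates; pairs at
#' or above the threshold are flagged, and constant columns are flagged as
#' having undefined correlation.
#'
#' @param data Data frame.
#' @param term_names Names of numeric covariate columns (>= 2).
#' @param threshold Absolute correlation flag level (study rule: 0.6).
#' @return List with `pairs` (tibble `term1, term2, r, flagged`) and
#'   `undefined` (constant columns).
#' @export
screen_collinearity <- function(data, term_names, threshold = 0.6) {
  stopifnot(length(term_names) >= 2)
  cols <- data[term_names]
  const <- vapply(cols, function(x) sd(x, na.rm = TRUE) == 0, logical(1))
  undefined <- term_names[const]
  ok <- term_names[!const]
  rows <- list()
  if (length(ok) >= 2) {
    cmb <- utils::combn(ok, 2)
    for (j in seq_len(ncol(cmb))) {
      r <- cor(data[[cmb[1, j]]], data[[cmb[2, j]]],
               use = "pairwise.complete.obs")
      rows[[j]] <- tibble::tibble(term1 = cmb[1, j], term2 = cmb[2, j],
                                  r = r, flagged = abs(r) >= threshold)
    }
  }
  list(pairs = if (length(rows)) do.call(rbind, rows) else
         tibble::tibble(term1 = character(), term2 = character(),
                        r = numeric(), flagged = logical()),
       undefined = undefined)
}
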