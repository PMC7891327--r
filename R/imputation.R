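# Chained-equations multiple imputation tailored to the cohort schema.
#
# Each incomplete column is imputed from a conditional model on all other
# covariates plus the outcome, with proper Bayesian parameter draws so that
# between-imputation variance is honestly propagated into Rubin pooling:
#  - continuous: normal linear model, sigma^2 drawn from its scaled inverse
#    chi-square posterior and beta from N(betahat, sigma^2 (X'X)^-1);
#  - binary: logistic model, beta drawn from N(betahat, vcov);
#  - categorical (incl. parity levels): multinomial logit via nnet::multinom
#    with a parameter draw from its estimated covariance.
# Glucose is modelled on the natural-log scale (it is right-skewed and must
# stay positive). BMI is never regression-imputed: it is back-computed from
# height and weight (and weight back-solved from observed BMI) so the
# BMI = weight/height^2 identity survives imputation.

.continuous_cols  <- c("age_years", "height_cm", "weight_kg", "sbp_mmhg", "glucose_mmol_l")
.binary_cols      <- c("smoking", "family_history_dm", "history_gdm", "history_macrosomia")
.categorical_cols <- c("ethnicity", "education", "conception")

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of the cohort (default 10, matching the
#' ten-imputation analysis the pipeline emulates). Within each chain, missing
#' cells are initialised by sampling observed values of the same column and
#' the conditional models are cycled for `n_iter` sweeps. Deterministic given
#' `seed`.
#'
#' @param cohort cohort `data.frame`; the `gdm` outcome must be complete.
#' @param m number of imputations (>= 2).
#' @param seed integer RNG seed.
#' @param n_iter chained-equation sweeps per chain.
#' @return object of class `imputed_set`: list with `m`, `tables` (list of
#'   completed data.frames), `seed`, `iterations`.
#' @export
impute <- function(cohort, m = 10L, seed = 1L, n_iter = 10L) {
  stopifnot(is.data.frame(cohort))
  if (m < 2) stop("m must be >= 2 for Rubin pooling")
  if (anyNA(cohort$gdm)) stop("outcome column 'gdm' must be complete")
  all_missing <- names(cohort)[vapply(cohort, function(x) all(is.na(x)), logical(1))]
  if (length(all_missing)) {
    stop("column(s) entirely missing, no conditional model possible: ",
         paste(all_missing, collapse = ", "))
  }
  set.seed(seed)
  tables <- lapply(seq_len(m), function(i) .impute_one_chain(cohort, n_iter))
  structure(list(m = as.integer(m), tables = tables, seed = as.integer(seed),
                 iterations = as.integer(n_iter)),
            class = "imputed_set")
}

.impute_one_chain <- function(cohort, n_iter) {
  miss <- lapply(cohort, is.na)
  incomplete <- names(cohort)[vapply(miss, any, logical(1))]
  if (!length(incomplete)) return(cohort)
  tbl <- cohort

  # initialise by sampling observed values
  for (col in incomplete) {
    obs <- tbl[[col]][!miss[[col]]]
    tbl[[col]][miss[[col]]] <- sample(obs, sum(miss[[col]]), replace = TRUE)
  }
  tbl <- .passive_bmi(tbl, miss)

  model_cols <- setdiff(incomplete, "bmi")
  for (iter in seq_len(n_iter)) {
    for (col in model_cols) {
      idx <- miss[[col]]
      X <- .imputation_design(tbl, col)
      if (col %in% .continuous_cols) {
        y <- tbl[[col]]
        log_scale <- col == "glucose_mmol_l"
        if (log_scale) y <- log(y)
        draw <- .draw_normal(X[!idx, , drop = FALSE], y[!idx], X[idx, , drop = FALSE])
        tbl[[col]][idx] <- if (log_scale) exp(draw) else draw
      } else if (col %in% .binary_cols) {
        pr <- .draw_binary_prob(X[!idx, , drop = FALSE], tbl[[col]][!idx],
                                X[idx, , drop = FALSE])
        tbl[[col]][idx] <- stats::rbinom(sum(idx), 1L, pr)
      } else {
        lv <- as.character(sort(unique(cohort[[col]][!miss[[col]]])))
        drawn <- .draw_categorical(X[!idx, , drop = FALSE],
                                   as.character(tbl[[col]][!idx]),
                                   X[idx, , drop = FALSE], lv)
        tbl[[col]][idx] <- if (col == "parity") as.integer(drawn) else drawn
      }
    }
    tbl <- .passive_bmi(tbl, miss)
    # parity 0 implies no obstetric history
    for (col in c("history_gdm", "history_macrosomia")) {
      if (col %in% incomplete) tbl[[col]][miss[[col]] & tbl$parity == 0L] <- 0L
    }
  }
  tbl
}

# keep bmi = weight/(height/100)^2 coherent: any two observed members of the
# (bmi, height, weight) triple determine the third, and bmi is never
# regression-imputed, so recompute missing members deterministically after
# each sweep
.passive_bmi <- function(tbl, miss) {
  if (!is.null(miss$height_cm)) {
    fx <- miss$height_cm & !miss$bmi & !miss$weight_kg
    tbl$height_cm[fx] <- 100 * sqrt(tbl$weight_kg[fx] / tbl$bmi[fx])
  }
  if (!is.null(miss$weight_kg)) {
    fx <- miss$weight_kg & !miss$bmi
    tbl$weight_kg[fx] <- tbl$bmi[fx] * (tbl$height_cm[fx] / 100)^2
  }
  if (!is.null(miss$bmi)) {
    tbl$bmi[miss$bmi] <- tbl$weight_kg[miss$bmi] / (tbl$height_cm[miss$bmi] / 100)^2
  }
  tbl
}

# design matrix of all covariates except the target (and except bmi, which is
# collinear with height+weight by construction), plus the outcome
.imputation_design <- function(tbl, target) {
  keep <- setdiff(names(tbl), c(target, "bmi"))
  parts <- lapply(keep, function(col) {
    x <- tbl[[col]]
    if (is.character(x)) {
      lv <- sort(unique(x))
      if (length(lv) < 2L) return(NULL)
      m <- outer(x, lv[-1L], `==`) * 1
      colnames(m) <- paste0(col, "_", lv[-1L])
      m
    } else {
      m <- matrix(as.numeric(x), ncol = 1L)
      colnames(m) <- col
      m
    }
  })
  parts <- Filter(Negate(is.null), parts)
  cbind(`(Intercept)` = 1, do.call(cbind, parts))
}

# proper Bayesian linear-regression draw (ridge-stabilised)
.draw_normal <- function(X, y, Xmis) {
  p <- ncol(X)
  XtX <- crossprod(X) + diag(1e-6, p)
  Xty <- crossprod(X, y)
  V <- solve(XtX)
  betahat <- drop(V %*% Xty)
  res <- y - drop(X %*% betahat)
  nu <- max(length(y) - p, 1L)
  s2 <- sum(res^2) / nu
  sigma2 <- nu * s2 / stats::rchisq(1L, nu)
  beta <- betahat + drop(t(chol(sigma2 * V)) %*% stats::rnorm(p))
  drop(Xmis %*% beta) + stats::rnorm(nrow(Xmis), 0, sqrt(sigma2))
}

.draw_binary_prob <- function(X, y, Xmis) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || any(!is.finite(fit$coefficients))) {
    return(rep(mean(y), nrow(Xmis)))  # frequency fallback for degenerate fits
  }
  beta <- fit$coefficients
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w)) + diag(1e-6, ncol(X))
  V <- solve(XtWX)
  beta_star <- beta + drop(t(chol(V)) %*% stats::rnorm(length(beta)))
  stats::plogis(pmin(30, pmax(-30, drop(Xmis %*% beta_star))))
}

.draw_categorical <- function(X, y, Xmis, levels_) {
  if (length(levels_) < 2L) return(rep(levels_, nrow(Xmis)))
  fit <- tryCatch(
    suppressWarnings(nnet::multinom(factor(y, levels = levels_) ~ X - 1,
                                    trace = FALSE, maxit = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    pr <- as.numeric(table(factor(y, levels = levels_)) / length(y))
    return(sample(levels_, nrow(Xmis), replace = TRUE, prob = pr))
  }
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L)
  # perturb coefficients with their approximate standard errors
  se <- tryCatch(summary(fit)$standard.errors, error = function(e) NULL)
  if (!is.null(se)) {
    if (is.null(dim(se))) se <- matrix(se, nrow = 1L)
    se[!is.finite(se)] <- 0
    cf <- cf + matrix(stats::rnorm(length(cf)), nrow(cf)) * se
  }
  eta <- cbind(0, Xmis %*% t(cf))
  eta <- pmin(eta, 30)
  pr <- exp(eta) / rowSums(exp(eta))
  vapply(seq_len(nrow(pr)), function(i) sample(levels_, 1L, prob = pr[i, ]),
         character(1))
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' Point estimate is the mean of per-imputation estimates; total variance is
#' within + (1 + 1/m) x between, with no transformation of the estimates.
#' Interval uses the Barnard-Rubin small-sample degrees of freedom when a
#' complete-data df is supplied, otherwise a normal reference.
#'
#' @param estimates numeric vector of per-imputation point estimates.
#' @param variances numeric vector of per-imputation variances (same length).
#' @param conf confidence level.
#' @param df_complete complete-data degrees of freedom for the Barnard-Rubin
#'   adjustment; `Inf` (default) gives the normal reference.
#' @return object of class `pooled_estimate`: `qbar`, `W`, `B`, `T`, `m`,
#'   `df`, `ci_low`, `ci_high`.
#' @export
rubin_pool <- function(estimates, variances, conf = 0.95, df_complete = Inf) {
  m <- length(estimates)
  if (m < 2) stop("need at least 2 imputations to pool")
  if (length(variances) != m) stop("estimates and variances differ in length")
  if (any(variances < 0)) stop("variances must be non-negative")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  if (Tv > 0) {
    lambda <- (1 + 1 / m) * B / Tv
    if (lambda > 0 && is.finite(df_complete)) {
      nu_old <- (m - 1) / lambda^2
      nu_obs <- (df_complete + 1) / (df_complete + 3) * df_complete * (1 - lambda)
      df <- nu_old * nu_obs / (nu_old + nu_obs)
    } else if (lambda > 0) {
      df <- (m - 1) / lambda^2
    } else {
      df <- Inf
    }
  } else {
    df <- Inf
  }
  crit <- if (is.finite(df)) stats::qt(1 - (1 - conf) / 2, df) else
    stats::qnorm(1 - (1 - conf) / 2)
  structure(list(qbar = qbar, W = W, B = B, T = Tv, m = m, df = df,
                 ci_low = qbar - crit * sqrt(Tv),
                 ci_high = qbar + crit * sqrt(Tv)),
            class = "pooled_estimate")
}

#' Stack an imputed set into one long table
#'
#' Concatenates the `m` completed tables row-wise with an added `imputation`
#' index column; used for calibration plots that treat the imputed data sets
#' as one large data set.
#'
#' @param imputed an `imputed_set` from [impute()].
#' @return long `data.frame` with an `imputation` column.
#' @export
stack_imputations <- function(imputed) {
  stopifnot(inherits(imputed, "imputed_set"))
  out <- do.call(rbind, lapply(seq_along(imputed$tables), function(i) {
    tbl <- imputed$tables[[i]]
    tbl$imputation <- i
    tbl
  }))
  rownames(out) <- NULL
  out
}

#' Rebuild an imputed set from its stacked long form
#'
#' Inverse of [stack_imputations()]: splits on the `imputation` column and
#' drops it.
#'
#' @param stacked long `data.frame` with an `imputation` column.
#' @return an `imputed_set`.
#' @export
unstack_imputations <- function(stacked) {
  if (is.null(stacked$imputation)) stop("stacked table lacks an 'imputation' column")
  idx <- sort(unique(stacked$imputation))
  tables <- lapply(idx, function(i) {
    tbl <- stacked[stacked$imputation == i, setdiff(names(stacked), "imputation")]
    rownames(tbl) <- NULL
    tbl
  })
  structure(list(m = length(tables), tables = tables, seed = NA_integer_,
                 iterations = NA_integer_),
            class = "imputed_set")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("<pooled_estimate> qbar %.4f (95%% CI %.4f-%.4f)  W %.3g  B %.3g  T %.3g  m %d\n",
              x$qbar, x$ci_low, x$ci_high, x$W, x$B, x$T, x$m))
  invisible(x)
}
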