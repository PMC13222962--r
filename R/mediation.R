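#' Linear mediation with bootstrap ACME inference
#'
#' Fits the two OLS regressions `M ~ X (+ covariates)` and
#' `Y ~ X + M (+ covariates)`; the average causal mediation effect is the
#' product `ACME = a * b` of the X->M and M->Y|X coefficients, the average
#' direct effect is `c'`, and the total effect is `c` from `Y ~ X
#' (+ covariates)` (which equals `c' + a b` exactly in OLS). Confidence
#' intervals are percentile intervals over nonparametric case-resampling
#' bootstrap draws; the bootstrap p-value is `2 * min(frac <= 0,
#' frac >= 0)`.
#'
#' @param data data.frame holding the variables.
#' @param x,m,y column names of the exposure, mediator and outcome.
#' @param covariates optional character vector of covariate column names.
#' @param n_boot bootstrap draws (0 skips the bootstrap: point estimates
#'   only).
#' @param seed integer seed for the bootstrap.
#' @param conf_level CI level.
#' @return list of class `bb_mediation`: path estimates `a`, `b`, `c_prime`,
#'   `total`, `acme`, `ade`, `prop_mediated`, bootstrap `ci_acme`,
#'   `ci_total`, `p_acme`, `p_total`, `n`, `n_boot`, `seed`.
#' @export
fit_mediation <- function(data, x, m, y, covariates = NULL, n_boot = 5000,
                          seed = 1L, conf_level = 0.95) {
  cols <- c(x, m, y, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data[, cols, drop = FALSE]
  cc <- complete.cases(df)
  if (sum(!cc) > 0) {
    message("dropping ", sum(!cc), " incomplete cases")
  }
  df <- df[cc, , drop = FALSE]
  n <- nrow(df)
  if (n < 10) stop("need at least 10 complete cases", call. = FALSE)
  if (var(df[[x]]) == 0 || var(df[[m]]) == 0) {
    stop("zero-variance exposure or mediator", call. = FALSE)
  }
  covm <- if (length(covariates)) as.matrix(df[, covariates, drop = FALSE])
          else NULL

  paths <- function(d, covmat) {
    xm <- cbind(1, d[[x]], covmat)
    a <- stats::lm.fit(xm, d[[m]])$coefficients[2]
    xym <- cbind(1, d[[x]], d[[m]], covmat)
    cf <- stats::lm.fit(xym, d[[y]])$coefficients
    if (any(is.na(cf[2:3]))) {
      stop("mediator is collinear with the exposure: paths not identifiable",
           call. = FALSE)
    }
    c_prime <- cf[2]
    b <- cf[3]
    total <- stats::lm.fit(xm, d[[y]])$coefficients[2]
    c(a = unname(a), b = unname(b), c_prime = unname(c_prime),
      total = unname(total))
  }
  est <- paths(df, covm)
  acme <- est["a"] * est["b"]

  ci_acme <- ci_total <- c(NA_real_, NA_real_)
  p_acme <- p_total <- NA_real_
  boot_acme <- boot_total <- NULL
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    boots <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      paths(df[idx, , drop = FALSE],
            if (is.null(covm)) NULL else covm[idx, , drop = FALSE])
    }, numeric(4))
    boot_acme <- boots["a", ] * boots["b", ]
    boot_total <- boots["total", ]
    alpha <- (1 - conf_level) / 2
    ci_acme <- unname(quantile(boot_acme, c(alpha, 1 - alpha)))
    ci_total <- unname(quantile(boot_total, c(alpha, 1 - alpha)))
    p_acme <- min(1, 2 * min(mean(boot_acme <= 0), mean(boot_acme >= 0)))
    p_total <- min(1, 2 * min(mean(boot_total <= 0), mean(boot_total >= 0)))
  }
  structure(list(
    a = unname(est["a"]), b = unname(est["b"]),
    c_prime = unname(est["c_prime"]), total = unname(est["total"]),
    acme = unname(acme), ade = unname(est["c_prime"]),
    prop_mediated = unname(acme / est["total"]),
    ci_acme = ci_acme, ci_total = ci_total,
    p_acme = p_acme, p_total = p_total,
    boot_se_acme = if (is.null(boot_acme)) NA_real_ else sd(boot_acme),
    n = n, n_boot = n_boot, seed = as.integer(seed),
    conf_level = conf_level
  ), class = "bb_mediation")
}

#' @method print bb_mediation
#' @export
print.bb_mediation <- function(x, ...) {
  cat(sprintf(
    "Linear mediation (n = %d)\n  a = %.4f, b = %.4f, c' = %.4f\n  ACME = %.4f [%.4f, %.4f], p = %s\n  Total = %.4f [%.4f, %.4f], p = %s\n",
    x$n, x$a, x$b, x$c_prime, x$acme, x$ci_acme[1], x$ci_acme[2],
    format.pval(x$p_acme), x$total, x$ci_total[1], x$ci_total[2],
    format.pval(x$p_total)))
  invisible(x)
}

#' Four-model mediation comparison over (bone, brain, cognition) roles
#'
#' Runs the four prespecified role assignments of the three variables
#' (bone density X, regional activity M, cognition Y):
#' model 1 `X -> M -> Y`, model 2 `Y -> M -> X`, model 3 `M -> Y -> X`, and
#' model 4 `X -> Y -> M`. A model is flagged when its bootstrap ACME CI
#' excludes zero; the best-supported model is the flagged model with the
#' largest `|ACME| / bootstrap SE`.
#'
#' @param data data.frame.
#' @param bone,brain,cognition column names of the three variables.
#' @param covariates optional covariate column names.
#' @inheritParams fit_mediation
#' @return list with `fits` (four `bb_mediation` objects), `summary`
#'   (data.frame: model, x, m, y, acme, ci, p, flagged), and `best_model`.
#' @export
compare_four_models <- function(data, bone, brain, cognition,
                                covariates = NULL, n_boot = 1000,
                                seed = 1L) {
  roles <- list(
    model1 = c(x = bone, m = brain, y = cognition),
    model2 = c(x = cognition, m = brain, y = bone),
    model3 = c(x = brain, m = cognition, y = bone),
    model4 = c(x = bone, m = cognition, y = brain)
  )
  fits <- lapply(seq_along(roles), function(i) {
    r <- roles[[i]]
    fit_mediation(data, x = r[["x"]], m = r[["m"]], y = r[["y"]],
                  covariates = covariates, n_boot = n_boot,
                  seed = child_seed(seed, i))
  })
  names(fits) <- names(roles)
  summary <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    r <- roles[[i]]
    flagged <- is.finite(f$ci_acme[1]) &&
      (f$ci_acme[1] > 0 || f$ci_acme[2] < 0)
    data.frame(model = names(roles)[i], x = r[["x"]], m = r[["m"]],
               y = r[["y"]], acme = f$acme, ci_lo = f$ci_acme[1],
               ci_hi = f$ci_acme[2], p_acme = f$p_acme, flagged = flagged,
               acme_z = abs(f$acme) / f$boot_se_acme,
               stringsAsFactors = FALSE)
  }))
  best <- if (any(summary$flagged)) {
    cand <- summary[summary$flagged, ]
    cand$model[which.max(cand$acme_z)]
  } else NA_character_
  list(fits = fits, summary = summary, best_model = best)
}
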