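#' Thickness-ranked pair randomization
#'
#' Implements randomization by randomly permuted blocks of size 2 on
#' thickness-ranked biofilms: the biofilms of one participant are ranked by
#' thickness, consecutive pairs of similar thickness are formed, and within
#' each pair one biofilm is assigned to each arm uniformly at random. Every
#' call yields exactly equal arm sizes.
#'
#' @param values Numeric vector of biofilm thicknesses for one participant
#'   (even length).
#' @param seed Integer seed.
#' @param arms Character length-2: the two arm labels.
#' @return Data frame aligned with `values`: `value`, `rank` (1 =
#'   thickest), `pair` (block index), `arm`.
#' @examples
#' rank_pair_randomize(c(22, 10, 20, 12), seed = 1)
#' @export
rank_pair_randomize <- function(values, seed, arms = c("enzyme", "control")) {
  n <- length(values)
  if (n < 2L || n %% 2L != 0L) {
    stop_biofilmq("pairing requires an even number (>= 2) of biofilms",
                  "biofilmq_pairing_error")
  }
  if (any(!is.finite(values))) {
    stop_biofilmq("thickness values must be finite",
                  "biofilmq_validation_error")
  }
  stopifnot(length(arms) == 2L)
  local_seed(seed, {
    ord <- order(values, decreasing = TRUE)
    pair_of_rank <- rep(seq_len(n / 2L), each = 2L)
    flips <- rbinom(n / 2L, 1L, 0.5)
    # the thicker biofilm of each ranked pair gets arms[1] iff flip == 1
    arm_of_rank <- character(n)
    for (k in seq_len(n / 2L)) {
      a <- if (flips[k] == 1L) arms else rev(arms)
      arm_of_rank[c(2L * k - 1L, 2L * k)] <- a
    }
    out <- data.frame(value = values,
                      rank = NA_integer_,
                      pair = NA_integer_,
                      arm = NA_character_)
    out$rank[ord] <- seq_len(n)
    out$pair[ord] <- pair_of_rank
    out$arm[ord] <- arm_of_rank
    out
  })
}

#' Consensus outlier detection
#'
#' Joint application of several outlier detection rules; a record is a
#' consensus outlier when flagged by at least half of the methods used
#' (ceiling of m/2). Methods:
#' \describe{
#'   \item{zscore}{robust z-score using median and MAD;
#'     flag when |z| >= 3.29.}
#'   \item{iqr}{flag outside the quartile fences
#'     Q1 - 1.7 IQR, Q3 + 1.7 IQR.}
#'   \item{cooks}{Cook's distance from a fitted gamma working model (needs
#'     `data` + `formula`); flag when distance > 4/n.}
#'   \item{eti}{flag outside the central 99.9 percent equal-tailed interval
#'     of the empirical distribution.}
#' }
#' Distributional methods need at least `min_n` observations; methods that
#' cannot run are skipped with a warning and the vote is taken over the
#' remaining ones.
#'
#' @param values Numeric outcome vector.
#' @param methods Character subset of `c("zscore", "iqr", "cooks", "eti")`.
#' @param data,formula Trial table and model formula for the Cook's
#'   distance working model (gamma regression, log link). `values` must be
#'   the model response.
#' @param zscore_cut,iqr_factor,eti_level,cooks_factor Per-method
#'   thresholds; `cooks_factor` is the numerator of the 4/n rule.
#' @param min_n Minimum observations for the distributional methods.
#' @return An object of class `outlier_report`: `flags` (logical matrix,
#'   one column per method used), `consensus` (logical vector),
#'   `methods_used`, `thresholds`.
#' @export
detect_outliers_consensus <- function(values,
                                      methods = c("zscore", "iqr", "cooks",
                                                  "eti"),
                                      data = NULL, formula = NULL,
                                      zscore_cut = 3.29,
                                      iqr_factor = 1.7,
                                      eti_level = 0.999,
                                      cooks_factor = 4,
                                      min_n = 5) {
  methods <- match.arg(methods, several.ok = TRUE)
  x <- as.numeric(values)
  n <- length(x)
  if (any(!is.finite(x))) {
    stop_biofilmq("outcome values must be finite", "biofilmq_validation_error")
  }
  flags <- list()
  if ("zscore" %in% methods) {
    if (n >= min_n) {
      s <- mad(x)
      z <- if (s > 0) abs(x - median(x)) / s else rep(0, n)
      flags$zscore <- z >= zscore_cut
    } else {
      warning("zscore method skipped: too few observations")
    }
  }
  if ("iqr" %in% methods) {
    if (n >= min_n) {
      q <- quantile(x, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      flags$iqr <- x < q[1] - iqr_factor * iqr | x > q[2] + iqr_factor * iqr
    } else {
      warning("iqr method skipped: too few observations")
    }
  }
  if ("cooks" %in% methods) {
    if (is.null(data) || is.null(formula)) {
      warning("cooks method skipped: no accompanying design (`data` + `formula`)")
    } else if (n >= min_n) {
      fit <- fit_gamma_log(data, formula)
      d <- cooks.distance(fit)
      flags$cooks <- as.numeric(d) > cooks_factor / n
    } else {
      warning("cooks method skipped: too few observations")
    }
  }
  if ("eti" %in% methods) {
    if (n >= min_n) {
      alpha <- (1 - eti_level) / 2
      q <- quantile(x, c(alpha, 1 - alpha), names = FALSE)
      flags$eti <- x < q[1] | x > q[2]
    } else {
      warning("eti method skipped: too few observations")
    }
  }
  if (!length(flags)) {
    stop_biofilmq("no outlier detection method could run",
                  "biofilmq_validation_error")
  }
  fm <- do.call(cbind, flags)
  consensus <- rowSums(fm) >= ceiling(ncol(fm) / 2)
  structure(
    list(flags = fm,
         consensus = consensus,
         methods_used = colnames(fm),
         thresholds = list(zscore_cut = zscore_cut, iqr_factor = iqr_factor,
                           eti_level = eti_level,
                           cooks_factor = cooks_factor)),
    class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Consensus outlier report: %d of %d records flagged (methods: %s)\n",
              sum(x$consensus), length(x$consensus),
              paste(x$methods_used, collapse = ", ")))
  invisible(x)
}

#' Gamma regression with a log link
#'
#' Fits the study's outcome model for positive, right-skewed biofilm
#' outcomes: a gamma GLM with log link, so covariates act multiplicatively
#' on the mean and exp(coefficient) is a ratio of means. A pre-treatment
#' covariate enters linearly on the log-link scale.
#'
#' @param table Trial table (data frame) with the model variables.
#' @param formula Model formula, e.g. `outcome ~ treatment` or
#'   `outcome ~ treatment + pre_value`.
#' @return A fitted `glm` object.
#' @export
fit_gamma_log <- function(table, formula = outcome ~ treatment) {
  mf <- model.frame(formula, table)
  y <- model.response(mf)
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop_biofilmq("gamma regression requires strictly positive finite outcomes",
                  "biofilmq_domain_error")
  }
  fit <- glm(formula, family = Gamma(link = "log"), data = table,
             control = list(maxit = 100))
  if (!fit$converged) {
    stop_biofilmq("gamma regression did not converge within the iteration limit",
                  "biofilmq_convergence_error")
  }
  if (fit$rank < ncol(model.matrix(fit))) {
    stop_biofilmq("design matrix is rank deficient", "biofilmq_rank_error")
  }
  fit
}

#' Ordinary linear regression for pH outcomes
#'
#' The treatment effect on biofilm pH is estimated on the identity scale:
#' the coefficient is the mean pH difference (enzyme minus control).
#'
#' @param table Trial table (data frame).
#' @param formula Model formula, default `outcome ~ treatment`.
#' @return A fitted `lm` object.
#' @export
fit_linear <- function(table, formula = outcome ~ treatment) {
  fit <- lm(formula, data = table)
  p <- ncol(model.matrix(fit))
  if (fit$rank < p) {
    stop_biofilmq("design matrix is rank deficient", "biofilmq_rank_error")
  }
  fit
}

#' Cluster (participant) bootstrap for regression estimates
#'
#' Resamples participants with replacement (all records of a resampled
#' participant travel together), refits the model on each replicate, and
#' returns bootstrap standard errors, percentile 95 percent confidence
#' intervals, and two-sided p-values from the normal-approximation Wald
#' statistic (original coefficient over bootstrap SE). Replicates whose
#' refit fails (non-convergence or rank-deficient resampled design) are
#' dropped and counted; more than `max_fail_frac` failures aborts.
#'
#' @param table Trial table (data frame).
#' @param formula Model formula (response on the left).
#' @param family A `glm` family: `Gamma(link = "log")` (default) or
#'   `gaussian()` for pH models.
#' @param cluster Name of the cluster (participant) column.
#' @param B Number of bootstrap replicates (>= 200).
#' @param seed Integer seed.
#' @param conf_level Confidence level for the percentile intervals.
#' @param max_fail_frac Maximum tolerated fraction of failed replicates.
#' @return An object of class `cluster_bootstrap`: `coef` (original fit),
#'   `replicates` (matrix of bootstrap coefficients), `se`, `ci` (matrix
#'   with `lower`/`upper`), `p_value`, `B`, `n_failed`, `seed`.
#' @export
cluster_bootstrap <- function(table, formula = outcome ~ treatment,
                              family = Gamma(link = "log"),
                              cluster = "participant",
                              B = 2000, seed, conf_level = 0.95,
                              max_fail_frac = 0.2) {
  if (B < 200) {
    stop_biofilmq("`B` must be >= 200", "biofilmq_validation_error")
  }
  if (!cluster %in% names(table)) {
    stop_biofilmq(sprintf("cluster column `%s` not found", cluster),
                  "biofilmq_validation_error")
  }
  fit0 <- glm(formula, family = family, data = table,
              control = list(maxit = 100))
  if (!fit0$converged || fit0$rank < ncol(model.matrix(fit0))) {
    stop_biofilmq("full-data model did not fit cleanly",
                  "biofilmq_convergence_error")
  }
  X <- model.matrix(fit0)
  y <- model.response(model.frame(fit0))
  p <- ncol(X)
  cl <- as.character(table[[cluster]])
  idx_by_cluster <- split(seq_along(cl), cl)
  ncl <- length(idx_by_cluster)
  if (ncl < 2L) {
    stop_biofilmq("cluster bootstrap requires >= 2 clusters",
                  "biofilmq_validation_error")
  }
  coef0 <- coef(fit0)
  reps <- local_seed(seed, {
    out <- matrix(NA_real_, nrow = B, ncol = p,
                  dimnames = list(NULL, colnames(X)))
    for (b in seq_len(B)) {
      take <- sample.int(ncl, ncl, replace = TRUE)
      idx <- unlist(idx_by_cluster[take], use.names = FALSE)
      fitb <- tryCatch(
        suppressWarnings(
          glm.fit(X[idx, , drop = FALSE], y[idx], family = family,
                  control = list(maxit = 100))),
        error = function(e) NULL)
      if (!is.null(fitb) && fitb$converged && fitb$rank == p) {
        out[b, ] <- fitb$coefficients
      }
    }
    out
  })
  ok <- !is.na(reps[, 1])
  n_failed <- sum(!ok)
  if (n_failed / B > max_fail_frac) {
    stop_biofilmq(sprintf(
      "unstable bootstrap: %d of %d replicates failed to refit", n_failed, B),
      "biofilmq_unstable_bootstrap_error")
  }
  reps_ok <- reps[ok, , drop = FALSE]
  alpha <- (1 - conf_level) / 2
  ci <- t(apply(reps_ok, 2, quantile, probs = c(alpha, 1 - alpha),
                names = FALSE))
  colnames(ci) <- c("lower", "upper")
  se <- apply(reps_ok, 2, sd)
  p_value <- 2 * pnorm(-abs(coef0 / se))
  structure(
    list(coef = coef0, replicates = reps_ok, se = se, ci = ci,
         p_value = p_value, B = B, n_failed = n_failed, seed = seed,
         conf_level = conf_level, fit = fit0),
    class = "cluster_bootstrap")
}

#' @export
print.cluster_bootstrap <- function(x, ...) {
  cat(sprintf("Cluster bootstrap (%d replicates, %d failed, seed %s)\n",
              x$B, x$n_failed, format(x$seed)))
  tab <- data.frame(coef = x$coef, boot_se = x$se,
                    ci_low = x$ci[, "lower"], ci_high = x$ci[, "upper"],
                    p = x$p_value)
  print(round(tab, 4))
  invisible(x)
}

#' Ratio-of-means effect report from a gamma model and its bootstrap
#'
#' Summarizes the treatment effect on the response scale:
#' `ratio_of_means = exp(treatment coefficient)`, confidence bounds as exp
#' of the bootstrap percentile bounds, a two-sided bootstrap-Wald p-value,
#' and per-arm adjusted predictions with covariates held at reference
#' values (default: sample means).
#'
#' @param bootstrap A `cluster_bootstrap` fitted with a gamma log-link
#'   model.
#' @param term Name of the treatment coefficient (default
#'   `"treatmentenzyme"`).
#' @param reference Named list of covariate reference values for the
#'   adjusted predictions; defaults to sample means of numeric covariates.
#' @return An object of class `effect_estimate`: `ratio_of_means`,
#'   `ci_low`, `ci_high`, `p_value`, `adjusted_predictions` (named per-arm
#'   response-scale predictions), `n_used`, `bootstrap_B`, `seed`.
#' @export
effect_report <- function(bootstrap, term = "treatmentenzyme",
                          reference = NULL) {
  stopifnot(inherits(bootstrap, "cluster_bootstrap"))
  if (!term %in% names(bootstrap$coef)) {
    stop_biofilmq(sprintf("coefficient `%s` not in the model", term),
                  "biofilmq_validation_error")
  }
  fit <- bootstrap$fit
  mf <- model.frame(fit)
  treat_var <- grep("^treatment$", names(mf), value = TRUE)
  adjusted <- NULL
  if (length(treat_var) == 1L) {
    arms <- levels(mf[[treat_var]])
    newdata <- data.frame(treatment = factor(arms, levels = arms))
    for (v in setdiff(names(mf), c(treat_var, names(mf)[1]))) {
      val <- if (!is.null(reference) && v %in% names(reference)) {
        reference[[v]]
      } else if (is.numeric(mf[[v]])) {
        mean(mf[[v]])
      } else {
        mf[[v]][1]
      }
      newdata[[v]] <- val
    }
    adjusted <- setNames(as.numeric(predict(fit, newdata = newdata,
                                            type = "response")), arms)
  }
  structure(
    list(ratio_of_means = unname(exp(bootstrap$coef[term])),
         ci_low = unname(exp(bootstrap$ci[term, "lower"])),
         ci_high = unname(exp(bootstrap$ci[term, "upper"])),
         p_value = unname(bootstrap$p_value[term]),
         adjusted_predictions = adjusted,
         n_used = nobs(fit),
         n_excluded = attr(bootstrap, "n_excluded"),
         bootstrap_B = bootstrap$B,
         seed = bootstrap$seed),
    class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Ratio of means (enzyme/control): %.2f (95%% CI: %.2f-%.2f; p = %.2g)\n",
              x$ratio_of_means, x$ci_low, x$ci_high, x$p_value))
  if (!is.null(x$adjusted_predictions)) {
    cat("Adjusted predictions:",
        paste(sprintf("%s %.1f", names(x$adjusted_predictions),
                      x$adjusted_predictions), collapse = "; "), "\n")
  }
  cat(sprintf("n = %d; bootstrap B = %d (seed %s)\n", x$n_used,
              x$bootstrap_B, format(x$seed)))
  invisible(x)
}
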