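#' Fit a Student-t mixture by EM
#'
#' One- or two-component mixture of t distributions with the degrees of
#' freedom fixed (default nu = 4; estimating nu is unstable at the sample
#' sizes involved and can be enabled with `estimate_df`). Runs `restarts`
#' EM starts from seeded random initializations and keeps the best
#' log-likelihood. The scale update uses the standard latent-weight form
#' `u = (nu + 1) / (nu + ((x - mu)/sigma)^2)`.
#'
#' @param values Numeric vector, >= 20 finite values.
#' @param k Number of components, 1 or 2.
#' @param seed Integer seed; fitting is deterministic given it.
#' @param nu Degrees of freedom (fixed). Default 4.
#' @param max_iter Maximum EM iterations per start. Default 500.
#' @param tol Absolute log-likelihood convergence tolerance. Default 1e-6.
#' @param restarts Number of seeded restarts. Default 5.
#' @param estimate_df If TRUE, nu is profiled over a grid (2, 4, 8, 16, 32)
#'   per start and the best likelihood kept.
#' @return A list of class `t_mixture_fit` with `k`, `mu`, `sigma`, `nu`,
#'   `weight`, `loglik`, `bic`, `n`, `converged` and `degenerate` flags.
#' @export
fit_t_mixture <- function(values, k, seed = 1L, nu = 4, max_iter = 500,
                          tol = 1e-6, restarts = 5, estimate_df = FALSE) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 20L) stop("need at least 20 finite values, got ", n)
  if (!k %in% c(1L, 2L)) stop("k must be 1 or 2")
  if (stats::sd(x) == 0) stop("constant input: no scale to fit")

  nus <- if (estimate_df) c(2, 4, 8, 16, 32) else nu
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + 1000L * (r - 1L))
    for (df in nus) {
      fit <- .t_mix_em(x, k, df, max_iter, tol)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  }
  p <- (k - 1L) + 2L * k + if (estimate_df) 1L else 0L
  best$bic <- -2 * best$loglik + p * log(n)
  best$n <- n
  structure(best, class = "t_mixture_fit")
}

.t_mix_em <- function(x, k, nu, max_iter, tol) {
  n <- length(x)
  sig_floor <- max(stats::sd(x) * 1e-6, .Machine$double.eps)
  tconst <- lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi)
  if (k == 1L) {
    mu <- unname(stats::median(x)) + stats::runif(1, -0.1, 0.1) * stats::sd(x)
    sigma <- stats::sd(x)
    weight <- 1
  } else {
    mu <- sort(unname(sample(x, 2L))) +
      stats::runif(2, -0.05, 0.05) * stats::sd(x)
    sigma <- rep(stats::sd(x) / 2, 2L)
    weight <- c(0.5, 0.5)
  }
  ll_old <- -Inf
  converged <- FALSE
  degenerate <- FALSE
  ex <- (nu + 1) / 2
  for (it in seq_len(max_iter)) {
    # E step in log space; z2 reused for the latent scale weights
    z2 <- matrix(0, n, k)
    logd <- matrix(0, n, k)
    for (j in seq_len(k)) {
      z2[, j] <- ((x - mu[j]) / sigma[j])^2
      logd[, j] <- tconst - log(sigma[j]) - ex * log1p(z2[, j] / nu) +
        log(weight[j])
    }
    if (k == 1L) {
      lse <- logd[, 1]
      resp <- matrix(1, n, 1)
    } else {
      m <- pmax(logd[, 1], logd[, 2])
      lse <- m + log(exp(logd[, 1] - m) + exp(logd[, 2] - m))
      resp <- exp(logd - lse)
    }
    ll <- sum(lse)
    u <- (nu + 1) / (nu + z2)
    # M step
    for (j in seq_len(k)) {
      ruw <- resp[, j] * u[, j]
      mu[j] <- sum(ruw * x) / sum(ruw)
      s2 <- sum(ruw * (x - mu[j])^2) / sum(resp[, j])
      sigma[j] <- sqrt(max(s2, sig_floor^2))
      if (sigma[j] <= sig_floor) degenerate <- TRUE
    }
    weight <- colMeans(resp)
    if (abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  ord <- order(mu)
  list(k = k, mu = mu[ord], sigma = sigma[ord], nu = nu,
       weight = weight[ord], loglik = ll_old, converged = converged,
       degenerate = degenerate)
}

#' Bimodality test by BIC
#'
#' Fits one- and two-component t mixtures and declares bimodality when the
#' two-component BIC is strictly lower.
#'
#' @inheritParams fit_t_mixture
#' @return A list with `bimodal` (logical), `fit1` and `fit2`.
#' @export
is_bimodal <- function(values, seed = 1L, nu = 4, restarts = 5) {
  fit1 <- fit_t_mixture(values, k = 1L, seed = seed, nu = nu,
                        restarts = restarts)
  fit2 <- fit_t_mixture(values, k = 2L, seed = seed, nu = nu,
                        restarts = restarts)
  list(bimodal = fit2$bic < fit1$bic, fit1 = fit1, fit2 = fit2)
}

#' Split samples into patients-up / patients-down
#'
#' Decision tree applied to one exemplar's normalized deconvolution scores
#' within one cohort, in order:
#' \enumerate{
#'   \item fewer than 10 samples with a positive score: the pair is
#'     excluded from survival analysis;
#'   \item more than half the scores are zero: zeros are patients-down,
#'     positives patients-up (`zero_split`);
#'   \item the score distribution is bimodal (two-component t mixture wins
#'     by BIC): samples above the upper component mean are up, below the
#'     lower component mean are down, samples strictly between the two
#'     means stay unassigned;
#'   \item otherwise the cohort is split at the median; exact-median
#'     samples go down.
#' }
#'
#' @param scores Named numeric vector (names = sample ids) of one
#'   exemplar's scores in one cohort.
#' @param config A [run_config()] (supplies the seed).
#' @param seed Optional explicit seed for the mixture fits.
#' @param strict_up_rule If TRUE, additionally requires at least 10
#'   non-zero samples inside the up group, excluding the pair otherwise
#'   (stricter reporting variant).
#' @return A list of class `group_assignment` with `sample_ids`, `label`
#'   (up/down/unassigned), `rule` (bimodal/median/zero_split/excluded) and
#'   `cutpoints`.
#' @export
split_samples <- function(scores, config = run_config(), seed = NULL,
                          strict_up_rule = FALSE) {
  if (is.null(seed)) seed <- config$rng_seed
  if (is.null(names(scores))) {
    names(scores) <- paste0("s", seq_along(scores))
  }
  n <- length(scores)
  assign_all <- function(label, rule, cutpoints = numeric(0)) {
    structure(
      list(sample_ids = names(scores),
           label = stats::setNames(rep(label, n), names(scores)),
           rule = rule, cutpoints = cutpoints),
      class = "group_assignment"
    )
  }
  if (n < 20L) {
    warning("cohort has ", n, " samples (< 20); excluded")
    return(assign_all("unassigned", "excluded"))
  }
  if (sum(scores > 0) < 10L) {
    return(assign_all("unassigned", "excluded"))
  }
  label <- stats::setNames(rep("unassigned", n), names(scores))
  if (sum(scores == 0) > 0.5 * n) {
    label[scores == 0] <- "down"
    label[scores > 0] <- "up"
    rule <- "zero_split"
    cutpoints <- 0
  } else {
    bim <- tryCatch(is_bimodal(scores, seed = seed),
                    error = function(e) list(bimodal = FALSE))
    if (isTRUE(bim$bimodal)) {
      mu_lo <- bim$fit2$mu[1]
      mu_hi <- bim$fit2$mu[2]
      label[scores > mu_hi] <- "up"
      label[scores < mu_lo] <- "down"
      rule <- "bimodal"
      cutpoints <- c(lower_mean = mu_lo, upper_mean = mu_hi)
    } else {
      med <- stats::median(scores)
      label[scores > med] <- "up"
      label[scores <= med] <- "down"
      rule <- "median"
      cutpoints <- c(median = med)
    }
  }
  if (strict_up_rule && sum(scores[label == "up"] > 0) < 10L) {
    return(assign_all("unassigned", "excluded"))
  }
  structure(
    list(sample_ids = names(scores), label = label, rule = rule,
         cutpoints = cutpoints),
    class = "group_assignment"
  )
}
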