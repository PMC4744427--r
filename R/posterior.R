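#' Modal number of mixture components
#'
#' The number of components supported by the data is read off the
#' posterior as the most frequent cluster count among the kept
#' iterations (the quantity whose histogram is inspected to call the
#' cluster number). Ties are broken toward the smaller count: with equal
#' posterior support the more parsimonious mixture wins.
#'
#' @param trace a `dpgmm_trace` from [run_gibbs()].
#' @return The modal cluster count, a positive integer.
#' @export
modal_cluster_count <- function(trace) {
  stopifnot(inherits(trace, "dpgmm_trace"))
  if (length(trace$K) == 0L)
    stop("empty trace: nothing was recorded after burn-in", call. = FALSE)
  tab <- table(trace$K)
  ks <- as.integer(names(tab))
  ks[tab == max(tab)][1L]  # names are sorted ascending: tie -> smaller K
}

# map one kept iteration's cluster labels to ranks of ascending mean
.relabel_by_mean <- function(params) {
  ord <- order(params$mu)
  relab <- integer(length(ord))
  relab[ord] <- seq_along(ord)
  relab
}

#' Summarize a Gibbs trace into posterior estimates
#'
#' Conditions on the kept iterations whose cluster count equals the
#' modal count, relabels each such iteration's clusters by ascending
#' cluster mean (the identifiability convention for label switching),
#' and then reports:
#' \itemize{
#'   \item posterior means of each relabeled cluster's mean and variance;
#'   \item equal-tailed Bayesian credible intervals from the empirical
#'     \eqn{\alpha/2} and \eqn{1-\alpha/2} quantiles of the same draws;
#'   \item the modal relabeled assignment \eqn{\hat c_i} of every
#'     observation (ties to the smallest label);
#'   \item mixing proportions \eqn{\hat\pi_k} as the share of
#'     observations modally assigned to cluster \eqn{k}.
#' }
#'
#' @param trace a `dpgmm_trace`.
#' @param level credible level, e.g. `0.95` for 2.5%/97.5% bounds.
#' @return A list of class `dpgmm_summary` with elements `K_mode`,
#'   `pi_hat`, `mu_hat`, `sigma_sq_hat`, `bci_mu`, `bci_sigma_sq`
#'   (matrices with `lower`/`upper` columns), `c_hat`, `level`,
#'   `n_draws` (iterations used).
#' @export
summarize_trace <- function(trace, level = 0.95) {
  stopifnot(inherits(trace, "dpgmm_trace"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("`level` must be in (0, 1)", call. = FALSE)
  K_mode <- modal_cluster_count(trace)
  use <- which(trace$K == K_mode)
  n <- length(trace$y)
  n_use <- length(use)

  mu_draws <- matrix(NA_real_, n_use, K_mode)
  s2_draws <- matrix(NA_real_, n_use, K_mode)
  c_relab <- matrix(NA_integer_, n_use, n)
  for (j in seq_len(n_use)) {
    p <- trace$params[[use[j]]]
    relab <- .relabel_by_mean(p)
    ord <- order(p$mu)
    mu_draws[j, ] <- p$mu[ord]
    s2_draws[j, ] <- p$sigma_sq[ord]
    c_relab[j, ] <- relab[trace$assignments[use[j], ]]
  }

  c_hat <- apply(c_relab, 2L, function(col) {
    tab <- tabulate(col, nbins = K_mode)
    which.max(tab)  # ties to the smallest label
  })
  pi_hat <- tabulate(c_hat, nbins = K_mode) / n

  alpha_sig <- 1 - level
  qs <- c(alpha_sig / 2, 1 - alpha_sig / 2)
  bci <- function(draws) {
    out <- t(apply(draws, 2L, stats::quantile, probs = qs, names = FALSE))
    colnames(out) <- c("lower", "upper")
    out
  }

  structure(list(K_mode = K_mode,
                 pi_hat = pi_hat,
                 mu_hat = colMeans(mu_draws),
                 sigma_sq_hat = colMeans(s2_draws),
                 bci_mu = bci(mu_draws),
                 bci_sigma_sq = bci(s2_draws),
                 c_hat = c_hat,
                 level = level,
                 n_draws = n_use),
            class = "dpgmm_summary")
}

#' @export
print.dpgmm_summary <- function(x, ...) {
  cat("DPGMM posterior summary (", x$n_draws, " draws at modal K = ",
      x$K_mode, ")\n", sep = "")
  pct <- function(p) sprintf("%.2f %%", 100 * p)
  lo <- (1 - x$level) / 2
  tab <- data.frame(
    cluster = seq_len(x$K_mode),
    pi_hat = round(x$pi_hat, 3),
    mu_hat = round(x$mu_hat, 3),
    mu_lo = round(x$bci_mu[, "lower"], 3),
    mu_hi = round(x$bci_mu[, "upper"], 3),
    sigma_sq_hat = round(x$sigma_sq_hat, 3),
    s2_lo = round(x$bci_sigma_sq[, "lower"], 3),
    s2_hi = round(x$bci_sigma_sq[, "upper"], 3)
  )
  names(tab)[c(4, 5, 7, 8)] <-
    paste(rep(c("mu", "s2"), each = 2), c(pct(lo), pct(1 - lo)))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a posterior summary as a machine-readable table
#'
#' One row per cluster with columns `cluster`, `pi_hat`, `mu_hat`,
#' `sigma_sq_hat`, `mu_bci_low`, `mu_bci_high`, `sigma_sq_bci_low`,
#' `sigma_sq_bci_high` (tab-separated).
#'
#' @param summary a `dpgmm_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summary, path) {
  stopifnot(inherits(summary, "dpgmm_summary"))
  tab <- data.frame(cluster = seq_len(summary$K_mode),
                    pi_hat = summary$pi_hat,
                    mu_hat = summary$mu_hat,
                    sigma_sq_hat = summary$sigma_sq_hat,
                    mu_bci_low = summary$bci_mu[, "lower"],
                    mu_bci_high = summary$bci_mu[, "upper"],
                    sigma_sq_bci_low = summary$bci_sigma_sq[, "lower"],
                    sigma_sq_bci_high = summary$bci_sigma_sq[, "upper"])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fitted mixture density
#'
#' Evaluates the posterior point-estimate mixture
#' \eqn{\sum_k \hat\pi_k N(x; \hat\mu_k, \hat\sigma_k^2 + \tau^2)}.
#' With `tau_sq = 0` this is the fitted distribution of true effects,
#' as overlaid on effect histograms; a positive `tau_sq` gives the
#' predictive density of an observation with that squared SE.
#'
#' @param summary a `dpgmm_summary`.
#' @param x numeric vector of evaluation points.
#' @param tau_sq squared SE added to every component variance, `>= 0`.
#' @return Densities at `x`; nonnegative, integrating to one.
#' @export
fitted_density <- function(summary, x, tau_sq = 0) {
  stopifnot(inherits(summary, "dpgmm_summary"), tau_sq >= 0)
  vapply(x, function(xi) {
    sum(summary$pi_hat *
          dnorm(xi, summary$mu_hat, sqrt(summary$sigma_sq_hat + tau_sq)))
  }, numeric(1))
}
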