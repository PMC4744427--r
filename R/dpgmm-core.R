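#' Hyperparameters of the measurement-error DPGMM
#'
#' Collects the Dirichlet process concentration \eqn{\alpha} and the
#' parameters of the conjugate base measure
#' \eqn{G_0 = N(\mu; \mu_0, \sigma_0^2)\, IG(\sigma^2; r_1, r_2)}.
#' The inverse gamma is parameterized by shape \eqn{r_1} and rate
#' \eqn{r_2}, with density proportional to
#' \eqn{(\sigma^2)^{-r_1-1} e^{-r_2/\sigma^2}}.
#'
#' Defaults are the settings used throughout: `alpha = 0.05` (set low
#' because larger concentrations inflate the posterior number of
#' clusters), `r1 = 1`, `r2 = 0.01`, `mu0 = 0`, `sigma0_sq = 0.01`.
#'
#' @param alpha concentration parameter, `> 0`.
#' @param mu0 base-measure prior mean.
#' @param sigma0_sq base-measure prior variance, `> 0`.
#' @param r1 inverse-gamma shape, `> 0`.
#' @param r2 inverse-gamma rate, `> 0`.
#' @return A list of class `dp_hyperparams`.
#' @export
dp_hyperparams <- function(alpha = 0.05, mu0 = 0, sigma0_sq = 0.01,
                           r1 = 1, r2 = 0.01) {
  for (nm in c("alpha", "sigma0_sq", "r1", "r2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single positive number", call. = FALSE)
  }
  stopifnot(is.numeric(mu0), length(mu0) == 1L, is.finite(mu0))
  structure(list(alpha = alpha, mu0 = mu0, sigma0_sq = sigma0_sq,
                 r1 = r1, r2 = r2),
            class = "dp_hyperparams")
}

#' Conditional posterior of a latent true effect
#'
#' Under the model \eqn{y_i \sim N(\theta_i, \sigma_k^2)},
#' \eqn{\theta_i \sim N(\mu_k, \tau_i^2)}, the full conditional of the
#' latent true effect \eqn{\theta_i} is normal with precision-weighted
#' mean and pooled precision:
#' \deqn{\theta_i \mid \cdot \sim N\!\left(
#'   \frac{y_i/\sigma_k^2 + \mu_k/\tau_i^2}{1/\sigma_k^2 + 1/\tau_i^2},
#'   \frac{1}{1/\sigma_k^2 + 1/\tau_i^2}\right).}
#' Note the parameterization: the cluster variance \eqn{\sigma_k^2} acts
#' on the observation and the known SE \eqn{\tau_i^2} on the latent mean,
#' so the marginal of \eqn{y_i} is \eqn{N(\mu_k, \sigma_k^2 + \tau_i^2)}.
#'
#' @param y observed effect.
#' @param tau_sq squared known SE, `> 0`.
#' @param mu_k,sigma_k_sq current cluster mean and variance (`> 0`).
#' @return `list(mean =, variance =)`.
#' @export
theta_conditional <- function(y, tau_sq, mu_k, sigma_k_sq) {
  if (tau_sq <= 0 || sigma_k_sq <= 0)
    stop("`tau_sq` and `sigma_k_sq` must be strictly positive", call. = FALSE)
  prec <- 1 / sigma_k_sq + 1 / tau_sq
  list(mean = (y / sigma_k_sq + mu_k / tau_sq) / prec,
       variance = 1 / prec)
}

#' Unnormalized assignment weight for an occupied cluster
#'
#' The Gibbs weight for assigning observation \eqn{i} to occupied cluster
#' \eqn{k} multiplies the two Gaussian kernels by the Chinese-restaurant
#' prior count:
#' \deqn{\frac{n_{-i,k}}{2\pi\sqrt{\sigma_k^2 \tau_i^2}}
#'   \exp\!\left(-\frac{(y_i-\theta_i)^2}{2\sigma_k^2}
#'               -\frac{(\theta_i-\mu_k)^2}{2\tau_i^2}\right),}
#' where \eqn{n_{-i,k}} counts the cluster's members excluding
#' observation \eqn{i} (the shared constant \eqn{1/(n-1+\alpha)} is
#' dropped; weights are normalized jointly with the new-cluster weight).
#'
#' @param y observed effect.
#' @param theta latent true effect.
#' @param tau_sq squared SE, `> 0`.
#' @param mu_k,sigma_k_sq cluster mean and variance.
#' @param n_minus_ik cluster size excluding observation `i`, `>= 1`
#'   (an emptied cluster must be removed by the caller first).
#' @param log return the log weight.
#' @return The (log) unnormalized weight.
#' @export
existing_cluster_weight <- function(y, theta, tau_sq, mu_k, sigma_k_sq,
                                    n_minus_ik, log = FALSE) {
  if (any(n_minus_ik < 1L))
    stop("`n_minus_ik` must be >= 1: remove emptied clusters before ",
         "computing assignment weights", call. = FALSE)
  if (any(tau_sq <= 0) || any(sigma_k_sq <= 0))
    stop("`tau_sq` and `sigma_k_sq` must be strictly positive", call. = FALSE)
  lw <- base::log(n_minus_ik) - base::log(2 * pi) -
    0.5 * base::log(sigma_k_sq * tau_sq) -
    (y - theta)^2 / (2 * sigma_k_sq) -
    (theta - mu_k)^2 / (2 * tau_sq)
  if (log) lw else exp(lw)
}

#' Unnormalized assignment weight for a new cluster
#'
#' When observation \eqn{i} considers opening cluster \eqn{K+1}, the
#' unknown \eqn{(\mu_{K+1}, \sigma_{K+1}^2)} are integrated out against
#' the conjugate base measure, which is available in closed form:
#' \deqn{\frac{\alpha}{2\pi}\,\frac{r_2^{r_1}}{\Gamma(r_1)}\,
#'   \frac{\Gamma(r_1 + 1/2)}
#'        {\left(\tfrac12 (y_i-\theta_i)^2 + r_2\right)^{r_1+1/2}}
#'   \sqrt{\frac{1}{\tau_i^2+\sigma_0^2}}
#'   \exp\!\left(-\frac{(\theta_i-\mu_0)^2}{2(\tau_i^2+\sigma_0^2)}\right).}
#' The two factors are the scaled-t marginal of \eqn{y_i-\theta_i} under
#' the inverse-gamma variance prior and the Gaussian convolution
#' \eqn{N(\theta_i; \mu_0, \tau_i^2 + \sigma_0^2)}.
#'
#' @param y observed effect.
#' @param theta latent true effect.
#' @param tau_sq squared SE, `> 0`.
#' @param hp a [dp_hyperparams()].
#' @param log return the log weight.
#' @return The (log) unnormalized weight; proportional to `alpha`.
#' @export
new_cluster_weight <- function(y, theta, tau_sq, hp, log = FALSE) {
  if (tau_sq <= 0) stop("`tau_sq` must be strictly positive", call. = FALSE)
  lw <- base::log(hp$alpha) - base::log(2 * pi) +
    hp$r1 * base::log(hp$r2) - lgamma(hp$r1) + lgamma(hp$r1 + 0.5) -
    (hp$r1 + 0.5) * base::log(0.5 * (y - theta)^2 + hp$r2) -
    0.5 * base::log(tau_sq + hp$sigma0_sq) -
    (theta - hp$mu0)^2 / (2 * (tau_sq + hp$sigma0_sq))
  if (log) lw else exp(lw)
}

#' Conditional posterior of a cluster mean
#'
#' Given the latent true effects currently assigned to cluster \eqn{k},
#' the mean \eqn{\mu_k} has the conjugate normal conditional
#' \deqn{\mu_k \mid \cdot \sim N\!\left(
#'   \frac{\sum_i \theta_i/\tau_i^2 + \mu_0/\sigma_0^2}
#'        {\sum_i 1/\tau_i^2 + 1/\sigma_0^2},
#'   \frac{1}{\sum_i 1/\tau_i^2 + 1/\sigma_0^2}\right),}
#' the sums running over the cluster members. An empty cluster returns
#' the prior \eqn{(\mu_0, \sigma_0^2)}.
#'
#' @param thetas latent effects of the cluster members (may be empty).
#' @param taus_sq their squared SEs, same length, all `> 0`.
#' @param hp a [dp_hyperparams()].
#' @return `list(mean =, variance =)`.
#' @export
mu_conditional <- function(thetas, taus_sq, hp) {
  if (length(thetas) != length(taus_sq))
    stop("`thetas` and `taus_sq` must have the same length", call. = FALSE)
  if (any(taus_sq <= 0)) stop("`taus_sq` must be strictly positive", call. = FALSE)
  prec <- sum(1 / taus_sq) + 1 / hp$sigma0_sq
  list(mean = (sum(thetas / taus_sq) + hp$mu0 / hp$sigma0_sq) / prec,
       variance = 1 / prec)
}

#' Conditional posterior of a cluster variance
#'
#' The residuals \eqn{y_i - \theta_i} of the cluster members update the
#' inverse-gamma prior to
#' \deqn{\sigma_k^2 \mid \cdot \sim IG\!\left(r_1 + n_k/2,\;
#'   \tfrac12 \sum_i (y_i - \theta_i)^2 + r_2\right).}
#'
#' @param residuals_sq_sum \eqn{\sum_{i \in k} (y_i - \theta_i)^2}, `>= 0`.
#' @param n_k cluster size, `>= 0`.
#' @param hp a [dp_hyperparams()].
#' @return `list(shape =, rate =)` of the inverse-gamma conditional.
#' @export
sigma_sq_conditional <- function(residuals_sq_sum, n_k, hp) {
  if (residuals_sq_sum < 0)
    stop("`residuals_sq_sum` must be >= 0", call. = FALSE)
  if (n_k < 0) stop("`n_k` must be >= 0", call. = FALSE)
  list(shape = hp$r1 + n_k / 2, rate = residuals_sq_sum / 2 + hp$r2)
}

#' Chinese restaurant process prior probability
#'
#' The exchangeable prior on cluster indicators induced by the Dirichlet
#' process: conditional on the other \eqn{n-1} assignments, observation
#' \eqn{i} joins occupied cluster \eqn{k} with probability
#' \eqn{n_{-i,k}/(n-1+\alpha)} and opens a new cluster with probability
#' \eqn{\alpha/(n-1+\alpha)}. Over any full partition of the other
#' observations these probabilities sum to one exactly.
#'
#' @param n_minus_ik members of the cluster excluding observation `i`
#'   (ignored when `is_new`).
#' @param n total number of observations, `>= 1`.
#' @param alpha concentration parameter, `> 0`.
#' @param is_new probability of opening a new cluster instead.
#' @return A probability in `[0, 1]`.
#' @examples
#' crp_prior_prob(149, n = 150, alpha = 0.05)           # stay with the crowd
#' crp_prior_prob(0, n = 150, alpha = 0.05, is_new = TRUE)
#' @export
crp_prior_prob <- function(n_minus_ik, n, alpha, is_new = FALSE) {
  stopifnot(n >= 1L, alpha > 0)
  if (is_new) return(alpha / (n - 1 + alpha))
  if (any(n_minus_ik > n - 1L))
    stop("`n_minus_ik` cannot exceed n - 1", call. = FALSE)
  if (any(n_minus_ik < 0L)) stop("`n_minus_ik` must be >= 0", call. = FALSE)
  n_minus_ik / (n - 1 + alpha)
}
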