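# Quadrature oracles for the conjugate conditionals, kept independent of
# the closed forms they check: each integrates the unnormalized density
# numerically and reports moments.

# moments of p(theta) ~ N(y; theta, sigma_k_sq) * N(theta; mu_k, tau_sq)
oracle_theta_moments <- function(y, tau_sq, mu_k, sigma_k_sq) {
  f <- function(th) dnorm(y, th, sqrt(sigma_k_sq)) * dnorm(th, mu_k, sqrt(tau_sq))
  # integrate on a window around the dominant factor to keep the
  # adaptive quadrature well-conditioned at tiny tau
  ctr <- (y / sigma_k_sq + mu_k / tau_sq) / (1 / sigma_k_sq + 1 / tau_sq)
  hw <- 12 * sqrt(min(sigma_k_sq, tau_sq))
  z <- integrate(f, ctr - hw, ctr + hw, rel.tol = 1e-10)$value
  m1 <- integrate(function(th) th * f(th), ctr - hw, ctr + hw,
                  rel.tol = 1e-10)$value / z
  m2 <- integrate(function(th) (th - m1)^2 * f(th), ctr - hw, ctr + hw,
                  rel.tol = 1e-10)$value / z
  list(mean = m1, variance = m2)
}

# moments of p(mu) ~ prod_i N(theta_i; mu, tau_i_sq) * N(mu; mu0, sigma0_sq)
oracle_mu_moments <- function(thetas, taus_sq, hp) {
  f <- function(m) {
    vapply(m, function(mm) {
      prod(dnorm(thetas, mm, sqrt(taus_sq))) *
        dnorm(mm, hp$mu0, sqrt(hp$sigma0_sq))
    }, numeric(1))
  }
  prec <- sum(1 / taus_sq) + 1 / hp$sigma0_sq
  ctr <- (sum(thetas / taus_sq) + hp$mu0 / hp$sigma0_sq) / prec
  hw <- 12 / sqrt(prec)
  z <- integrate(f, ctr - hw, ctr + hw, rel.tol = 1e-10)$value
  m1 <- integrate(function(m) m * f(m), ctr - hw, ctr + hw,
                  rel.tol = 1e-10)$value / z
  m2 <- integrate(function(m) (m - m1)^2 * f(m), ctr - hw, ctr + hw,
                  rel.tol = 1e-10)$value / z
  list(mean = m1, variance = m2)
}

# numerical integration of the new-cluster integrand
#   alpha * int int N(y; theta, s2) N(theta; mu, tau_sq)
#                 N(mu; mu0, sigma0_sq) IG(s2; r1, r2) dmu ds2
# done as iterated 1-D integrals (the integrand factorizes over mu and s2)
oracle_new_cluster_weight <- function(y, theta, tau_sq, hp) {
  dinvgamma <- function(s2, shape, rate) {
    exp(shape * log(rate) - lgamma(shape) - (shape + 1) * log(s2) - rate / s2)
  }
  i_sigma <- integrate(function(u) {
    s2 <- exp(u)  # log-scale substitution, Jacobian s2
    dnorm(y, theta, sqrt(s2)) * dinvgamma(s2, hp$r1, hp$r2) * s2
  }, -40, 20, rel.tol = 1e-10)$value
  i_mu <- integrate(function(m) {
    dnorm(theta, m, sqrt(tau_sq)) * dnorm(m, hp$mu0, sqrt(hp$sigma0_sq))
  }, -Inf, Inf, rel.tol = 1e-10)$value
  hp$alpha * i_sigma * i_mu
}
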