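# shared fixtures and small utilities for sampler tests

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# two tight, mean-separated groups with tiny SEs
two_group_data <- function(n_per = 20, centers = c(-5, 5), seed = 1) {
  set.seed(seed)
  value <- c(rnorm(n_per, centers[1], 0.1), rnorm(n_per, centers[2], 0.1))
  se <- runif(2 * n_per, 0, 0.01)
  obs <- effect_table(value, se)
  obs$component <- rep(1:2, each = n_per)
  obs
}

# a dpgmm_state sitting at a given labelled configuration
state_at <- function(obs, labels, mu, sigma_sq) {
  structure(list(assignments = as.integer(labels), thetas = obs$value,
                 mu = mu, sigma_sq = sigma_sq,
                 nk = as.integer(tabulate(labels, length(mu))),
                 K = length(mu)),
            class = "dpgmm_state")
}

expect_valid_state <- function(state, n) {
  expect_s3_class(state, "dpgmm_state")
  expect_length(state$assignments, n)
  expect_identical(sum(state$nk), as.integer(n))
  expect_true(all(state$nk >= 1L))
  expect_identical(sort(unique(state$assignments)), seq_len(state$K))
  expect_length(state$mu, state$K)
  expect_length(state$sigma_sq, state$K)
  expect_true(all(state$sigma_sq > 0))
}
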