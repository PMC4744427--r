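test_that("effect tables parse from TSV and CSV with flexible headers", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("effect\tse\ttrait",
               "0.5\t0.1\tyield",
               "-0.3\t0.05\tyield",
               "1.2\t0.2\theight"), tsv)
  obs <- read_effect_table(tsv)
  expect_s3_class(obs, "effect_table")
  expect_equal(nrow(obs), 3)
  expect_equal(obs$value, c(0.5, -0.3, 1.2))
  expect_equal(obs$se, c(0.1, 0.05, 0.2))
  expect_equal(obs$trait, c("yield", "yield", "height"))

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("VALUE,STDERR", "0.8,0.2"), csv)
  obs2 <- read_effect_table(csv)
  expect_equal(obs2$value, 0.8)
  expect_equal(obs2$se, 0.2)
})

test_that("SEs are reconstructed from a LOD column when se is absent", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("effect\tlod", "0.5\t3", "-0.5\t3"), tsv)
  obs <- read_effect_table(tsv)
  expect_equal(obs$se, rep(0.5 / sqrt(2 * log(10) * 3), 2))
})

test_that("malformed tables are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  file.create(f)
  expect_error(read_effect_table(f), "empty")

  writeLines(c("foo\tbar", "1\t2"), f)
  expect_error(read_effect_table(f), "missing required column")

  writeLines(c("effect\tse", "1\t0.1", "oops\t0.2"), f)
  expect_error(read_effect_table(f), "row\\(s\\) 2")

  writeLines(c("effect\tse", "1\t0.1", "2\t"), f)
  expect_error(read_effect_table(f), "row\\(s\\) 2")

  expect_error(read_effect_table(file.path(tempdir(), "no-such-file.tsv")),
               "not found")
})

test_that("effect tables round-trip through the writer", {
  obs <- effect_table(c(0.5, -0.3), c(0.1, 0.05), trait = "gy")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_effect_table(obs, f)
  back <- read_effect_table(f)
  expect_equal(back$value, obs$value)
  expect_equal(back$se, obs$se)
  expect_equal(back$trait, obs$trait)
})

test_that("phenotypic_sd covers the three information levels", {
  expect_identical(phenotypic_sd("raw_sd", pheno_sd = 1.7), 1.7)
  expect_equal(phenotypic_sd("range", pheno_range = 16), 2.0)
  # h^2 = sigma_g^2 / sigma_P^2 => sigma_P^2 = sigma_e^2 h^2/(1-h^2) + sigma_e^2
  expect_equal(phenotypic_sd("heritability", error_variance = 1,
                             heritability = 0.5),
               sqrt(2), tolerance = 1e-12)
  expect_error(phenotypic_sd("heritability", error_variance = 1,
                             heritability = 1), "below 1")
  expect_error(phenotypic_sd("raw_sd", pheno_sd = -2), "positive")
  expect_error(phenotypic_sd("range", pheno_range = 0), "positive")
})

test_that("scaling divides value and SE and refuses dominance coefficients", {
  obs <- effect_table(c(0.8, -0.4), c(0.2, 0.1))
  sc <- scale_effects(obs, 2)
  expect_equal(sc$value, c(0.4, -0.2))
  expect_equal(sc$se, c(0.1, 0.05))
  expect_equal(scale_effects(obs, 1), obs)
  expect_error(scale_effects(obs, 0), "positive")

  # scaling then unscaling is the identity
  set.seed(1)
  r <- effect_table(rnorm(20), runif(20))
  expect_equal(scale_effects(scale_effects(r, 3.7), 1 / 3.7)$value, r$value,
               tolerance = 1e-12)

  dom <- effect_table(0.5, 0.1, kind = "dominance_coefficient")
  expect_error(scale_effects(dom, 2), "additive")
})

test_that("doubling appends exact sign-negated copies", {
  obs <- effect_table(c(0.5, -0.3), c(0.1, 0.05))
  d <- double_effects(obs)
  expect_equal(nrow(d), 4)
  expect_equal(d$value, c(0.5, -0.3, -0.5, 0.3))
  expect_equal(d$se, c(0.1, 0.05, 0.1, 0.05))
  expect_identical(sum(d$value), 0)  # exact, not approximate

  # multiset closed under negation
  set.seed(2)
  r <- effect_table(rnorm(31), runif(31))
  dr <- double_effects(r)
  expect_equal(nrow(dr), 62)
  expect_equal(sort(dr$value), sort(-dr$value))
  expect_identical(sum(dr$value), 0)

  expect_equal(nrow(double_effects(effect_table(numeric(0), numeric(0)))), 0)
  z <- double_effects(effect_table(0, 0.02))
  expect_equal(z$value, c(0, 0))
  expect_equal(z$se, c(0.02, 0.02))

  dom <- effect_table(0.5, 0.1, kind = "dominance_coefficient")
  expect_error(double_effects(dom), "additive")
})

test_that("dominance coefficients use the delta-method SE", {
  x <- dominance_coefficient(a = 2, d = 1, se_a = 0.2, se_d = 0.1)
  expect_equal(x$value, 0.5)
  expect_equal(x$se, 0.5 * sqrt(0.01 + 0.01), tolerance = 1e-12)
  expect_identical(x$kind, "dominance_coefficient")

  y <- dominance_coefficient(a = 1, d = 1, se_a = 0.1, se_d = 0.1)
  expect_equal(y$value, 1)
  expect_equal(y$se, sqrt(0.02), tolerance = 1e-12)

  # |a| in the denominator: sign of a flips the value, not the SE
  z <- dominance_coefficient(a = -2, d = 1, se_a = 0, se_d = 0)
  expect_equal(z$value, 0.5)
  expect_identical(z$se, 0)

  # SE invariant under joint sign flips; zero iff both inputs zero
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(1); d <- rnorm(1)
    sa <- runif(1); sd_ <- runif(1)
    if (a == 0 || d == 0) next
    base <- dominance_coefficient(a, d, sa, sd_)
    flip <- dominance_coefficient(-a, -d, sa, sd_)
    expect_equal(base$se, flip$se, tolerance = 1e-12)
    expect_gt(base$se, 0)
  }

  # d = 0: value 0, SE from the limit of the delta expansion
  w <- dominance_coefficient(a = 2, d = 0, se_a = 0.2, se_d = 0.1)
  expect_equal(w$value, 0)
  expect_equal(w$se, 0.05)

  expect_error(dominance_coefficient(0, 1, 0.1, 0.1), "nonzero")
})

test_that("LOD-derived SEs follow the chi-square approximation", {
  expect_equal(se_from_lod(1, 1 / (2 * log(10))), 1, tolerance = 1e-12)
  expect_equal(se_from_lod(0.5, 3), 0.5 / sqrt(2 * log(10) * 3),
               tolerance = 1e-12)
  expect_equal(se_from_lod(-0.5, 3), se_from_lod(0.5, 3))
  expect_error(se_from_lod(0.5, 0), "positive")
  expect_error(se_from_lod(0, 3), "nonzero")
})

test_that("replicate SEs are sample SDs with a minimum-environment filter", {
  expect_identical(se_from_replicates(c(1, 1, 1)), 0)
  expect_equal(se_from_replicates(c(0, 2)), sqrt(2), tolerance = 1e-12)
  expect_identical(se_from_replicates(0.5), NA_real_)
  expect_identical(se_from_replicates(c(1, 2, 3), min_env = 4), NA_real_)

  # equals the two-pass brute-force variance computation
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(sample(2:12, 1))
    m <- sum(x) / length(x)
    expect_equal(se_from_replicates(x),
                 sqrt(sum((x - m)^2) / (length(x) - 1)), tolerance = 1e-12)
  }
})
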