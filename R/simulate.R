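#' Specify a (possibly truncated) Gaussian mixture of QTL effects
#'
#' Describes the generating process for synthetic effect data: component
#' means, variances and mixing proportions, the sample size, an optional
#' open truncation window (values strictly inside it are rejected and
#' redrawn from the same component, mimicking the detection threshold of
#' QTL mapping), and the range of the uniform distribution the known
#' standard errors are drawn from.
#'
#' @param means numeric vector of component means.
#' @param variances component variances, `> 0`, same length.
#' @param proportions mixing proportions, summing to 1, same length.
#' @param n number of observations to generate.
#' @param truncation `NULL`, or `c(low, high)` with `low < high`.
#' @param se_range `c(a, b)` with `0 <= a < b`; \eqn{\tau_i \sim U[a, b]}.
#' @return A list of class `mixture_spec`.
#' @export
mixture_spec <- function(means, variances, proportions, n,
                         truncation = NULL, se_range = c(0, 0.01)) {
  if (length(means) != length(variances) ||
      length(means) != length(proportions))
    stop("`means`, `variances`, `proportions` must have equal length",
         call. = FALSE)
  if (any(variances <= 0)) stop("`variances` must be positive", call. = FALSE)
  if (any(proportions <= 0) || abs(sum(proportions) - 1) > 1e-8)
    stop("`proportions` must be positive and sum to 1", call. = FALSE)
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (!is.null(truncation)) {
    if (length(truncation) != 2L || truncation[1] >= truncation[2])
      stop("`truncation` must be c(low, high) with low < high", call. = FALSE)
  }
  if (length(se_range) != 2L || se_range[1] < 0 ||
      se_range[1] >= se_range[2])
    stop("`se_range` must be c(a, b) with 0 <= a < b", call. = FALSE)
  structure(list(means = as.numeric(means),
                 variances = as.numeric(variances),
                 proportions = as.numeric(proportions),
                 n = n, truncation = truncation,
                 se_range = as.numeric(se_range)),
            class = "mixture_spec")
}

#' Validation mixture I: three well-spread components, complete data
#'
#' 150 effects from a three-component mixture with means (-1, 0, 1),
#' variances (0.360, 0.640, 0.040) and equal mixing proportions, SEs
#' uniform on `[0, 0.01]`, no truncation. Represents the case where all
#' true QTL are known; the fitted model should recover three clusters.
#'
#' @return A [mixture_spec()].
#' @export
sim1_spec <- function() {
  mixture_spec(means = c(-1, 0, 1),
               variances = c(0.360, 0.640, 0.040),
               proportions = c(1, 1, 1) / 3,
               n = 150L)
}

#' Validation mixture II: two zero-mean components, truncated near zero
#'
#' 300 effects from a two-component mixture with both means zero,
#' variances (0.023, 0.360) and proportions (0.8, 0.2), truncated on the
#' open window (-0.1, 0.1) to emulate undetected near-zero QTL effects,
#' SEs uniform on `[0, 0.01]`. The fitted model should recover two
#' clusters despite the gap in the histogram.
#'
#' @return A [mixture_spec()].
#' @export
sim2_spec <- function() {
  mixture_spec(means = c(0, 0),
               variances = c(0.023, 0.360),
               proportions = c(0.8, 0.2),
               n = 300L,
               truncation = c(-0.1, 0.1))
}

# deterministic allocation of n draws to components: floor(n * p) each,
# remaining slots to the largest fractional parts (ties to lower index)
.allocate_counts <- function(proportions, n) {
  raw <- n * proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

.max_rejection_draws <- 1e6

#' Draw synthetic QTL effects from a mixture specification
#'
#' Component membership is allocated deterministically by default
#' (`round(n * proportions)`, remainders to the largest fractional
#' parts), which matches an exact uniform split for equal proportions
#' and divisible `n`; `allocation = "multinomial"` samples the counts
#' instead. Values falling strictly inside the truncation window are
#' rejected and redrawn from the same component, so `n` is preserved and
#' each component keeps its truncated shape.
#'
#' @param spec a [mixture_spec()].
#' @param seed optional integer seed; when supplied the output is a pure
#'   function of `(spec, seed)`.
#' @param allocation `"equal"` (deterministic counts) or `"multinomial"`.
#' @return An [effect_table()] with an extra `component` column holding
#'   the true component label of every observation.
#' @examples
#' obs <- simulate_mixture(sim2_spec(), seed = 7)
#' range(abs(obs$value))  # nothing inside (-0.1, 0.1)
#' @export
simulate_mixture <- function(spec, seed = NULL,
                             allocation = c("equal", "multinomial")) {
  stopifnot(inherits(spec, "mixture_spec"))
  allocation <- match.arg(allocation)
  if (!is.null(seed)) set.seed(seed)

  counts <- if (allocation == "equal") {
    .allocate_counts(spec$proportions, spec$n)
  } else {
    as.integer(rmultinom(1, spec$n, spec$proportions))
  }

  comp <- rep(seq_along(counts), counts)
  value <- numeric(spec$n)
  pos <- 1L
  for (k in seq_along(counts)) {
    m <- counts[k]
    if (m == 0L) next
    draws <- rnorm(m, spec$means[k], sqrt(spec$variances[k]))
    if (!is.null(spec$truncation)) {
      lo <- spec$truncation[1]; hi <- spec$truncation[2]
      attempts <- m
      bad <- which(draws > lo & draws < hi)
      while (length(bad) > 0L) {
        attempts <- attempts + length(bad)
        if (attempts > .max_rejection_draws)
          stop("rejection limit reached: the truncation window removes ",
               "essentially all mass of component ", k, call. = FALSE)
        draws[bad] <- rnorm(length(bad), spec$means[k],
                            sqrt(spec$variances[k]))
        bad <- bad[draws[bad] > lo & draws[bad] < hi]
      }
    }
    value[pos:(pos + m - 1L)] <- draws
    pos <- pos + m
  }
  se <- runif(spec$n, spec$se_range[1], spec$se_range[2])

  out <- effect_table(value, se, kind = "additive")
  out$component <- comp
  out
}
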