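#' Construct a table of observed QTL effects
#'
#' The basic data container of the package: one row per observed effect
#' \eqn{y_i} with its known standard error \eqn{\tau_i}. Additive effects
#' are expected in phenotypic-standard-deviation units after
#' [scale_effects()]; dominance coefficients (d/|a|) are unitless by
#' construction.
#'
#' @param value numeric vector of observed effects.
#' @param se numeric vector of standard errors, same length, all `>= 0`.
#' @param trait optional character vector of trait labels.
#' @param kind `"additive"` or `"dominance_coefficient"` (recycled).
#' @return A `data.frame` of class `effect_table` with columns `value`,
#'   `se`, `trait`, `kind`.
#' @examples
#' effect_table(c(0.5, -0.3), c(0.1, 0.05))
#' @export
effect_table <- function(value, se, trait = NA_character_,
                         kind = c("additive", "dominance_coefficient")) {
  kind <- match.arg(kind)
  value <- as.numeric(value)
  se <- as.numeric(se)
  if (length(se) != length(value))
    stop("`value` and `se` must have the same length", call. = FALSE)
  if (any(!is.finite(value)))
    stop("all effect values must be finite", call. = FALSE)
  if (any(!is.finite(se)) || any(se < 0))
    stop("all standard errors must be finite and >= 0", call. = FALSE)
  out <- data.frame(
    value = value,
    se = se,
    trait = rep_len(as.character(trait), length(value)),
    kind = rep_len(kind, length(value)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("effect_table", "data.frame")
  out
}

# keep the subclass through [.data.frame
#' @export
`[.effect_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- c("effect_table", "data.frame")
  out
}

.assert_additive <- function(obs, what) {
  if (any(obs$kind != "additive"))
    stop(what, " applies to additive effects only; dominance coefficients ",
         "are already unitless and must not be transformed this way",
         call. = FALSE)
}

#' Read a delimited table of QTL effects
#'
#' Accepts comma- or tab-separated files with a header row. Column names
#' are matched case-insensitively: the effect column may be named
#' `effect`, `value` or `a`; the standard-error column `se` or `stderr`.
#' If no SE column is present but a `lod` column is, standard errors are
#' reconstructed with [se_from_lod()]. An optional `trait` column is
#' carried through.
#'
#' @param path path to the file.
#' @param kind effect kind recorded for every row.
#' @return An [effect_table()].
#' @export
read_effect_table <- function(path, kind = c("additive", "dominance_coefficient")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(trimws(first)))
    stop("empty effect table: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  if (nrow(raw) == 0L) stop("effect table has a header but no rows: ", path,
                            call. = FALSE)
  nm <- tolower(names(raw))
  pick <- function(cands) {
    hit <- which(nm %in% cands)
    if (length(hit)) hit[1L] else NA_integer_
  }
  i_val <- pick(c("effect", "value", "a"))
  if (is.na(i_val))
    stop("missing required column: one of 'effect', 'value', 'a'", call. = FALSE)
  i_se <- pick(c("se", "stderr"))
  i_lod <- pick("lod")
  i_trait <- pick("trait")
  if (is.na(i_se) && is.na(i_lod))
    stop("missing required column: 'se' (or 'lod' to derive it)", call. = FALSE)

  num <- function(col, label) {
    x <- trimws(raw[[col]])
    miss <- !nzchar(x) | toupper(x) %in% c("NA", "NAN")
    if (any(miss))
      stop("missing ", label, " in row(s) ", paste(which(miss), collapse = ", "),
           call. = FALSE)
    y <- suppressWarnings(as.numeric(x))
    if (any(is.na(y)))
      stop("non-numeric ", label, " in row(s) ",
           paste(which(is.na(y)), collapse = ", "), call. = FALSE)
    y
  }
  value <- num(i_val, paste0("'", names(raw)[i_val], "'"))
  if (!is.na(i_se)) {
    se <- num(i_se, paste0("'", names(raw)[i_se], "'"))
  } else {
    lod <- num(i_lod, "'lod'")
    se <- se_from_lod(value, lod)
  }
  trait <- if (!is.na(i_trait)) raw[[i_trait]] else NA_character_
  effect_table(value, se, trait, kind)
}

#' Write an effect table
#'
#' Emits the standard tab-separated layout (`effect`, `se`, `trait`,
#' `kind`) read back by [read_effect_table()].
#'
#' @param obs an [effect_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(obs, path) {
  out <- data.frame(effect = obs$value, se = obs$se,
                    trait = obs$trait, kind = obs$kind)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Phenotypic standard deviation from study-level information
#'
#' QTL effects from different studies are made comparable by expressing
#' them in units of the trait's phenotypic standard deviation. When the
#' raw SD is not reported, two fallbacks are used, in order of preference:
#' the error variance and heritability of the trait, via
#' \eqn{\sigma_P = \sqrt{\sigma_e^2 / (1 - h^2)}} (since
#' \eqn{h^2 = \sigma_g^2/\sigma_P^2} implies
#' \eqn{\sigma_P^2 = \sigma_e^2 + \sigma_e^2 h^2/(1-h^2)}), or the
#' phenotypic range divided by 8, the range of a normal trait being taken
#' to span about eight standard deviations.
#'
#' @param mode `"raw_sd"`, `"heritability"` or `"range"`.
#' @param pheno_sd reported phenotypic SD (mode `"raw_sd"`).
#' @param error_variance residual error variance (mode `"heritability"`).
#' @param heritability narrow-sense \eqn{h^2} in `(0, 1)` (mode
#'   `"heritability"`).
#' @param pheno_range range of observed phenotype values (mode `"range"`).
#' @return The phenotypic standard deviation, a positive scalar.
#' @examples
#' phenotypic_sd("range", pheno_range = 16) # 2
#' phenotypic_sd("heritability", error_variance = 1, heritability = 0.5)
#' @export
phenotypic_sd <- function(mode = c("raw_sd", "heritability", "range"),
                          pheno_sd = NULL, error_variance = NULL,
                          heritability = NULL, pheno_range = NULL) {
  mode <- match.arg(mode)
  pos <- function(x, label) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("`", label, "` must be a single positive number for mode '", mode,
           "'", call. = FALSE)
    x
  }
  switch(mode,
    raw_sd = pos(pheno_sd, "pheno_sd"),
    heritability = {
      ev <- pos(error_variance, "error_variance")
      h2 <- pos(heritability, "heritability")
      if (h2 >= 1)
        stop("`heritability` must be strictly below 1 (h^2 = 1 leaves no ",
             "error variance to anchor the phenotypic SD)", call. = FALSE)
      sqrt(ev * h2 / (1 - h2) + ev)
    },
    range = pos(pheno_range, "pheno_range") / 8
  )
}

#' Scale additive effects to phenotypic-standard-deviation units
#'
#' Divides both the effect and its SE by the phenotypic standard
#' deviation. Dominance coefficients are rejected: the phenotypic SD
#' cancels in the d/a ratio, so they need no scaling.
#'
#' @param obs an [effect_table()] of additive effects.
#' @param sd positive scalar, or a vector with one SD per row.
#' @return The scaled [effect_table()].
#' @export
scale_effects <- function(obs, sd) {
  .assert_additive(obs, "scale_effects()")
  if (!is.numeric(sd) || any(!is.finite(sd)) || any(sd <= 0))
    stop("`sd` must be positive and finite", call. = FALSE)
  if (!length(sd) %in% c(1L, nrow(obs)))
    stop("`sd` must be a scalar or one value per row", call. = FALSE)
  obs$value <- obs$value / sd
  obs$se <- obs$se / sd
  obs
}

#' Double additive effects with their sign-negated copies
#'
#' QTL mapping lacks power near zero, so the observed distribution of
#' additive effects is effectively truncated around the origin, and the
#' sign of an effect only records which parent carried the favourable
#' allele. Doubling appends `-y` with the same SE for every observed `y`,
#' forcing every mixture component mean to zero and restoring the
#' symmetry that the detection threshold destroyed. Not applied to
#' dominance coefficients, whose observed values already concentrate
#' around zero.
#'
#' @param obs an [effect_table()] of additive effects.
#' @return An [effect_table()] with `2 * nrow(obs)` rows whose values sum
#'   to exactly zero.
#' @export
double_effects <- function(obs) {
  .assert_additive(obs, "double_effects()")
  if (nrow(obs) == 0L) return(obs)
  neg <- obs
  neg$value <- -neg$value
  out <- rbind(obs, neg)
  class(out) <- c("effect_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' Dominance coefficient with delta-method standard error
#'
#' The dominance coefficient is the ratio of the dominance deviation `d`
#' to the absolute additive effect, `d / |a|` (the sign of `a` only
#' records the parental origin of the favourable allele). Its standard
#' error comes from the first-order delta method assuming no covariance
#' between `a` and `d`:
#' \deqn{SE_{d/a} = |d/a| \sqrt{(SE_a/a)^2 + (SE_d/d)^2}.}
#' At `d = 0` the ratio-of-relative-errors form is undefined; the limit
#' of the delta expansion gives `se_d / |a|`, which is used instead.
#'
#' @param a additive effect, nonzero.
#' @param d dominance deviation.
#' @param se_a,se_d standard errors of `a` and `d`, both `>= 0`.
#' @param trait optional trait label.
#' @return A one-row [effect_table()] with `kind = "dominance_coefficient"`.
#' @examples
#' dominance_coefficient(a = 2, d = 1, se_a = 0.2, se_d = 0.1)
#' @export
dominance_coefficient <- function(a, d, se_a, se_d, trait = NA_character_) {
  stopifnot(length(a) == 1L, length(d) == 1L)
  if (!is.finite(a) || a == 0)
    stop("`a` must be nonzero: the dominance coefficient d/|a| is undefined ",
         "for a zero additive effect", call. = FALSE)
  if (se_a < 0 || se_d < 0) stop("standard errors must be >= 0", call. = FALSE)
  value <- d / abs(a)
  se <- if (d == 0) se_d / abs(a)
        else abs(d / a) * sqrt((se_a / a)^2 + (se_d / d)^2)
  effect_table(value, se, trait, "dominance_coefficient")
}

#' Standard error of an effect from its LOD score
#'
#' When a study reports only the LOD score of a QTL, an approximate SE is
#' back-derived by treating `2 ln(10) * LOD` as the chi-square statistic
#' `(effect / SE)^2` of the effect, giving
#' `SE = |effect| / sqrt(2 ln(10) * LOD)`. This is an approximation: it
#' assumes the LOD reflects a single-parameter Wald-type test of the
#' effect.
#'
#' @param effect observed effect(s), nonzero.
#' @param lod LOD score(s), strictly positive.
#' @return Standard error(s), same length as `effect`.
#' @examples
#' se_from_lod(0.5, 3)
#' @export
se_from_lod <- function(effect, lod) {
  if (any(!is.finite(lod)) || any(lod <= 0))
    stop("`lod` must be strictly positive", call. = FALSE)
  if (any(effect == 0))
    stop("`effect` must be nonzero to derive an SE from a LOD score",
         call. = FALSE)
  abs(effect) / sqrt(2 * log(10) * lod)
}

#' Standard error from replicate effect estimates
#'
#' For QTL detected in several environments or experiments, the SE is the
#' sample standard deviation (n - 1 denominator) of the replicate
#' estimates. QTL seen in fewer than `min_env` environments carry no
#' usable replicate information and are excluded: the function returns
#' `NA_real_` as the exclusion signal rather than raising an error.
#'
#' @param values replicate effect estimates for one QTL.
#' @param min_env minimum number of environments (default 2, the
#'   inclusion filter used in the meta-analysis).
#' @return The sample SD, or `NA_real_` when the record is excluded.
#' @examples
#' se_from_replicates(c(0, 2))   # sqrt(2)
#' se_from_replicates(0.5)       # NA: detected in one environment only
#' @export
se_from_replicates <- function(values, min_env = 2L) {
  if (min_env < 2L) stop("`min_env` must be at least 2", call. = FALSE)
  if (length(values) < min_env) return(NA_real_)
  stats::sd(values)
}
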