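#' Write a Gibbs trace to disk
#'
#' The trace is stored as two files: `<path>` is a tab-separated table
#' with one row per kept iteration (columns `iteration`, `K`, `nll`),
#' convenient for convergence plots, and `<path>.json` is a sidecar with
#' everything needed to re-summarize the run: the per-iteration cluster
#' parameters, the assignment matrix, the data (`y`, `tau_sq`) and the
#' run configuration (seed, schedule, hyperparameters).
#'
#' @param trace a `dpgmm_trace` from [run_gibbs()].
#' @param path output path for the columnar table; the sidecar gets a
#'   `.json` suffix appended.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "dpgmm_trace"))
  tab <- data.frame(iteration = seq_along(trace$K), K = trace$K,
                    nll = trace$nll)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- trace$config
  side <- list(
    y = trace$y,
    tau_sq = trace$tau_sq,
    assignments = trace$assignments,
    params = trace$params,
    config = list(iterations = cfg$iterations, burn_in = cfg$burn_in,
                  thin = cfg$thin, seed = cfg$seed,
                  hyperparams = unclass(cfg$hyperparams))
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a Gibbs trace written by [write_trace()]
#'
#' @param path path given to [write_trace()] (the `.json` sidecar must
#'   sit next to it).
#' @return A `dpgmm_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("trace sidecar not found: ", sidecar, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (nrow(tab) == 0L) stop("empty trace table: ", path, call. = FALSE)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  cfg <- side$config
  config <- mcmc_config(iterations = cfg$iterations, burn_in = cfg$burn_in,
                        thin = cfg$thin, seed = cfg$seed,
                        hyperparams = do.call(dp_hyperparams,
                                              as.list(cfg$hyperparams)))
  params <- lapply(seq_len(nrow(tab)), function(j) {
    p <- side$params[[j]]
    list(mu = as.numeric(p$mu), sigma_sq = as.numeric(p$sigma_sq),
         size = as.integer(p$size))
  })
  structure(list(K = as.integer(tab$K), nll = as.numeric(tab$nll),
                 assignments = matrix(as.integer(side$assignments),
                                      nrow = nrow(tab)),
                 params = params,
                 y = as.numeric(side$y), tau_sq = as.numeric(side$tau_sq),
                 config = config),
            class = "dpgmm_trace")
}
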