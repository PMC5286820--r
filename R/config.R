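#' @include io.R
NULL

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis: significance
#' cutoffs (|log2FC| > `fc_cut`, p < `p_cut`, q < `q_cut`, all strict),
#' the inherent-filter span, the wave-counting parameters, whether the
#' moderated t is used, and the seed that drives all randomness.
#'
#' @param fc_cut log2 fold-change cutoff (default 1).
#' @param p_cut,q_cut p-value and FDR cutoffs (default 0.05).
#' @param inherent_span log2FC span of the inherent-difference filter
#'   (default 1).
#' @param wave_window_frac,wave_amplitude_mm wave-counter parameters, see
#'   [waveConfig()].
#' @param moderated use the moderated t (default TRUE).
#' @param seed integer seed for simulation subcommands.
#' @return a list of class `runConfig`.
#' @export
runConfig <- function(fc_cut = 1.0, p_cut = 0.05, q_cut = 0.05,
                      inherent_span = 1.0, wave_window_frac = 0.05,
                      wave_amplitude_mm = 0.1, moderated = TRUE, seed = 1L) {
  vals <- list(fc_cut = fc_cut, p_cut = p_cut, q_cut = q_cut,
               inherent_span = inherent_span,
               wave_window_frac = wave_window_frac,
               wave_amplitude_mm = wave_amplitude_mm,
               moderated = isTRUE(moderated), seed = as.integer(seed))
  num <- c("fc_cut", "p_cut", "q_cut", "inherent_span", "wave_window_frac",
           "wave_amplitude_mm")
  for (k in num) if (!is.numeric(vals[[k]]) || vals[[k]] <= 0)
    stop("config value '", k, "' must be positive")
  structure(vals, class = "runConfig")
}

#' Read / write a run configuration
#'
#' Plain YAML key-value files; unknown keys are rejected, missing keys
#' take their defaults, so `writeRunConfig()` then `readRunConfig()`
#' round-trips exactly.
#'
#' @param path file path.
#' @return a [runConfig()].
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(runConfig()))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(runConfig, vals)
}

#' @rdname readRunConfig
#' @param cfg a [runConfig()].
#' @export
writeRunConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "runConfig"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
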