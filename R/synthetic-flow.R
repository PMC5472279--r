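# Seeded generator for DNA-content flow-cytometry event mixtures.

FLOW_POPULATIONS <- c("ES", "RS", "2C", "4C")

#' Generate synthetic DNA-stain flow-cytometry events
#'
#' Draws per-event intensities from a 4-population log-normal mixture
#' emulating DNA-content profiles of dissociated testis: elongated
#' spermatids (ES, condensed chromatin, dimmest), round spermatids
#' (RS, 1C), spermatogonia (2C) and primary spermatocytes (4C). Each
#' population's arithmetic mean equals the requested mean and its
#' coefficient of variation equals `cv`. The true label is stored per
#' event.
#'
#' @param n_events number of events.
#' @param fractions length-4 non-negative vector summing to 1
#'   (ES, RS, 2C, 4C).
#' @param mean_intensities length-4 strictly increasing positive vector.
#' @param cv positive coefficient of variation of each population.
#' @param seed integer seed.
#' @return data.frame with columns `intensity`, `true_label` (factor with
#'   levels ES, RS, 2C, 4C) and `source`.
#' @export
gen_flow_events <- function(n_events, fractions = c(0.3, 0.4, 0.2, 0.1),
                            mean_intensities = c(0.45, 1, 2, 4),
                            cv = 0.05, seed = 1L) {
  stopifnot(n_events >= 1, length(fractions) == 4,
            length(mean_intensities) == 4, cv > 0)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be non-negative and sum to 1")
  if (is.unsorted(mean_intensities, strictly = TRUE) ||
      any(mean_intensities <= 0))
    stop("mean intensities must be strictly increasing and positive")
  local_seed(seed)
  lab <- sample(factor(FLOW_POPULATIONS, levels = FLOW_POPULATIONS),
                n_events, replace = TRUE, prob = fractions)
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean_intensities) - sdlog^2 / 2
  intensity <- stats::rlnorm(n_events, meanlog[as.integer(lab)], sdlog)
  data.frame(intensity = intensity, true_label = lab, source = "synthetic")
}
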