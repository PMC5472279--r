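# Seeded generators for the binding-assay curves. All three models share
# their closed-form evaluation with the fitting code, so noise-free
# generation is exact by construction.

#' Ground truth for a synthetic assay curve
#'
#' @param model_name one of `"4PL"`, `"boltzmann"`, `"wiseman_one_site"`.
#' @param true_params named list of model parameters: for `4PL` `top`,
#'   `bottom`, `logIC50`, `hill` (nonzero); for `boltzmann` `f_min`,
#'   `f_max`, `tm_c`, `slope_a` (> 0); for `wiseman_one_site` `n_sites`,
#'   `K_A` (> 0), `delta_H` (kJ/mol), `cell_conc` (M).
#' @param noise_sd non-negative noise standard deviation.
#' @param noise_type `"additive"` (y + N(0, sd)) or `"multiplicative"`
#'   (y * (1 + N(0, sd))).
#' @param seed integer seed.
#' @return Object of class `curve_ground_truth`.
#' @export
curve_ground_truth <- function(model_name, true_params, noise_sd = 0,
                               noise_type = c("additive", "multiplicative"),
                               seed = 1L) {
  noise_type <- match.arg(noise_type)
  if (!model_name %in% c("4PL", "boltzmann", "wiseman_one_site"))
    stop("unknown model_name: ", model_name)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  req <- switch(model_name,
    "4PL" = c("top", "bottom", "logIC50", "hill"),
    "boltzmann" = c("f_min", "f_max", "tm_c", "slope_a"),
    "wiseman_one_site" = c("n_sites", "K_A", "delta_H", "cell_conc"))
  missing <- setdiff(req, names(true_params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  p <- true_params
  if (model_name == "4PL" && p$hill == 0) stop("hill must be nonzero")
  if (model_name == "boltzmann" && p$slope_a <= 0) stop("slope_a must be > 0")
  if (model_name == "wiseman_one_site" && (p$K_A <= 0 || p$cell_conc <= 0))
    stop("K_A and cell_conc must be positive")
  structure(list(model_name = model_name, true_params = p,
                 noise_sd = noise_sd, noise_type = noise_type, seed = seed),
            class = "curve_ground_truth")
}

#' Evaluate or sample a synthetic assay curve
#'
#' Evaluates the ground-truth model on `x_values` and adds seeded noise;
#' with `noise_sd = 0` the returned `y` equal the closed-form model values
#' to machine precision.
#'
#' @param gt a [curve_ground_truth].
#' @param x_values abscissa: log10 molar concentration (`4PL`),
#'   temperature in Celsius, increasing (`boltzmann`), or molar ratio
#'   (`wiseman_one_site`).
#' @return data.frame with columns `x` and `y`.
#' @export
gen_curve <- function(gt, x_values) {
  stopifnot(inherits(gt, "curve_ground_truth"))
  p <- gt$true_params
  if (gt$model_name == "boltzmann" && is.unsorted(x_values, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  y <- switch(gt$model_name,
    "4PL" = fourpl(x_values, p$top, p$bottom, p$logIC50, p$hill),
    "boltzmann" = boltzmann_sigmoid(x_values, p$f_min, p$f_max, p$tm_c,
                                    p$slope_a),
    "wiseman_one_site" = wiseman_ndh(x_values, p$n_sites, p$K_A, p$delta_H,
                                     p$cell_conc))
  if (gt$noise_sd > 0) {
    local_seed(gt$seed)
    eps <- stats::rnorm(length(y), 0, gt$noise_sd)
    y <- if (gt$noise_type == "additive") y + eps else y * (1 + eps)
  }
  data.frame(x = x_values, y = y)
}
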