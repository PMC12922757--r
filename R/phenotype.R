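#' Phenotype parameters for the synthetic cohort generator
#'
#' Ground-truth parameters of one simulated cell population. Cells perform a
#' biased persistent random walk toward the chemoattractant (+x); on reaching
#' the constriction they dwell a geometric number of frames, squeeze through,
#' and continue with post-constriction modifiers applied.
#'
#' `post_directionality_factor` is defined on the *observable*: it is the
#' target ratio of post- to pre-constriction median directionality
#' (confinement ratio) of the cohort. The generator realizes it by
#' recalibrating the post-segment heading noise (see
#' [simulate_cohort()]), since directionality is a nonlinear emergent of
#' persistence, bias and noise.
#'
#' @param label population name (e.g. "control", "knockout")
#' @param base_speed instantaneous speed, um/min
#' @param persistence heading persistence weight, 0-1
#' @param gradient_bias weight of the +x chemotactic pull, >= 0
#' @param noise_sigma heading noise SD, radians
#' @param post_speed_factor multiplier on speed after constriction exit
#' @param post_directionality_factor target post/pre median-directionality ratio
#' @param spike_prob probability of a post-constriction calcium spike
#' @param polarity_loss_prob probability the cell depolarizes (eccentricity
#'   drops) after exit
#' @param keratocyte_prob probability a non-depolarized cell adopts
#'   keratocyte-like morphology after exit
#' @param dwell_mean_frames mean frames paused at the constriction
#' @param vesicle_median_pre,vesicle_median_post target medians for the
#'   per-cell nuclear-envelope vesicle counts before/after constriction
#' @param pass_prob probability a cell that reaches the constriction passes
#'   (cells that fail remain arrested at the pillar)
#' @param step_cv coefficient of variation of the log-normal step jitter
#' @return object of class `cta_phenotype`
#' @export
phenotype_params <- function(label = "control", base_speed = 12,
                             persistence = 0.6, gradient_bias = 0.35,
                             noise_sigma = 0.9, post_speed_factor = 1,
                             post_directionality_factor = 1,
                             spike_prob = 0.5, polarity_loss_prob = 0.5,
                             keratocyte_prob = 0.5, dwell_mean_frames = 4,
                             vesicle_median_pre = 4, vesicle_median_post = 7,
                             pass_prob = 1, step_cv = 0.3) {
  ph <- list(label = label, base_speed = base_speed, persistence = persistence,
             gradient_bias = gradient_bias, noise_sigma = noise_sigma,
             post_speed_factor = post_speed_factor,
             post_directionality_factor = post_directionality_factor,
             spike_prob = spike_prob, polarity_loss_prob = polarity_loss_prob,
             keratocyte_prob = keratocyte_prob,
             dwell_mean_frames = dwell_mean_frames,
             vesicle_median_pre = vesicle_median_pre,
             vesicle_median_post = vesicle_median_post,
             pass_prob = pass_prob, step_cv = step_cv)
  probs <- c(persistence = persistence, spike_prob = spike_prob,
             polarity_loss_prob = polarity_loss_prob,
             keratocyte_prob = keratocyte_prob, pass_prob = pass_prob)
  if (any(probs < 0 | probs > 1))
    cta_stop("persistence and all probabilities must lie in [0, 1]")
  if (base_speed <= 0) cta_stop("base_speed must be > 0")
  if (gradient_bias < 0) cta_stop("gradient_bias must be >= 0")
  if (noise_sigma < 0) cta_stop("noise_sigma must be >= 0")
  if (post_speed_factor <= 0 || post_directionality_factor <= 0)
    cta_stop("post-constriction multipliers must be > 0")
  if (dwell_mean_frames < 1) cta_stop("dwell_mean_frames must be >= 1")
  structure(ph, class = "cta_phenotype")
}

#' Shipped phenotype presets
#'
#' Three presets mirroring the qualitative constriction-response contrasts of
#' the assayed populations: `control` (speed maintained, modest directionality
#' gain, ~50% post-constriction calcium spikes), `knockout` (reduced
#' post-constriction speed and directionality, no spikes, fewer keratocyte
#' transitions, but vesicle budding intact), and `overexpresser` (strong
#' post-constriction directionality gain and keratocyte transition).
#'
#' @param which one of "control", "knockout", "overexpresser"
#' @return a `cta_phenotype`
#' @export
phenotype_presets <- function(which = c("control", "knockout", "overexpresser")) {
  which <- match.arg(which)
  switch(which,
    control = phenotype_params("control",
      post_speed_factor = 1.0, post_directionality_factor = 1.1,
      spike_prob = 0.5, polarity_loss_prob = 0.5, keratocyte_prob = 0.5),
    knockout = phenotype_params("knockout",
      post_speed_factor = 0.6, post_directionality_factor = 0.7,
      spike_prob = 0, polarity_loss_prob = 0.2, keratocyte_prob = 0.25),
    overexpresser = phenotype_params("overexpresser",
      post_speed_factor = 1.0, post_directionality_factor = 1.3,
      spike_prob = 0.6, polarity_loss_prob = 0.3, keratocyte_prob = 0.7))
}

#' @export
print.cta_phenotype <- function(x, ...) {
  cat(sprintf("phenotype '%s': speed %g um/min, persistence %g, bias %g, noise %g rad\n",
              x$label, x$base_speed, x$persistence, x$gradient_bias, x$noise_sigma))
  cat(sprintf("  post: speed x%g, directionality x%g; spikes %g; keratocyte %g\n",
              x$post_speed_factor, x$post_directionality_factor,
              x$spike_prob, x$keratocyte_prob))
  invisible(x)
}
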