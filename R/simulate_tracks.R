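# Seeded simulator of per-well tracking exports with group-structured
# locomotor activity and multiplicative phase/treatment effects.

#' Configure a synthetic tracking experiment
#'
#' Describes group-structured larval locomotor activity over a lighting
#' protocol. Expected per-bin distance is
#' `baseline_distance_mm_per_bin x group multipliers x phase multiplier`,
#' with lognormal multiplicative noise of coefficient of variation
#' `noise_cv` (distances are positive and right-skewed). Movement duration
#' per bin is `baseline_movement_s_per_bin`, scaled for treated groups by
#' `ptz_distance_factor / ptz_speed_factor` so that both the distance and
#' the speed fold changes of the treatment are realized.
#'
#' @param n_per_group animals per group.
#' @param groups group labels (e.g. `c("RC", "tbMO")`).
#' @param protocol a [protocol_spec()]; bins are one integration period long.
#' @param baseline_distance_mm_per_bin expected control distance per dark
#'   bin, in mm.
#' @param baseline_movement_s_per_bin expected movement duration per bin, in
#'   seconds (must stay below the integration period).
#' @param hypoactivity_factor distance multiplier for `hypo_groups`
#'   (e.g. 0.5 halves distance, and with unchanged movement duration also
#'   halves speed).
#' @param hypo_groups labels receiving the hypoactivity factor.
#' @param light_factor distance multiplier applied in light phases (larvae
#'   move less under light).
#' @param ptz_speed_factor,ptz_distance_factor treatment multipliers on swim
#'   speed and distance for `ptz_groups`.
#' @param ptz_groups labels of treated groups.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 disables noise).
#' @param n_replicates biological replicates; animals are assigned
#'   round-robin (enables replicate-level analysis).
#' @param seed integer seed.
#' @return a `track_sim_config` object.
#' @export
track_sim_config <- function(n_per_group = 12L,
                             groups = c("RC", "tbMO"),
                             protocol = protocol_spec(),
                             baseline_distance_mm_per_bin = 300,
                             baseline_movement_s_per_bin = 60,
                             hypoactivity_factor = 0.5,
                             hypo_groups = "tbMO",
                             light_factor = 0.6,
                             ptz_speed_factor = 1,
                             ptz_distance_factor = 1,
                             ptz_groups = character(),
                             noise_cv = 0.2,
                             n_replicates = 3L,
                             seed = 1L) {
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  mult <- c(baseline_distance_mm_per_bin, baseline_movement_s_per_bin,
            hypoactivity_factor, light_factor, ptz_speed_factor,
            ptz_distance_factor)
  if (any(mult <= 0)) stop("baselines and multipliers must be > 0")
  if (!all(hypo_groups %in% groups) || !all(ptz_groups %in% groups))
    stop("hypo_groups and ptz_groups must be a subset of groups")
  stopifnot(inherits(protocol, "protocol_spec"))
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 protocol = protocol,
                 baseline_distance_mm_per_bin = baseline_distance_mm_per_bin,
                 baseline_movement_s_per_bin = baseline_movement_s_per_bin,
                 hypoactivity_factor = hypoactivity_factor,
                 hypo_groups = hypo_groups, light_factor = light_factor,
                 ptz_speed_factor = ptz_speed_factor,
                 ptz_distance_factor = ptz_distance_factor,
                 ptz_groups = ptz_groups, noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "track_sim_config")
}

# Mean-one lognormal multiplier with the given coefficient of variation.
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Simulate a tracking export
#'
#' One row per animal per integration bin with `smldist`/`lardist` (mm) and
#' `smldur`/`lardur` (s) split 30/70 and 40/60 of the per-bin totals.
#' Movement durations are clamped to the bin length. Same seed, same bytes.
#'
#' @param config a [track_sim_config()].
#' @return list of class `track_sim`: `bins` (data frame with
#'   `TRACKING_COLUMNS` plus `replicate`), `truth` (per-group expected
#'   multipliers), `protocol`, `config`.
#' @examples
#' sim <- simulate_tracks(track_sim_config(n_per_group = 4, seed = 3))
#' head(sim$bins)
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "track_sim_config"))
  set.seed(config$seed)
  proto <- config$protocol
  bin_s <- proto$integration_s
  phase_bins <- rep(seq_len(nrow(proto$phases)),
                    proto$phases$duration_s / bin_s)
  bin_start <- (seq_along(phase_bins) - 1L) * bin_s
  lighting <- proto$phases$lighting[phase_bins]
  n_bins <- length(phase_bins)

  rows <- list()
  for (g in config$groups) {
    hypo <- if (g %in% config$hypo_groups) config$hypoactivity_factor else 1
    ptz_d <- if (g %in% config$ptz_groups) config$ptz_distance_factor else 1
    ptz_s <- if (g %in% config$ptz_groups) config$ptz_speed_factor else 1
    mu_dur <- config$baseline_movement_s_per_bin * (ptz_d / ptz_s)
    for (i in seq_len(config$n_per_group)) {
      phase_mult <- ifelse(lighting == "light", config$light_factor, 1)
      dist <- config$baseline_distance_mm_per_bin * hypo * ptz_d *
        phase_mult * lognoise(n_bins, config$noise_cv)
      dur <- pmin(mu_dur * lognoise(n_bins, config$noise_cv), bin_s)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = sprintf("%s_%02d", g, i), group = g,
        replicate = ((i - 1L) %% config$n_replicates) + 1L,
        bin_start_s = bin_start, bin_end_s = bin_start + bin_s,
        lighting = lighting,
        smldist = 0.3 * dist, lardist = 0.7 * dist,
        smldur = 0.4 * dur, lardur = 0.6 * dur,
        stringsAsFactors = FALSE)
    }
  }
  bins <- do.call(rbind, rows)
  rownames(bins) <- NULL

  truth <- data.frame(
    group = config$groups,
    distance_multiplier = vapply(config$groups, function(g)
      (if (g %in% config$hypo_groups) config$hypoactivity_factor else 1) *
        (if (g %in% config$ptz_groups) config$ptz_distance_factor else 1),
      numeric(1)),
    speed_multiplier = vapply(config$groups, function(g)
      (if (g %in% config$hypo_groups) config$hypoactivity_factor else 1) *
        (if (g %in% config$ptz_groups) config$ptz_speed_factor else 1),
      numeric(1)),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  structure(list(bins = bins, truth = truth, protocol = proto,
                 config = config),
            class = "track_sim")
}
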