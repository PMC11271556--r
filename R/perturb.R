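#' Configuration of the simulated-operator perturbation model
#'
#' Manual post-processing of a dynamic study (axis orientation, valve-plane
#' placement, residual motion correction, handling of extracardiac activity)
#' varies between operators. This model maps each correction to a TAC-level
#' perturbation of the myocardial segments:
#'
#' * valve plane: the basal ring is mixed with the blood pool (a valve plane
#'   set too low samples cavity activity into basal segments);
#' * axis orientation: each segment is mixed circumferentially with its
#'   neighbour within the ring, in a drawn rotation direction;
#' * residual motion: a single signed blood-spillover offset added to every
#'   segment (imperfect motion correction moves myocardial samples relative
#'   to the cavity globally);
#' * inferior contamination: RCA-territory segments are mixed with the
#'   hepatic/intestinal extracardiac curve.
#'
#' Mixing fractions are drawn as `|N(0, sd)|` clipped to `[0, 0.5]`; the
#' motion offset is signed `N(0, sd)`. A second processing by the same
#' operator reuses the operator's draw plus an increment scaled by
#' `intra_operator_scale`, so same-operator replicates differ less than
#' different operators.
#'
#' @param valve_plane_sd SD of the basal-segment blood mixing fraction.
#' @param axis_sd SD of the circumferential mixing fraction.
#' @param motion_sd SD of the global additive blood-fraction offset.
#' @param inferior_contamination_sd SD of the RCA-segment extracardiac
#'   mixing fraction.
#' @param intra_operator_scale Multiplier (< 1) applied to the increment
#'   drawn for a same-operator repeat processing.
#' @return An object of class `perturbation_config`.
#' @export
perturbation_config <- function(valve_plane_sd = 0.045, axis_sd = 0.03,
                                motion_sd = 0.014,
                                inferior_contamination_sd = 0.07,
                                intra_operator_scale = 0.5) {
  for (nm in c("valve_plane_sd", "axis_sd", "motion_sd",
               "inferior_contamination_sd"))
    assert_scalar_num(get(nm), nm, lo = 0)
  assert_scalar_num(intra_operator_scale, "intra_operator_scale", 0, 1)
  structure(list(valve_plane_sd = valve_plane_sd, axis_sd = axis_sd,
                 motion_sd = motion_sd,
                 inferior_contamination_sd = inferior_contamination_sd,
                 intra_operator_scale = intra_operator_scale),
            class = "perturbation_config")
}

# Raw (pre-transform) perturbation draws for one study processing.
draw_perturbation_raw <- function(pcfg, seed, scale = 1) {
  with_seed_(seed, list(
    valve  = stats::rnorm(1, 0, scale * pcfg$valve_plane_sd),
    axis   = stats::rnorm(1, 0, scale * pcfg$axis_sd),
    motion = stats::rnorm(1, 0, scale * pcfg$motion_sd),
    inf    = stats::rnorm(5, 0, scale * pcfg$inferior_contamination_sd)
  ))
}

# Cyclic neighbour within each ring, rotation direction d in {-1, +1}.
ring_neighbour <- function(d) {
  nb <- integer(17)
  for (ring in list(1:6, 7:12, 13:16)) {
    k <- length(ring)
    nb[ring] <- ring[((seq_len(k) - 1 + d) %% k) + 1]
  }
  nb[17] <- 17L
  nb
}

perturb_study <- function(study, raw) {
  tacs <- study$tacs
  cb <- tacs$blood
  seg_cols <- sprintf("seg%02d", 1:17)
  segs <- as.matrix(tacs[seg_cols])

  # axis: circumferential mixing with the neighbour in the drawn direction
  m_ax <- clip(abs(raw$axis), 0, 0.5)
  if (m_ax > 0) {
    nb <- ring_neighbour(if (raw$axis >= 0) 1L else -1L)
    segs <- (1 - m_ax) * segs + m_ax * segs[, nb]
  }
  # valve plane: a misplaced basal slice limit shifts the whole short-axis
  # stack, so blood mixing is strongest basally and graded down the rings
  m_v <- clip(abs(raw$valve), 0, 0.5)
  if (m_v > 0) {
    ring_factor <- c(rep(1, 6), rep(0.4, 6), rep(0.15, 5))
    for (s in 1:17) {
      m <- m_v * ring_factor[s]
      segs[, s] <- (1 - m) * segs[, s] + m * cb
    }
  }
  # inferior contamination: RCA segments mixed with the extracardiac curve
  m_inf <- clip(abs(raw$inf), 0, 0.5)
  if (any(m_inf > 0)) {
    if (is.null(tacs$extracardiac))
      abort_input("inferior contamination requires an `extracardiac` TAC")
    rca <- c(3, 4, 9, 10, 15)
    for (j in seq_along(rca)) {
      segs[, rca[j]] <- (1 - m_inf[j]) * segs[, rca[j]] +
        m_inf[j] * tacs$extracardiac
    }
  }
  # residual motion: signed global blood-fraction offset
  if (raw$motion != 0) segs <- pmax(segs + raw$motion * cb, 0)

  tacs[seg_cols] <- tibble::as_tibble(segs)
  dynamic_study(study$condition, study$schedule, tacs,
                patient_id = study$patient_id, truth = study$truth,
                blood_fine = study$blood_fine,
                extracardiac_fine = study$extracardiac_fine)
}

#' Apply a simulated operator's post-processing perturbation
#'
#' Perturbs the rest and stress studies of a pair with independent draws per
#' condition (each study is processed separately). Deterministic in
#' `(pair, pcfg, operator_seed, replicate)`: replicate 1 is the operator's
#' base processing; replicate 2 and later add a fresh increment scaled by
#' `pcfg$intra_operator_scale`, modelling a repeat processing by the same
#' operator. A zero-magnitude configuration returns the input unchanged.
#'
#' @param pair A `study_pair`.
#' @param pcfg A [perturbation_config()].
#' @param operator_seed Integer seed identifying the operator.
#' @param replicate Processing replicate number (1 = base).
#' @return A perturbed `study_pair`.
#' @export
apply_operator_perturbation <- function(pair, pcfg, operator_seed,
                                        replicate = 1) {
  stopifnot(inherits(pair, "study_pair"), inherits(pcfg, "perturbation_config"))
  one <- function(study) {
    base <- draw_perturbation_raw(pcfg, derive_seed(operator_seed, study$condition, "base"))
    raw <- base
    if (replicate > 1) {
      inc <- draw_perturbation_raw(
        pcfg, derive_seed(operator_seed, study$condition, "rep", replicate),
        scale = pcfg$intra_operator_scale)
      raw <- purrr::map2(base, inc, `+`)
    }
    perturb_study(study, raw)
  }
  study_pair(one(pair$rest), one(pair$stress), patient_id = pair$patient_id)
}
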