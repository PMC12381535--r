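# Fixture builders used across the suite.  Everything is generated in code.

PLANTED7 <- c("crea_day2", "age", "agvhd", "disease_phase", "cgvhd",
              "disease", "plt_engraft")

# a tiny handwritten valid cohort data frame (3 records)
tiny_cohort_df <- function() {
  data.frame(
    gender = c(1, 2, 1), age = c(47, 30, 65),
    disease = c(2, 1, 3), disease_phase = c(1, 2, 1),
    donor_type = c(2, 1, 3), hla_group = c(1, 2, 1),
    graft_source = c(1, 1, 2), conditioning = c(2, 1, 2),
    plt_day2 = c(61.6, 20, 150), ldh_day2 = c(180, 500, 90),
    crea_day2 = c(2.6, 0.9, 4.1), cd34 = c(6, 3.2, 9.9),
    neut_engraft = c(1, 1, 0), plt_engraft = c(1, 0, 1),
    dri = c(1, 3, 2), agvhd = c(1, 2, 1), cgvhd = c(0, 1, 0),
    sec_malig = c(0, 0, 1),
    outcome = c("alive", "dead", "alive_lt24"))
}

# cohort whose outcome is a deterministic function of the DRI code alone
# (low -> alive, intermediate -> dead, high -> alive_lt24): perfectly
# separable on {dri}, with integer codes so no split interpolation can miss
separable_cohort <- function(n = 400, seed = 11) {
  co <- generate_cohort(n, seed = seed, constraint = NULL)
  df <- as.data.frame(co)
  df$outcome <- c("alive", "dead", "alive_lt24")[df$dri]
  as_cohort(df, provenance = "synthetic deterministic-dri")
}

# strong noise-free planted signal with equal weight on each of the seven
# influential parameters (platelet engraftment protective), ordered
# thresholds as in the default mechanism
recovery_signal <- function(strength = 12) {
  w <- c(1, 1, 1, 1, 1, 1, -1) / sqrt(7)
  r1 <- stats::qnorm(0.47)
  r2 <- stats::qnorm(0.69)
  signal_spec(PLANTED7,
              rbind(-strength * w, strength * w, 0 * w),
              c(0, -strength * (r1 + r2), -strength * r1),
              noise_scale = 0)
}

# planted-signal cohort with a strong, noise-free mechanism on the seven
# influential parameters
strong_signal_cohort <- function(n = 564, seed = 1, strength = 12) {
  generate_cohort(n, seed = seed, signal = recovery_signal(strength),
                  constraint = NULL)
}

fast_protocol <- function(n_splits = 2, n_seeds = 1, master_seed = 1) {
  split_protocol(n_splits = n_splits, n_seeds = n_seeds,
                 master_seed = master_seed)
}
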