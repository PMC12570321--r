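# Shared end-to-end scenario: quantify a default synthetic field against an
# anchored calibration built from a simulated fixed-cell anchor field
# (buffer-equilibrated at pH 5.0), mirroring the single-anchor protocol.

run_endtoend <- function(seed) {
  cfg <- sim_config(seed = seed)
  sim <- simulate_stack(cfg)

  anchor_cfg <- sim_config(seed = seed + 1000L, ph = c(5.0, 0))
  anchor_ratio <- field_ratio(
    background_correct(simulate_stack(anchor_cfg)$stack))$ratio
  sol <- fit_sigmoid(simulate_titration(cfg$probe, seq(3.5, 7.4, 0.25),
                                        replicates = 2, noise_cv = 0.02,
                                        seed = seed + 2000L))
  sol$bottom <- sol$bottom / cfg$reference_response
  sol$top <- sol$top / cfg$reference_response
  cal <- build_calibration_anchored(anchor_ratio, 5.0, sol)

  st <- background_correct(sim$stack)
  field <- field_ratio(st, calibration = cal)
  objects <- quantify_objects(st, cal, units = "pixel")

  treated_truth <- apply_treatment(sim$truth, 0.4)
  treated <- simulate_stack(sim_config(seed = seed + 5000L),
                            truth = treated_truth)
  objects_t <- quantify_objects(background_correct(treated$stack), cal,
                                units = "pixel")
  list(cfg = cfg, truth = sim$truth, cal = cal, field = field,
       objects = objects, treated_truth = treated_truth,
       objects_treated = objects_t)
}

# Absolute per-object pH error against the nearest ground-truth organelle
# (lateral match within 4 px).
matched_object_errors <- function(objects, truth) {
  ok <- objects$flag %in% c("ok", "extrapolated") & !is.na(objects$ph)
  errs <- vapply(which(ok), function(i) {
    d2 <- (truth$y - objects$centroid_y[i])^2 +
      (truth$x - objects$centroid_x[i])^2
    j <- which.min(d2)
    if (d2[j] < 16) abs(objects$ph[i] - truth$ph[j]) else NA_real_
  }, numeric(1))
  errs[!is.na(errs)]
}

mean_object_ph <- function(objects) {
  ok <- objects$flag %in% c("ok", "extrapolated")
  mean(objects$ph[ok], na.rm = TRUE)
}
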