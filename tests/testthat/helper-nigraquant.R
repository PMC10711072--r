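# shared fixtures: the calibrated default phantom configuration is expensive
# (~10 s) and deterministic, so it is computed once per test run
calibrated_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_copula(phantom_config(seed = 1))
    cache
  }
})

# reference effect sizes implied by the published group summaries at the
# published sample sizes
reference_effect_sizes <- function() {
  fm <- reference_feature_marginals()
  ns <- reference_group_sizes()
  g <- vapply(seq_len(nrow(fm)), function(i)
    hedges_g(fm$mean_control[i], fm$sd_control[i], ns["control"],
             fm$mean_patient[i], fm$sd_patient[i], ns["patient"]),
    numeric(1))
  names(g) <- fm$feature
  g
}

# small deterministic volume + mask pair for feature-extraction tests
toy_volume <- function(values, dims = c(6, 6, 3), voxel = c(0.5, 0.5, 3),
                       modality = "NM") {
  arr <- array(0, dims)
  arr[seq_along(values)] <- values
  volume_image(arr, voxel, modality)
}
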