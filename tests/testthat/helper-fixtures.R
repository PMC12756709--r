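# shared fixtures: small phantoms keep the suite fast without changing any
# protocol value (prescription, bounds, fractionation stay at defaults)

small_phantom_config <- function(shape = 24) {
  phantom_config(shape = rep(shape, 3), gtv_radius = 9, ctv_hd_radius = 12,
                 ctv_ld_radius = 15, oar_radius = 6, body_radius = 33,
                 centre_jitter_mm = 1.5)
}

tiny_phantom_config <- function() {
  phantom_config(shape = c(16, 16, 16), gtv_radius = 7.5, ctv_hd_radius = 10,
                 ctv_ld_radius = 12, oar_radius = 4.5, body_radius = 22,
                 centre_jitter_mm = 1)
}

small_case <- function(seed = 1, config = small_phantom_config()) {
  ph <- make_phantom(config, seed = seed)
  maps <- make_cell_map(ph$grid, ph$structures$masks$GTV, seed = seed)
  c(ph, maps)
}

# survival of a dose vector under given per-voxel clonogen counts (direct
# evaluation used by the brute-force planning oracles)
survival_of_dose <- function(d, counts, params = tcp_params(),
                             scheme = fractionation_scheme()) {
  voxel_tcp(eqd(d, scheme), counts, params)$survival
}
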