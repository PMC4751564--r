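# Shared fixtures: all synthetic, built in code at test time.

# Generator with every noise source switched off (offsets stay on unless
# zeroed explicitly), for exact-propagation checks.
noise_free_config <- function(n_strains = 96, seed = 1,
                              plate_offset_range = c(0.3, 0.6), ...) {
  screen_config(
    n_strains = n_strains, hit_fraction = 0, null_bio_sd = 0,
    well_noise_sd = 0, plate_offset_range = plate_offset_range,
    dropout_rate = 0, seed = seed, ...
  )
}

# One plate's F-J tibble from raw values.
make_fj <- function(values, strain_id = sprintf("s%03d", seq_along(values)),
                    plate_id = "P01", condition = "KCl",
                    role = rep("library", length(values))) {
  tibble::tibble(
    strain_id = strain_id, plate_id = plate_id, condition = condition,
    role = role, fj = values
  )
}

ratio_tbl <- function(x) {
  tibble::tibble(strain_id = names(x), log2_ratio = unname(x))
}

# Small Erdos-Renyi-style edge list: m unique unordered pairs over n genes.
random_edge_list <- function(n, m, seed = 1) {
  cfg <- graph_config(n_genes = n, background_edges = m,
                      planted_set_size = 0, planted_extra_edges = 0,
                      seed = seed)
  simulate_graph(cfg)
}
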