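# Small hand-built sample table used across tests.
demo_samples <- function() {
  tibble::tibble(
    sample_id = c("S1", "S2", "S3", "S4"),
    chocolate_type = c("dark", "milk", "milk", "dark"),
    cacao_pct = c(72, 35, 28, 55),
    cd_conc = c(0.29, 0.021, 0.013, 0.042)
  )
}

# Monte Carlo model with every symbol point-valued, for collapse and
# linearity checks. Bypasses default_mcs_model so the values are explicit.
point_model <- function(endpoint = "HQ", mode = "per_bw",
                        c_milk = 0.028, c_dark = 0.057,
                        ingr_milk = 0.37, ingr_dark = 0.22,
                        ef = 350, ed = 30, bw = 70,
                        iterations = 100, seed = 1) {
  consts <- chocrisk::default_constants()
  dists <- list(
    C_milk = chocrisk::dist_point(c_milk),
    C_dark = chocrisk::dist_point(c_dark),
    IngR_milk = chocrisk::dist_point(ingr_milk),
    IngR_dark = chocrisk::dist_point(ingr_dark),
    EF = chocrisk::dist_point(ef),
    ED = chocrisk::dist_point(ed),
    CF = chocrisk::dist_point(consts$cf)
  )
  if (mode == "absolute") dists$BW <- chocrisk::dist_point(bw)
  if (endpoint == "HQ") {
    dists$RfD <- chocrisk::dist_point(consts$rfd)
  } else {
    dists$CSF <- chocrisk::dist_point(consts$csf)
    dists$AT <- chocrisk::dist_point(consts$at_c)
  }
  structure(
    list(
      endpoint = endpoint, group = "test", mode = mode,
      iterations = iterations, seed = seed, dists = dists
    ),
    class = "mcs_model"
  )
}
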