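# shared fixtures and a per-session memo cache for expensive pipeline runs

memo <- local({
  env <- new.env(parent = emptyenv())
  function(key, expr) {
    if (is.null(env[[key]])) env[[key]] <- force(expr)
    env[[key]]
  }
})

test_props <- function(mua = 0.1) optical_properties(mua, 10, 1.4)
grid_20ps <- time_grid(0, 5, 0.02)
grid_8ps <- time_grid(0, 5, 0.008)

baseline_props_690 <- function() {
  tab <- extinction_table()
  optical_properties(hemoglobin_to_mua(30, 20, 690, tab), 10, 1.4)
}

# small homogeneous synthesis used by several acquisition/spectral tests
small_homog_dtof <- function(n_tot = 1e5, tmeas = 60, fs = 20, sdd = 4,
                             amp = 0.01, seed = 1) {
  key <- paste("dtof", n_tot, tmeas, fs, sdd, amp, seed)
  memo(key, {
    perts <- if (amp > 0)
      list(perturbation_spec(amp, 1, layer = "WHOLE", species = "both"))
    else list()
    hemo <- make_hemo_series(hemo_baseline(), perts, tmeas, fs, seed = seed)
    op <- slab_forward_operator(baseline_props_690(), slab_geometry(), sdd,
                                grid_20ps, 690)
    synthesize_dtof_series(
      hemo, list("690" = op),
      acquisition_settings(n_tot, tmeas, fs, sdd, 690, seed = seed))[["690"]]
  })
}

bilayer_op_690 <- function(sdd) {
  memo(paste("bilayer-op", sdd), {
    p <- baseline_props_690()
    tmpp_pathlengths(p, p, bilayer_geometry(), sdd, grid_20ps)
  })
}
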