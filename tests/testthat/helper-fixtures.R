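# shared fixtures and a memo cache so expensive solves are reused across
# test files within one run
.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

day2_model <- function(...) colony_model(d = 395, ...)

zero_tilt <- function(d = 395, ...)
  colony_model(d = d, tilt = tilt_distribution(0, 0, 0), ...)

day2_crystal <- function(pol = "TM")
  crystal_spec_2d(395, 395, 1.38, 1.34, pol)

# small commensurate FDTD fixture: 2 lateral periods, short slab
tiny_lattice <- function() lattice_spec(395, 375, box = c(1200, 790), ff = 0.55)

fast_cfg <- function(...)
  fdtd_config(n_steps = 4096, wavelengths = seq(300, 700, by = 5), ...)
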