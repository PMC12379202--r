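# shared fixtures: reference materials and light sampler settings

t4_br <- function() {
  br <- c(0.088, 0.644, 0.268)
  br / sum(br)
}

t4_voxel_br <- function() {
  br <- c(0.062, 0.683, 0.255)
  br / sum(br)
}

quick_control <- function() sampler_control(chains = 2L, warmup = 400L,
                                            iter = 400L, thin = 3L)

# low-activity phantom for clean (pile-up-free) selection tests
quiet_phantom <- function(activity = 0.1) {
  lapply(xad4_phantom(), function(tb) {
    tb$activity <- activity
    tb
  })
}

noiseless_scanner <- function() {
  scanner_spec(timing_sigma = 0, energy_fwhm_frac_511 = 0,
               randoms_rate_frac = 0)
}
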