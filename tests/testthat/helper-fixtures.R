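# Shared fixtures, all generated in code.

# default synthetic template (13 vials, synthetic round-number references)
fix_template <- function() syntheticPhantomTemplate()

# small noiseless study for fast end-to-end tests
fix_quick_sim <- function(noiseSigma = 0, seed = 42, ...) {
  simulatePhantom(simConfig(template = fix_template(),
                            noiseSigma = noiseSigma, seed = seed, ...))
}

# named reference ADC lookup from a template
fix_ref_adc <- function(template = fix_template()) {
  v <- vials(template)
  stats::setNames(v$ref_adc_um2s, v$label)
}

# in-plane vial centre error (mm) of a detection against simulation truth
fix_centre_errors <- function(det, sim) {
  truth <- sim$truth$vials
  ctrs <- t(vapply(detectedRois(det), roiCentre, numeric(3)))
  sqrt((ctrs[truth$label, 1] - truth$centre_x_mm)^2 +
       (ctrs[truth$label, 2] - truth$centre_y_mm)^2)
}

# brute-force one-sided signed-rank p (Pratt zeros), for n <= 12
bf_signed_rank_p <- function(x, alternative = "greater") {
  rk <- rank(abs(x))
  nz <- which(x != 0)
  r <- rk[nz]
  w_obs <- sum(r[x[nz] > 0])
  m <- length(r)
  if (m == 0) return(1)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.vector(signs %*% r)
  if (alternative == "greater") mean(w_all >= w_obs - 1e-12)
  else mean(w_all <= w_obs + 1e-12)
}
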