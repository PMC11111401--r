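# shared fixtures: curves, tiny date sets, and a cheap MCMC configuration

identity_curve <- function(old = 7000, young = 0, sigma = 0) {
  synth_curve(old, young, wiggle_amplitude = 0, sigma = sigma)
}

# a .14c-style file written on the fly
write_curve_file <- function(lines) {
  path <- tempfile(fileext = ".14c")
  writeLines(lines, path)
  path
}

toy_dates <- function(cra, error = rep(30, length(cra)),
                      site = rep("S1", length(cra)),
                      region = "toy") {
  read_dates(data.frame(
    lab_id = sprintf("LAB-%03d", seq_along(cra)),
    site_id = site, cra = cra, error = error, region = region,
    stringsAsFactors = FALSE))
}

fast_mcmc <- function(seed = 1L, n_iter = 2000L, burn_in = 400L) {
  mcmc_config(n_chains = 3L, n_iter = n_iter, burn_in = burn_in,
              thin = 2L, seed = seed)
}

# synthetic posterior with fixed draws, for envelope tests
degenerate_posterior <- function(r, a, b, n = 100L) {
  structure(list(draws = matrix(r, nrow = n, ncol = 2),
                 accept = c(1, 1),
                 config = mcmc_config(n_iter = 2L, burn_in = 1L, thin = 1L),
                 a = a, b = b, n_bins = n),
            class = "posterior_sample")
}
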