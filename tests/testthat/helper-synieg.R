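# shared fixtures, built in code

# short uniform-grid signals for fast model tests
quick_signals <- function(preset = "serum10", dur = NULL, ...) {
  p <- stimulus_preset(preset, ...)
  if (!is.null(dur)) p$duration_min <- dur
  make_stimulus(p)
}

# a small, fast movie: 64x64 field, 4 sites, one-hour timecourse
small_movie <- function(seed = 1, optics = optics_noise(),
                        circuit = circuit_preset("fos_btg2", n_sites = 4),
                        t_max = 70) {
  sig <- make_stimulus(stimulus_preset("serum10"))
  traj <- simulate_circuit(circuit, signals = sig)
  sub <- traj[traj$time_min <= t_max, ]
  for (a in c("spec", "params", "stim_onset_min", "dt_min"))
    attr(sub, a) <- attr(traj, a)
  class(sub) <- class(traj)
  geom <- cell_geometry(image_shape = c(64, 64), nucleus_axes = c(18, 14),
                        n_sites = circuit$n_sites, seed = seed + 100)
  list(movie = render_movie(sub, geom, optics, seed = seed),
       traj = sub, geom = geom)
}

# render one synthetic Gaussian spot image (in photons, no camera offset)
spot_image <- function(n = 21, A = 100, x0 = 11, y0 = 11, sx = 1.5,
                       sy = 1.5, b = 10) {
  xm <- matrix(seq_len(n), n, n, byrow = TRUE)
  ym <- matrix(seq_len(n), n, n)
  b + A * exp(-(xm - x0)^2 / (2 * sx^2) - (ym - y0)^2 / (2 * sy^2))
}

# drop trajectory attributes so data-frame contents can be compared
plain_df <- function(x) {
  df <- as.data.frame(x)
  attributes(df) <- attributes(df)[c("names", "row.names")]
  class(df) <- "data.frame"
  df
}

# independent pooled-variance Student t oracle (hand evaluation of the
# textbook formula; kept free of stats::t.test)
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
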