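# builders for synthetic colony tables used across the model tests

# noise-free or noisy shell-expressing population on a log-uniform diameter
# grid; returns the colony-table columns the fitting functions consume
makeShellColonies <- function(w, n, xlo, xhi, m = 5e7, cv = 0, seed = 1,
                              widthFun = NULL) {
  set.seed(seed)
  x <- exp(stats::runif(n, log(xlo), log(xhi)))
  ww <- if (is.null(widthFun)) rep(w, n) else pmin(widthFun(x), x / 2)
  eps <- if (cv > 0) stats::rnorm(n, 0, cv) else 0
  f <- m * shellVolume(x, ww) * pmax(1 + eps, 0)
  data.frame(diameter_um = x, volume_mm3 = sphereVolume(x),
             surface_mm2 = sphereSurface(x), f_au = f,
             fv_au_mm3 = f / sphereVolume(x), fs_au_mm2 = f / sphereSurface(x))
}

# a HyperbolicFit carrying a known asymptote, for feeding the shell chain
# directly in geometry-consistent validation cases
makeFixedFit <- function(b, a = 1, c = 0, band = NULL, boot = NULL,
                         xRange = c(max(b, 1), 1500)) {
  new("HyperbolicFit", a = a, b = b, c = c, alpha = NA_real_, gamma = c,
      gammaSource = "intercept", degenerate = FALSE, loss = 0, tau = 0.5,
      n = 100L, xRange = xRange,
      boot = if (is.null(boot))
        matrix(numeric(0), 0, 3, dimnames = list(NULL, c("a", "b", "c")))
      else boot,
      band = if (is.null(band))
        data.frame(x = numeric(0), lo = numeric(0), hi = numeric(0))
      else band)
}

# one clean event plus one violator per gating rule
ruleEvents <- function() {
  clean <- data.frame(tof = 5000, peak_green = 200, width_green = 5000,
                      int_green = 100, int_red = 100, int_yellow = 100)
  ev <- clean[rep(1L, 6L), ]
  ev$tof[2] <- 164      # below TOF window
  ev$tof[3] <- 13006    # above TOF window
  ev$peak_green[4] <- 79
  ev$width_green[5] <- 1999
  ev$int_red[6] <- 24
  rownames(ev) <- NULL
  ev
}
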