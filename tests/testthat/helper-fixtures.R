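## shared fixtures: small, fast synthetic inputs built in code

quick_grid <- function(n = 60) exp(seq(log(1), log(1e4), length.out = n))

## tiny FTIR construction with exactly-zero SC regions (Gaussian bands)
gauss_band <- function(x, c0, w, a) a * exp(-log(2) * ((x - c0) / w)^2)

make_additive_ftir <- function(c0 = 0.8) {
  g <- seq(300, 5000, by = 2)
  solvent <- spectrum(g, gauss_band(g, 3300, 300, 1) +
                        gauss_band(g, 1600, 200, 0.8) +
                        gauss_band(g, 600, 250, 0.4), unit = "cm-1")
  sc_true <- spectrum(g, gauss_band(g, 1650, 40, 0.4) +
                        gauss_band(g, 1550, 35, 0.25), unit = "cm-1")
  solution <- spectrum(g, c0 * solvent$value + sc_true$value, unit = "cm-1")
  list(grid = g, solvent = solvent, sc_true = sc_true, solution = solution,
       c0 = c0)
}
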