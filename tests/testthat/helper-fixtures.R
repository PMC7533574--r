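# Shared fixtures: the published 18-b-value protocol constants and the
# group summary table the generator targets.

# printed b-value table (s/mm^2), by Delta (ms); entries are as printed,
# i.e. already rounded to integers
printed_bvalues <- list(
  `27.060` = c(151, 239, 377, 595, 939, 1481),
  `39.560` = c(245, 387, 611, 964, 1521, 2399),
  `52.060` = c(339, 535, 845, 1333, 2103, 3317)
)
printed_G0_mT <- c(15.67, 19.68, 24.73, 31.06, 39.01, 49.00)
printed_delta_ms <- 20.676

# published group summaries: mean and SD per hemisphere
ref_groups <- list(
  controls = list(n = 11,
    alpha = list(mean = c(1.588, 1.604), sd = c(0.047, 0.049)),
    hurst = list(mean = c(0.464, 0.479), sd = c(0.033, 0.028)),
    mu    = list(mean = c(-0.166, -0.145)),
    adc   = list(mean = c(0.00108, 0.00104), sd = c(0.00013, 0.00012))),
  mild = list(n = 12,
    alpha = list(mean = c(1.563, 1.562), sd = c(0.030, 0.040)),
    hurst = list(mean = c(0.470, 0.485), sd = c(0.027, 0.040)),
    mu    = list(mean = c(-0.170, -0.156)),
    adc   = list(mean = c(0.00119, 0.00115), sd = c(0.00013, 0.00017))),
  moderate = list(n = 12,
    alpha = list(mean = c(1.531, 1.519), sd = c(0.045, 0.041)),
    hurst = list(mean = c(0.468, 0.481), sd = c(0.030, 0.049)),
    mu    = list(mean = c(-0.186, -0.177)),
    adc   = list(mean = c(0.00139, 0.00137), sd = c(0.00021, 0.00025)))
)

# a scheme cut down to one Delta and two amplitudes, for cheap unit tests
tiny_scheme <- function() {
  build_scheme(Deltas = 40e-3, G0s = c(20e-3, 40e-3), delta = 20e-3,
               n_b0 = 2, directions = c("x", "y", "z"))
}

# 1-D "volume": one voxel per parameter triple, rendered under a scheme
signals_as_volume <- function(att_matrix, scheme, S0 = 1) {
  n <- nrow(att_matrix)
  vols <- cbind(matrix(S0, n, scheme$n_b0), S0 * att_matrix)
  array(vols, c(n, 1, 1, ncol(vols)))
}

# expand per-cell attenuation to per-measurement columns (3 directions)
cells_to_measurements <- function(att_cells, scheme) {
  m <- scheme$measurements
  cells <- scheme_cells(scheme)
  idx <- match(paste(format(m$Delta, digits = 15), format(m$G0, digits = 15)),
               paste(format(cells$Delta, digits = 15),
                     format(cells$G0, digits = 15)))
  att_cells[, idx, drop = FALSE]
}
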