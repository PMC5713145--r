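# Shared fixtures: small hand-built datasets and a desk-scale simulation
# configuration (small tetragonal cell so enumeration stays cheap).

# a partial dataset living on the h axis of a P1 cubic cell: one observation
# per element of `keys` (as (h, 1, 0) indices), unless intensities given per
# observation
make_axis_ds <- function(id, keys, intensity = NULL, sigma = NULL,
                         cell = crystal_cell(20, 20, 20), sg = 1) {
  if (is.null(intensity)) intensity <- 100 + 10 * keys
  if (is.null(sigma)) sigma <- rep(1, length(keys))
  partial_dataset(id, cell, sg,
                  data.frame(h = keys, k = 1L, l = 0L,
                             intensity = intensity, sigma = sigma))
}

small_config <- function(...) {
  args <- list(...)
  defaults <- list(cell = crystal_cell(30, 30, 45), sg = 96, d_min = 2.2,
                   n_classes = 2, datasets_per_class = 8, wedge_fraction = 0.3,
                   within_cc = 0.95, between_cc = 0.3, seed = 42)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

toy_xds_text <- function() {
  c("!FORMAT=XDS_ASCII    MERGE=FALSE    FRIEDEL'S_LAW=FALSE",
    "!SPACE_GROUP_NUMBER=    96",
    "!UNIT_CELL_CONSTANTS=    57.80    57.80    150.00  90.000  90.000  90.000",
    "!X-RAY_WAVELENGTH=  0.979000",
    "!ITEM_H=1", "!ITEM_K=2", "!ITEM_L=3", "!ITEM_IOBS=4", "!ITEM_SIGMA(IOBS)=5",
    "!END_OF_HEADER",
    "     1     2     3  1.234E+02  5.60E+00  0.5",
    "    -1     2     4  8.000E+01  4.00E+00  0.7",
    "!END_OF_DATA")
}
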