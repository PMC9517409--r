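#' Covariate vocabulary for station air-quality panels
#'
#' The panel layout carries 20 covariates: 4 co-pollutants (SO2, NO2, CO, O3),
#' 15 meteorological variables (humidity, precipitation, sun hours, three air
#' pressures, six air/surface temperatures, three wind speeds) and NDVI as a
#' vegetation-cover proxy. `covariate_names()` returns them in canonical column
#' order; `covariate_blocks()` groups them into the correlated blocks that the
#' synthetic generator emulates and that varimax-rotated components are labelled
#' against; `covariate_scales()` returns realistic means and standard deviations
#' (units as suffixed in the names: concentrations in ug/m3 except CO in mg/m3,
#' pressures in hPa, temperatures in degC, wind in m/s, precipitation in mm,
#' sun hours in h, ARH and NDVI unitless).
#'
#' @return `covariate_names()`: a character vector of length 20.
#'   `covariate_blocks()`: a named list of character vectors.
#'   `covariate_scales()`: a tibble with columns `variable`, `mean`, `sd`.
#' @examples
#' covariate_names()
#' covariate_blocks()$pollutant
#' @export
covariate_names <- function() {
  c("SO2", "NO2", "CO", "O3", "ARH", "HCP", "SH",
    "MaxP", "AP", "MinP", "MaxT", "AT", "MinT",
    "MaxWS", "AWS", "EWS", "MaxST", "AST", "MinST", "NDVI")
}

#' @rdname covariate_names
#' @export
covariate_blocks <- function() {
  list(
    temperature = c("MaxT", "AT", "MinT", "MaxST", "AST", "MinST", "O3"),
    wind        = c("MaxWS", "AWS", "EWS"),
    pressure    = c("MaxP", "AP", "MinP"),
    pollutant   = c("SO2", "NO2", "CO"),
    humidity    = c("ARH", "HCP", "SH"),
    vegetation  = "NDVI"
  )
}

#' @rdname covariate_names
#' @export
covariate_scales <- function() {
  tibble::tribble(
    ~variable, ~mean,   ~sd,
    "SO2",      20.66,  21.34,
    "NO2",      28.37,  16.15,
    "CO",        0.78,   0.45,
    "O3",       73.71,  29.01,
    "ARH",       0.62,   0.13,
    "HCP",       0.50,   1.76,
    "SH",        7.81,   2.99,
    "MaxP",    996.44,  11.83,
    "AP",      993.94,  11.98,
    "MinP",    991.08,  12.13,
    "MaxT",      7.47,  15.81,
    "AT",        1.13,  15.57,
    "MinT",     -4.86,  15.31,
    "MaxWS",     5.58,   1.73,
    "AWS",       2.64,   1.03,
    "EWS",       8.97,   2.88,
    "MaxST",    17.34,  21.19,
    "AST",       6.01,  14.39,
    "MinST",    -1.22,  10.43,
    "NDVI",     -0.07,   0.12
  )
}

# variables whose loading on the block factor is negative (sun hours move
# against humidity/precipitation within the humidity block)
negative_loading_vars <- function() "SH"
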