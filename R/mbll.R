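#' Modified Beer-Lambert law parameters
#'
#' The MBLL relates optical-density change at two wavelengths to chromophore
#' concentration changes via `dOD_lambda = (eps_HbO2,lambda * dHbO2 +
#' eps_HbR,lambda * dHbR) * d * DPF`, where `d` is the source-detector
#' separation and DPF the differential pathlength factor. Decadic (base-10)
#' extinction coefficients are paired with base-10 optical density
#' throughout (Homer2 uses the same convention pair).
#'
#' @param wavelengths two wavelengths, nm
#' @param extinction 2x2 matrix, rows = wavelengths, columns = (HbO2, HbR),
#'   decadic molar extinction in 1/(Molar cm); default looked up from the
#'   packaged table (approximate compiled literature values; round-trip
#'   identities hold for any invertible choice)
#' @param dpf differential pathlength factor (applied to both wavelengths)
#' @param separation source-detector separation, cm
#' @return an `mbll_params`
#' @export
mbll_params <- function(wavelengths = c(705, 830), extinction = NULL,
                        dpf = 6, separation = 3) {
  if (dpf <= 0 || separation <= 0)
    stop("dpf and separation must be > 0")
  if (is.null(extinction))
    extinction <- lookup_extinction(wavelengths)
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2, 2)))
    stop("extinction must be a 2x2 matrix (wavelength x chromophore)")
  if (abs(det(extinction)) < 1e-12 * prod(abs(extinction[1, ]) +
                                          abs(extinction[2, ])))
    stop("extinction matrix is singular or near-singular")
  structure(
    list(wavelengths = wavelengths, extinction = extinction, dpf = dpf,
         separation = separation, log_base = 10),
    class = "mbll_params"
  )
}

#' Look up extinction coefficients from the packaged table
#'
#' @param wavelengths wavelengths in nm (must be rows of the table)
#' @param table_path optional path to an alternative CSV with columns
#'   `wavelength_nm`, `eps_hbo2`, `eps_hbr`
#' @return 2x2 matrix (rows = wavelengths, cols = HbO2, HbR)
#' @export
lookup_extinction <- function(wavelengths, table_path = NULL) {
  if (is.null(table_path))
    table_path <- system.file("extdata", "extinction_coefficients.csv",
                              package = "nirsfilt")
  tab <- utils::read.csv(table_path)
  idx <- match(wavelengths, tab$wavelength_nm)
  if (anyNA(idx))
    stop("wavelength(s) not in extinction table: ",
         paste(wavelengths[is.na(idx)], collapse = ", "))
  m <- as.matrix(tab[idx, c("eps_hbo2", "eps_hbr")])
  dimnames(m) <- list(paste0(wavelengths, "nm"), c("HbO2", "HbR"))
  m
}

#' Optical density change from raw intensity
#'
#' `dOD = -log10(I / I_baseline)` per sample.
#'
#' @param intensity an intensity [channel_series()], all samples > 0
#' @param baseline `"mean"` (baseline = mean of the record) or `"first_n"`
#' @param n_baseline number of leading samples when `baseline = "first_n"`
#' @return an OD [channel_series()]
#' @export
od_from_intensity <- function(intensity, baseline = c("mean", "first_n"),
                              n_baseline = 25L) {
  stopifnot(inherits(intensity, "channel_series"))
  baseline <- match.arg(baseline)
  v <- intensity$values
  bad <- which(v <= 0)
  if (length(bad))
    stop("non-positive intensity at sample index ", bad[1])
  i0 <- if (baseline == "mean") mean(v) else mean(v[seq_len(min(n_baseline, length(v)))])
  channel_series(-log10(v / i0), intensity$fs, "OD",
                 wavelength = intensity$wavelength)
}

# pathlength-scaled extinction matrix E such that od = E %*% conc
mbll_matrix <- function(params) params$extinction * params$separation * params$dpf

#' Concentration changes from an OD pair (MBLL inversion)
#'
#' Solves the 2x2 system per sample.
#'
#' @param od_pair list of two OD [channel_series()] at the two wavelengths,
#'   in the order of `params$wavelengths`
#' @param params an [mbll_params()]
#' @return list with `hbo2` and `hbr` [channel_series()] (Molar)
#' @export
conc_from_od <- function(od_pair, params) {
  stopifnot(inherits(params, "mbll_params"), length(od_pair) == 2L)
  o1 <- as_series_values(od_pair[[1]]); o2 <- as_series_values(od_pair[[2]])
  fs <- od_pair[[1]]$fs
  if (length(o1) != length(o2) || fs != od_pair[[2]]$fs)
    stop("OD pair must share length and fs")
  Einv <- solve(mbll_matrix(params))
  hbo2 <- Einv[1, 1] * o1 + Einv[1, 2] * o2
  hbr <- Einv[2, 1] * o1 + Einv[2, 2] * o2
  list(hbo2 = channel_series(hbo2, fs, "HbO2"),
       hbr = channel_series(hbr, fs, "HbR"))
}

#' OD pair from concentration changes (forward MBLL)
#'
#' Exact inverse of [conc_from_od()].
#'
#' @param conc_pair list with `hbo2` and `hbr` [channel_series()] (Molar)
#' @param params an [mbll_params()]
#' @return list of two OD [channel_series()] in wavelength order
#' @export
od_from_conc <- function(conc_pair, params) {
  stopifnot(inherits(params, "mbll_params"))
  c1 <- as_series_values(conc_pair$hbo2); c2 <- as_series_values(conc_pair$hbr)
  fs <- conc_pair$hbo2$fs
  E <- mbll_matrix(params)
  list(
    channel_series(E[1, 1] * c1 + E[1, 2] * c2, fs, "OD",
                   wavelength = params$wavelengths[1]),
    channel_series(E[2, 1] * c1 + E[2, 2] * c2, fs, "OD",
                   wavelength = params$wavelengths[2])
  )
}
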