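#' Unit conventions for diffusion quantities
#'
#' The package uses one unit convention throughout: b-values in s/mm2 and
#' ADC reported in um2/s, so the exponent of the mono-exponential signal
#' model is \code{-b * adcUm2sToMm2s(adc)}. Since 1 mm2 = 1e6 um2, the
#' single conversion constant is 1 um2/s = 1e-6 mm2/s; free water at 0 degC
#' (about 1100 um2/s) is 1.1e-3 mm2/s, or equivalently 1.1 um2/ms, the unit
#' the QIBA diffusion profile uses for repeatability coefficients.
#'
#' @param adc numeric, ADC value(s) in um2/s.
#' @return `adcUm2sToMm2s` returns ADC in mm2/s; `adcMm2sToUm2s` its
#'   inverse; `adcUm2sToUm2ms` returns ADC in um2/ms.
#' @examples
#' adcUm2sToMm2s(1100)   # 1.1e-3
#' adcUm2sToUm2ms(1100)  # 1.1
#' @export
adcUm2sToMm2s <- function(adc) adc * 1e-6

#' @rdname adcUm2sToMm2s
#' @export
adcMm2sToUm2s <- function(adc) adc * 1e6

#' @rdname adcUm2sToMm2s
#' @export
adcUm2sToUm2ms <- function(adc) adc * 1e-3
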