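#' Melanopic photometric constants
#'
#' `K_MEL` is the melanopic irradiance (W m^-2) corresponding to one lux of
#' melanopic equivalent daylight illuminance (melanopic EDI), i.e. the
#' melanopic efficacy constant of the D65 reference illuminant (CIE S 026).
#' `R_EML` is the ratio of equivalent melanopic lux (EML, Lucas toolbox scale)
#' to melanopic EDI: EML = `R_EML` * melanopic EDI.
#'
#' @format Length-one numeric constants.
#' @name melanopic-constants
NULL

#' @rdname melanopic-constants
#' @export
K_MEL <- 1.3262e-3

#' @rdname melanopic-constants
#' @export
R_EML <- 1.103

#' Convert melanopic EDI to melanopic irradiance
#'
#' Melanopic equivalent daylight illuminance (lx) is converted to melanopic
#' irradiance E_e,mel (W m^-2) via the D65 melanopic efficacy constant
#' [K_MEL]: 250 lx corresponds to 0.33 W m^-2, the daytime recommendation of
#' the expert-consensus (Brown et al.) thresholds.
#'
#' @param edi Melanopic EDI in lux; non-negative numeric vector.
#' @param k_mel Conversion constant, W m^-2 per melanopic-EDI lux.
#' @return Melanopic irradiance in W m^-2.
#' @export
#' @examples
#' mel_edi_to_irradiance(250)  # ~0.33
mel_edi_to_irradiance <- function(edi, k_mel = K_MEL) {
  check_nonneg(edi, "edi")
  edi * k_mel
}

#' Convert melanopic irradiance to melanopic EDI
#'
#' Inverse of [mel_edi_to_irradiance()]; round-trip is exact to machine
#' precision.
#'
#' @param e Melanopic irradiance in W m^-2; non-negative numeric vector.
#' @inheritParams mel_edi_to_irradiance
#' @return Melanopic EDI in lux.
#' @export
irradiance_to_mel_edi <- function(e, k_mel = K_MEL) {
  check_nonneg(e, "e")
  e / k_mel
}

#' Convert equivalent melanopic lux to melanopic EDI
#'
#' EML (the Lucas-toolbox scale used by the WELL standard) relates to
#' melanopic EDI by the fixed ratio [R_EML]; the WELL tier-1 threshold of
#' 150 EML corresponds to 136 lx melanopic EDI.
#'
#' @param eml Equivalent melanopic lux; non-negative numeric vector.
#' @param r_eml Ratio EML / melanopic EDI.
#' @return Melanopic EDI in lux.
#' @export
eml_to_mel_edi <- function(eml, r_eml = R_EML) {
  check_nonneg(eml, "eml")
  eml / r_eml
}

#' @rdname eml_to_mel_edi
#' @param edi Melanopic EDI in lux.
#' @export
mel_edi_to_eml <- function(edi, r_eml = R_EML) {
  check_nonneg(edi, "edi")
  edi * r_eml
}

#' Approximate D55 equivalent illuminance from melanopic irradiance
#'
#' The N-VE framework is stated in D55 equivalent illuminance. D55 is
#' slightly warmer than the D65 reference, so one D55-equivalent lux carries
#' a little less melanopic power than one melanopic-EDI lux; the default
#' ratio 0.89 is an approximation (the weighting curve itself is out of
#' scope) and is configurable.
#'
#' @param e Melanopic irradiance, W m^-2.
#' @param r_d55 Melanopic content of D55 relative to D65.
#' @inheritParams mel_edi_to_irradiance
#' @return D55 equivalent illuminance, lx.
#' @export
irradiance_to_ed55 <- function(e, r_d55 = 0.89, k_mel = K_MEL) {
  check_nonneg(e, "e")
  e / (k_mel * r_d55)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop(sprintf("`%s` must be a non-negative numeric vector", name),
         call. = FALSE)
  }
  invisible(x)
}
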