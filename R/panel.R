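#' Default laboratory variable panel
#'
#' The reduced coagulation-oriented panel used throughout the package:
#' platelet count (PLT), plateletcrit (PCT), international normalized ratio
#' (INR), prothrombin time (PT), activated partial thromboplastin time (APTT),
#' D-dimer, fibrin degradation products (FDP), fibrinogen (FIB), the daily
#' SOFA score, and lactate. These are the variables that dominate feature
#' importance in coagulopathy prediction; wider hospital panels can be passed
#' anywhere a `variables` argument is accepted.
#'
#' @return character vector of variable names, in canonical order
#' @export
#' @examples
#' default_panel()
default_panel <- function() {
  c("PLT", "PCT", "INR", "PT", "APTT", "DDIMER", "FDP", "FIB", "SOFA", "LACTATE")
}

#' Physiologic reportable ranges for the default panel
#'
#' Used to clamp raw values before min-max normalization. These are broad
#' plausible laboratory reporting ranges (documented stand-ins for
#' hospital-specific clinical reportable ranges, which are never public).
#'
#' @return named list of `c(lo, hi)` per variable, with a `unit` attribute
#' @export
default_ranges <- function() {
  r <- list(
    PLT     = c(1, 1000),   # x10^9/L
    PCT     = c(0.01, 1),   # % plateletcrit
    INR     = c(0.5, 10),   # ratio
    PT      = c(8, 120),    # seconds
    APTT    = c(15, 240),   # seconds
    DDIMER  = c(0.01, 80),  # mg/L FEU
    FDP     = c(0.5, 300),  # mg/L
    FIB     = c(0.2, 12),   # g/L
    SOFA    = c(0, 24),     # score
    LACTATE = c(0.1, 30)    # mmol/L
  )
  attr(r, "unit") <- c(
    PLT = "1e9/L", PCT = "%", INR = "ratio", PT = "s", APTT = "s",
    DDIMER = "mg/L", FDP = "mg/L", FIB = "g/L", SOFA = "score",
    LACTATE = "mmol/L"
  )
  r
}

panel_units <- function(variables) {
  u <- attr(default_ranges(), "unit")
  out <- u[variables]
  out[is.na(out)] <- "unknown"
  names(out) <- variables
  out
}
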