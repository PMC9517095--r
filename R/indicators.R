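#' Monitoring-indicator catalogue
#'
#' The indicators carried by the national monitoring feeds: twelve
#' water-quality variables (four-hourly cadence) and three hydrology
#' variables (published twice daily). Column names are the canonical keys
#' used throughout the package, in payload files and in store tables;
#' \code{NH4} stands for ammonia nitrogen (NH4+-N).
#'
#' @return A data frame with columns \code{indicator}, \code{name},
#'   \code{units} and \code{category} (\code{"water_quality"} or
#'   \code{"hydrology"}).
#' @examples
#' wq_indicators()
#' @export
wq_indicators <- function() {
  data.frame(
    indicator = c("Tub", "COD_Mn", "NH4", "TP", "TN", "PH", "CHL", "CA",
                  "BOD5", "DO", "WT", "WQC", "WL", "WWL", "Q"),
    name = c("Turbidity", "Permanganate index", "Ammonia nitrogen",
             "Total phosphorus", "Total nitrogen", "pH",
             "Chlorophyll a", "Algal density",
             "Biochemical oxygen demand (5-day)", "Dissolved oxygen",
             "Water temperature", "Water quality classification",
             "Water level", "Warning water level", "Flow"),
    units = c("NTU", "mg/L", "mg/L", "mg/L", "mg/L", "-", "mg/L",
              "cells/L", "mg/L", "mg/L", "degC", "-", "m", "m", "m3/s"),
    category = c(rep("water_quality", 12), rep("hydrology", 3)),
    stringsAsFactors = FALSE
  )
}

#' Default set of modeled indicators
#'
#' The seven indicators for which forecast models are built by default:
#' ammonia nitrogen, biochemical oxygen demand, permanganate index,
#' dissolved oxygen, pH, total phosphorus and water temperature.
#'
#' @return Character vector of indicator keys.
#' @export
modeled_indicators <- function() {
  c("NH4", "BOD5", "COD_Mn", "DO", "PH", "TP", "WT")
}

# indicators whose units make negative values physically impossible
.nonnegative_indicators <- function() {
  c("Tub", "COD_Mn", "NH4", "TP", "TN", "CHL", "CA", "BOD5", "DO", "Q")
}

.numeric_indicators <- function() {
  setdiff(wq_indicators()$indicator, "WQC")
}

.is_known_indicator <- function(x) x %in% wq_indicators()$indicator
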