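#' Reference body-measurement comparison
#'
#' The published comparison of tape-measured ("true") and
#' point-cloud-extracted shoulder, abdominal and hip widths for seven sows,
#' in meters. Used as the worked example for [mean_relative_error()]: the
#' shoulder and hip columns reproduce the reported mean relative errors of
#' 3.144% and 3.820%.
#'
#' @return data frame with columns `id`, `true_shoulder`,
#'   `extracted_shoulder`, `true_abdomen`, `extracted_abdomen`, `true_hip`,
#'   `extracted_hip`.
#' @export
reference_body_measurements <- function() {
  path <- system.file("extdata", "reference_body_measurements.csv",
                      package = "pigback", mustWork = TRUE)
  utils::read.csv(path)
}
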