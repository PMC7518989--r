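# Shipped default calibration and packaged fixtures.

#' Shipped default calibration
#'
#' Loads the parameter file committed under `inst/extdata/params_default.yaml`:
#' the default calibration of the model on the packaged 2013-like heat-wave
#' fixture and city profile, from which the mitigation and
#' marginal-temperature experiments are reproduced. See the package
#' vignette for how these values were obtained.
#'
#' @return A [model_params()].
#' @export
default_params <- function() {
  read_params_yaml(heatsd_extdata("params_default.yaml"))
}

#' Path to a packaged data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
heatsd_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "heatsd")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no packaged file `", file, "`", call. = FALSE)
  path
}
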