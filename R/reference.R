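# Packaged reference coefficients.

#' Load the packaged reference emissions models
#'
#' Returns the reference coefficient set shipped with the package: the TPM
#' concentration surface and nicotine mass-ratio line characterised for one
#' pen-style e-cigarette with a 1.8%-nicotine 50:50 PG/VG e-liquid.  The
#' coefficients are device- and consumable-specific — the functional form
#' travels, the numbers do not.  The file's coefficient checksum is
#' verified on every load.
#'
#' @return A list with `tpm` ([tpm_model()]), `nic` ([nic_model()]) and
#'   `meta` (provenance, fit summary, design envelope).
#' @export
#' @examples
#' ref <- reference_model()
#' coef(ref$tpm)[["b1"]]
reference_model <- function() {
  path <- system.file("extdata", "reference_model.json", package = "puffyield",
                      mustWork = TRUE)
  m <- read_model(path)
  want <- m$meta$checksum
  got <- round(sum(c(m$tpm$b, m$nic$beta) * 1e6))
  if (is.null(want) || got != want)
    stop_data("packaged reference model is corrupted (checksum ", got,
              " != ", want, ")")
  m
}
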