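#' Write a clamp trace to CSV
#'
#' Columns `t_ms`, `V_mV`, `I_total_nA`, `I_L_nA`, `I_Cm_nA`, `I_Ca_nA`,
#' `I_H_nA`.
#'
#' @param trace a `"clamp_trace"`.
#' @param path output file.
#' @export
write_trace_csv <- function(trace, path) {
  out <- data.frame(t_ms = trace$t, V_mV = trace$V,
                    I_total_nA = trace$I_total, I_L_nA = trace$I_L,
                    I_Cm_nA = trace$I_Cm, I_Ca_nA = trace$I_Ca,
                    I_H_nA = trace$I_H)
  utils::write.csv(out, path, row.names = FALSE)
}

#' Write an impedance profile to CSV
#'
#' Columns `f_Hz`, `Z_MOhm`, `phi_rad`.
#'
#' @param profile an `"impedance_profile"`.
#' @param path output file.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(f_Hz = profile$f, Z_MOhm = profile$Z,
                              phi_rad = profile$phi),
                   path, row.names = FALSE)
}

#' Write / read an attribute set as JSON
#'
#' Flat JSON keyed by the attribute names; round-trips targets and measured
#' attribute sets.
#'
#' @param attrs an `"mpr_attributes"`.
#' @param path file path.
#' @export
write_attributes_json <- function(attrs, path) {
  jsonlite::write_json(unclass(attrs), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_attributes_json
#' @export
read_attributes_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "mpr_attributes")
}

#' Write / read model parameters as flat JSON
#'
#' @param params an `"mpr_params"` vector.
#' @param path file path.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(as.list(as_model_params(params, bounds = NULL)), path,
                       auto_unbox = TRUE, digits = NA)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  as_model_params(unlist(jsonlite::read_json(path, simplifyVector = TRUE)),
                  bounds = NULL)
}

#' Write / read a fitted model population as CSV
#'
#' One row per model: the eight parameters plus any objective, attribute and
#' provenance columns present.
#'
#' @param pop data frame (e.g. the `optimal` element of an `"mpr_fit"`).
#' @param path file path.
#' @export
write_population_csv <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  utils::read.csv(path)
}
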