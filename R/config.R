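#' Run configuration
#'
#' Thresholds and options used across the pipeline. Defaults are the
#' published constants: acceptable-mismatch revised RMSD thresholds of
#' 0.2 Angstrom (class I loci) and 0.1 Angstrom (class II loci), and a
#' 0.50 Angstrom single/total revised RMSD cutoff separating mild (grade
#' I-II) from severe (grade III-IV) predicted aGVHD.
#'
#' @param class1_threshold acceptable-mismatch threshold for HLA-A/B/Cw, Angstrom.
#' @param class2_threshold acceptable-mismatch threshold for DRB1/DQB1/DPB1, Angstrom.
#' @param severity_cutoff single/total revised RMSD cutoff for severe aGVHD, Angstrom.
#' @param boundary classification of a value exactly at the cutoff:
#'   `"severe"` (conservative default) or `"mild"`.
#' @param fit superposition fit set for the revised RMSD (`"region"` or `"all"`).
#' @param digits decimals used when reporting values (table convention: 4).
#' @return list of class `matching_config`.
#' @export
matching_config <- function(class1_threshold = 0.2, class2_threshold = 0.1,
                        severity_cutoff = 0.50,
                        boundary = c("severe", "mild"),
                        fit = c("region", "all"), digits = 4L) {
  boundary <- match.arg(boundary)
  fit <- match.arg(fit)
  if (class1_threshold <= 0 || class2_threshold <= 0 || severity_cutoff <= 0)
    abort("all thresholds must be positive", "config_error")
  structure(list(class1_threshold = class1_threshold,
                 class2_threshold = class2_threshold,
                 severity_cutoff = severity_cutoff,
                 boundary = boundary, fit = fit, digits = as.integer(digits)),
            class = "matching_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [matching_config()]; absent keys keep the
#' defaults.
#' @param path YAML file.
#' @return `matching_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("config file not found: %s", path), "hla_io_error")
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(matching_config)))]
  do.call(matching_config, args)
}
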