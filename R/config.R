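#' Default configuration
#'
#' Nested list mirroring the module/parameter hierarchy: `circulation`,
#' `atria`, `sarcomere` (shared by the three walls), `heart` (wall volumes,
#' reference areas, hypertrophy multiplier), `protocol` (solver tolerances,
#' convergence and homeostasis settings, preload fractions), `scenario`
#' (operating length and treatment Fmax target). The configuration is the
#' experiment: every published perturbation is an edit of these values.
#'
#' @return nested named list
#' @export
default_config <- function() {
  list(
    circulation = unclass(circulation_params()),
    atria = unclass(atrial_params()),
    sarcomere = unclass(sarcomere_params()),
    heart = list(Vw_L = 54, Vw_S = 30, Vw_R = 16,
                 Am_ref_L = 66, Am_ref_S = 23, Am_ref_R = 74,
                 k_stiff2_rv = 850, rv_mass_mult = 1.15),
    protocol = list(rtol = 1e-7, atol_frac = 1e-9, nsamp = 500,
                    max_beats = 500, sv_tol = 0.01, edv_tol = 5e-4,
                    aop_low = 110, aop_high = 125,
                    preload_fractions = c(1, 0.95, 0.9, 0.85, 0.8)),
    scenario = list(Ls_op = 2.2, a6_fmax_ratio = 0.78)
  )
}

flatten_keys <- function(x, prefix = NULL) {
  out <- character()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste0(prefix, ".", nm)
    if (is.list(x[[nm]])) out <- c(out, flatten_keys(x[[nm]], key))
    else out <- c(out, key)
  }
  out
}

#' Apply dotted-path overrides to a configuration
#'
#' Keys use dotted paths (`"circulation.PVR"`). Unknown keys and type
#' mismatches are errors naming the offending key.
#'
#' @param config nested list (see [default_config()])
#' @param overrides named list, e.g. `list("circulation.PVR" = 0.088)`
#' @return the updated configuration
#' @export
apply_overrides <- function(config, overrides) {
  if (!length(overrides)) return(config)
  valid <- flatten_keys(config)
  for (key in names(overrides)) {
    if (!key %in% valid)
      stop("unknown configuration key '", key, "'")
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    cur <- config[[path]]
    val <- overrides[[key]]
    if (!is.numeric(val) || !is.numeric(cur))
      stop("type mismatch for configuration key '", key,
           "': numeric value required")
    config[[path]] <- val
  }
  config
}

#' Parse a configuration file with overrides
#'
#' Precedence: package defaults, then values from the YAML file, then the
#' override list. Unknown keys at any stage are rejected with the offending
#' key named.
#'
#' @param path optional YAML file with (possibly partial) nested settings
#' @param overrides named list of dotted-path overrides
#' @return resolved configuration list of class `rv_config`
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    file_cfg <- yaml::read_yaml(path)
    flat <- function(x, prefix = NULL) {
      out <- list()
      for (nm in names(x)) {
        key <- if (is.null(prefix)) nm else paste0(prefix, ".", nm)
        if (is.list(x[[nm]])) out <- c(out, flat(x[[nm]], key))
        else out[[key]] <- x[[nm]]
      }
      out
    }
    config <- apply_overrides(config, flat(file_cfg))
  }
  config <- apply_overrides(config, overrides)
  structure(config, class = "rv_config")
}

#' Build a model from a configuration
#'
#' @param config output of [parse_config()] or [default_config()]
#' @return [rv_model()]
#' @export
model_from_config <- function(config = default_config()) {
  sarc <- do.call(sarcomere_params, config$sarcomere)
  sarc_r <- sarc
  sarc_r$k_stiff2 <- config$heart$k_stiff2_rv
  circ <- do.call(circulation_params, config$circulation)
  atr <- do.call(atrial_params, config$atria)
  h <- config$heart
  pr <- config$protocol
  rv_model(circ = circ, atria = atr,
           sarc_L = sarc, sarc_S = sarc, sarc_R = sarc_r,
           Vw = c(L = h$Vw_L, S = h$Vw_S, R = h$Vw_R),
           Am_ref = c(L = h$Am_ref_L, S = h$Am_ref_S, R = h$Am_ref_R),
           protocol = list(rtol = pr$rtol, atol_frac = pr$atol_frac,
                           nsamp = pr$nsamp, max_beats = pr$max_beats,
                           sv_tol = pr$sv_tol, edv_tol = pr$edv_tol,
                           aop_range = c(pr$aop_low, pr$aop_high)))
}

#' Write the resolved configuration next to run outputs
#'
#' Reproducibility contract: every analysis run records the fully resolved
#' configuration and the package version alongside its outputs.
#'
#' @param config resolved configuration
#' @param dir output directory (created if needed)
#' @return invisibly, the file path
#' @export
write_resolved_config <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "resolved_config.yaml")
  meta <- list(package_version =
                 as.character(utils::packageVersion("rvfsim")))
  yaml::write_yaml(c(unclass(config), meta), path)
  invisible(path)
}
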