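#' Read a simulation configuration file
#'
#' Configuration files are YAML or JSON with up to three top-level blocks:
#' `cohort` (arguments of [cohort_spec()]), `protocol` (arguments of
#' [protocol_config()]) and `eeg` (arguments of [eeg_synth_spec()], with
#' `bands` as a list of band records). Missing blocks fall back to the
#' package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list with elements `cohort`, `protocol`, `eeg`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file '%s' not found", path))
  ext <- tolower(sub(".*\\.", "", path))
  raw <- switch(ext,
                yaml = ,
                yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                config_error("config must be .yaml, .yml or .json"))
  # YAML 1.1 reads a bare `n:` key as the boolean FALSE; map it (and the
  # unambiguous alias `n_profiles`) back to the cohort-size argument
  if (!is.null(raw$cohort)) {
    names(raw$cohort)[names(raw$cohort) %in% c("FALSE", "n_profiles")] <- "n"
  }
  list(
    cohort = build_spec(cohort_spec, raw$cohort,
                        vec_args = c("cv_range", "score_means")),
    protocol = build_spec(protocol_config, raw$protocol,
                          vec_args = c("conditions", "effect_targets")),
    eeg = build_eeg_spec(raw$eeg)
  )
}

build_spec <- function(ctor, args, vec_args = character(0)) {
  args <- args %||% list()
  for (v in vec_args) if (!is.null(args[[v]])) args[[v]] <- unlist(args[[v]])
  do.call(ctor, args)
}

build_eeg_spec <- function(args) {
  args <- args %||% list()
  if (!is.null(args$bands)) {
    bands <- as.data.frame(do.call(rbind, lapply(args$bands, as.data.frame)))
    args$bands <- do.call(dplyr::bind_rows,
                          purrr::pmap(bands, band_spec))
  }
  do.call(eeg_synth_spec, args)
}

#' Default simulation configuration
#'
#' @return The configuration list [read_config()] would produce for an empty
#'   file: default cohort, protocol and EEG settings.
#' @export
default_config <- function() {
  list(cohort = cohort_spec(), protocol = protocol_config(),
       eeg = eeg_synth_spec())
}
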