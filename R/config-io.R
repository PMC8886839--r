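# Config serialization. One canonical YAML schema, versioned, with stable
# key ordering so saves are byte-reproducible and diffable.

config_to_list <- function(config) {
  list(
    schema_version = config$schema_version,
    threshold = config$threshold,
    weight_tolerance = config$weight_tolerance,
    weights_stale = config$weights_stale,
    criteria = lapply(config$criteria, function(cr) {
      out <- list(
        id = cr$id,
        name = cr$name,
        rank = cr$rank,
        weight = cr$weight,
        external_score = cr$external_score
      )
      if (!cr$external_score) {
        out$options <- lapply(cr$options, function(o) {
          list(label = o$label,
               score_fraction = o$score_fraction,
               exclusion_trigger = o$exclusion_trigger,
               provisional = o$provisional)
        })
      }
      out
    })
  )
}

#' Serialize a configuration to canonical YAML
#'
#' Output is deterministic (fixed key order, 17-significant-digit numerics)
#' so that two saves of the same configuration are byte-identical and
#' `load_config(save_config(cfg))` reproduces `cfg` exactly.
#'
#' @param config a valid `mcda_config`.
#' @param path optional file path; when given, the YAML is written there
#'   (UTF-8) and the path returned invisibly.
#' @return the YAML text (invisibly, if `path` is given).
#' @export
save_config <- function(config, path = NULL) {
  viol <- validate_config(config)
  if (nrow(viol) > 0) abort_mcda(format_violations(viol), "mcda_validation_error")
  txt <- yaml::as.yaml(config_to_list(config), precision = 17L,
                       indent.mapping.sequence = TRUE)
  if (!is.null(path)) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(txt, con, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Load and validate a configuration
#'
#' Accepts a file path or YAML text. Every structural invariant is checked;
#' violations are reported together with the offending field path.
#'
#' @param source path to a YAML config file, or a single string of YAML.
#' @return a validated `mcda_config`.
#' @export
load_config <- function(source) {
  raw <- tryCatch(
    {
      if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
        yaml::read_yaml(source)
      } else {
        yaml::yaml.load(paste(source, collapse = "\n"))
      }
    },
    error = function(e) abort_mcda(paste0("malformed config: ", conditionMessage(e)),
                                   "mcda_schema_error")
  )
  if (!is.list(raw) || is.null(raw$criteria)) {
    abort_mcda("malformed config: missing 'criteria'", "mcda_schema_error")
  }
  crits <- lapply(raw$criteria, function(cr) {
    for (f in c("id", "name", "rank", "weight")) {
      if (is.null(cr[[f]])) {
        abort_mcda(paste0("malformed config: criterion missing '", f, "'"),
                   "mcda_schema_error")
      }
    }
    structure(
      list(
        id = cr$id,
        name = cr$name,
        rank = as.integer(cr$rank),
        weight = as.numeric(cr$weight),
        options = lapply(cr$options, function(o) {
          structure(
            list(label = o$label,
                 score_fraction = as.numeric(o$score_fraction),
                 exclusion_trigger = isTRUE(o$exclusion_trigger),
                 provisional = isTRUE(o$provisional)),
            class = "scoring_option"
          )
        }),
        external_score = isTRUE(cr$external_score)
      ),
      class = "mcda_criterion"
    )
  })
  cfg <- structure(
    list(
      schema_version = as.integer(raw$schema_version %||% 1L),
      threshold = as.numeric(raw$threshold %||% 65),
      weight_tolerance = as.numeric(raw$weight_tolerance %||% 0.01),
      weights_stale = isTRUE(raw$weights_stale),
      criteria = crits
    ),
    class = "mcda_config"
  )
  viol <- validate_config(cfg)
  if (nrow(viol) > 0) abort_mcda(format_violations(viol), "mcda_validation_error")
  cfg
}
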