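#' Load the trigger-tool vocabulary
#'
#' The vocabulary is a versioned YAML configuration holding the code lists
#' (priorities, triage colours, conveyance modes, chief complaints),
#' physiologic plausibility bounds, rule thresholds, the five documentation
#' criteria behind trigger A1, the chief-complaint examination map behind B1D,
#' the condition-specific rules behind B1B and the drug formulary behind L1.
#' Keeping it in configuration rather than code reflects that trigger criteria
#' reference region-specific guidelines and documentation systems.
#'
#' @param path path to a vocabulary YAML; default is the configuration shipped
#'   with the package.
#' @return a list of class `att_vocabulary`.
#' @export
att_vocabulary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "vocabulary.yaml", package = "emstrigger")
  if (!nzchar(path) || !file.exists(path)) abort("vocabulary file not found")
  voc <- yaml::read_yaml(path)
  required <- c("codes", "bounds", "thresholds", "documentation_criteria",
                "core_vitals", "exam_map", "b1b_rules", "formulary")
  missing <- setdiff(required, names(voc))
  if (length(missing))
    abort(paste0("vocabulary is missing sections: ", paste(missing, collapse = ", ")))
  if (length(voc$documentation_criteria) == 0)
    abort("vocabulary must configure at least one documentation criterion")
  structure(voc, class = c("att_vocabulary", "list"))
}

#' Load the trigger registry
#'
#' The registry mirrors the trigger tool's published trigger list: id, title,
#' group (general, care process, medication), the evaluator kind that encodes
#' its positivity criteria, and parent links for the B1 and B6 subtriggers.
#' Two activation profiles are shipped: `"rrr900"`, the set used during the
#' 900-record retrospective review, and `"final"`, the revised set after the
#' last consensus round.
#'
#' @param profile activation profile name, `"rrr900"` (default) or `"final"`,
#'   or `NULL` to activate every registered trigger.
#' @param path path to a registry YAML; default is the shipped registry.
#' @return a tibble of class `att_registry` with one row per trigger
#'   (`trigger_id`, `title`, `group`, `kind`, `flag`, `parent`, `subtriggers`,
#'   `active`).
#' @export
att_registry <- function(profile = "rrr900", path = NULL) {
  path <- path %||% system.file("extdata", "registry.yaml", package = "emstrigger")
  if (!nzchar(path) || !file.exists(path)) abort("registry file not found")
  reg <- yaml::read_yaml(path)
  if (is.null(reg$triggers) || !length(reg$triggers)) abort("registry lists no triggers")
  tab <- tibble(
    trigger_id  = map_chr(reg$triggers, "id"),
    title       = map_chr(reg$triggers, "title"),
    group       = map_chr(reg$triggers, "group"),
    kind        = map_chr(reg$triggers, "kind"),
    flag        = map_chr(reg$triggers, function(x) x$flag %||% NA_character_),
    parent      = map_chr(reg$triggers, function(x) x$parent %||% NA_character_),
    subtriggers = map(reg$triggers, function(x) as.character(x$of %||% character()))
  )
  if (anyDuplicated(tab$trigger_id))
    abort("trigger ids must be unique in the registry")
  if (is.null(profile)) {
    tab$active <- TRUE
  } else {
    if (!profile %in% names(reg$profiles))
      abort(paste0("unknown registry profile: ", profile,
                   " (available: ", paste(names(reg$profiles), collapse = ", "), ")"))
    tab$active <- tab$trigger_id %in% unlist(reg$profiles[[profile]])
  }
  structure(tab, class = c("att_registry", class(tab)), profile = profile)
}

#' Bundle the configuration needed to screen records
#'
#' @param vocabulary an [att_vocabulary()] list.
#' @param registry an [att_registry()] table.
#' @return a list of class `att_config`.
#' @export
att_config <- function(vocabulary = att_vocabulary(), registry = att_registry()) {
  structure(list(vocabulary = vocabulary, registry = registry),
            class = "att_config")
}
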