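#' Read an architecture spec or run configuration from YAML
#'
#' An architecture section is either `preset: <name>` or an explicit
#' `variant`/`widths` pair (plus optional `num_classes`, `rotavg_copies`).
#'
#' @param path YAML file path.
#' @return An `architecture_spec`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("variant: decoupled", "widths: [5,5,5,5,5,5,5]"), f)
#' read_architecture_yaml(f)
#' @export
read_architecture_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$architecture)) cfg <- cfg$architecture
  architecture_from_config(cfg)
}

architecture_from_config <- function(cfg) {
  if (!is.null(cfg$preset)) return(architecture_preset(cfg$preset))
  stopifnot(!is.null(cfg$variant), !is.null(cfg$widths))
  architecture_spec(
    cfg$variant, unlist(cfg$widths),
    num_classes = cfg$num_classes %||% 4L,
    rotavg_copies = cfg$rotavg_copies %||% 12L
  )
}

#' Serialize an architecture spec to YAML
#'
#' @param spec An `architecture_spec`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_architecture_yaml <- function(spec, path) {
  obj <- list(
    variant = spec$variant,
    widths = as.integer(spec$widths),
    num_classes = spec$num_classes
  )
  if (!is.null(spec$rotavg_copies)) obj$rotavg_copies <- spec$rotavg_copies
  yaml::write_yaml(list(architecture = obj), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
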