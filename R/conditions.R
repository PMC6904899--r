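# Classed conditions so callers (and the CLI) can map failures to exit codes.

abort_config <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("quietward_config_error", "quietward_error"),
                      call = call))
}

abort_parse <- function(msg, file = NULL, line = NULL, call = sys.call(-1)) {
  loc <- if (!is.null(file)) {
    if (!is.null(line)) sprintf(" [%s:%d]", file, line) else sprintf(" [%s]", file)
  } else ""
  stop(errorCondition(paste0(msg, loc),
                      class = c("quietward_parse_error", "quietward_error"),
                      call = call))
}

abort_state <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("quietward_state_error", "quietward_error"),
                      call = call))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
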