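# Structured error conditions so callers (and the CLI) can branch on failure
# class rather than on message text.

stop_ct <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("ctoverrange_", class),
                                "ctoverrange_error")))
}

warn_ct <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(paste0("ctoverrange_", class),
                                     "ctoverrange_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
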