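#' @keywords internal
"_PACKAGE"

## internal helpers shared across modules

format_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("comutkit_format_error", "comutkit_error")))
}

param_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("comutkit_param_error", "comutkit_error")))
}

check_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    param_error(name, " must be a single number")
  }
  ok <- if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok) param_error(name, " must lie in ", if (open) "(0, 1)" else "[0, 1]",
                       ", got ", format(x))
  invisible(x)
}

check_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x)) {
    param_error(name, " must be a single integer")
  }
  if (positive && x < 1) param_error(name, " must be >= 1, got ", x)
  if (!positive && x < 0) param_error(name, " must be >= 0, got ", x)
  invisible(as.integer(x))
}

## significance stars at the conventional cutpoints (* <0.05, ** <0.01, *** <0.001)
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
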