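# Internal validation helpers and dotted-path access into nested lists.

SETTINGS <- c("home", "clinic", "hospital")

stop_val <- function(...) {
  stop(structure(
    class = c("ubt_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_val(name, " must be a single finite number")
  }
  invisible(x)
}

assert_proportion <- function(x, name) {
  assert_number(x, name)
  if (x < 0 || x > 1) stop_val(name, " must lie in [0, 1] (got ", format(x), ")")
  invisible(x)
}

assert_nonneg <- function(x, name) {
  assert_number(x, name)
  if (x < 0) stop_val(name, " must be non-negative (got ", format(x), ")")
  invisible(x)
}

# A per-setting map: named numeric over home/clinic/hospital (any order in input).
assert_setting_map <- function(x, name, proportions = TRUE) {
  if (is.list(x)) x <- unlist(x)
  if (!is.numeric(x) || is.null(names(x)) || !setequal(names(x), SETTINGS)) {
    stop_val(name, " must be a named numeric vector over {",
             paste(SETTINGS, collapse = ", "), "}")
  }
  x <- x[SETTINGS]
  for (s in SETTINGS) {
    if (proportions) assert_proportion(x[[s]], paste0(name, "[", s, "]"))
    else assert_nonneg(x[[s]], paste0(name, "[", s, "]"))
  }
  x
}

# Dotted-path accessors used by sensitivity analysis and calibration
# ("hidden.surgery_access.clinic", "ubt.efficacy_severe", ...).
get_path <- function(obj, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  for (p in parts) {
    if (is.null(obj) || !is.list(obj) && is.null(names(obj))) {
      stop_val("cannot resolve parameter path '", path, "'")
    }
    if (!p %in% names(obj)) stop_val("cannot resolve parameter path '", path, "'")
    obj <- obj[[p]]
  }
  if (!is.numeric(obj) || length(obj) != 1L) {
    stop_val("parameter path '", path, "' does not address a single numeric value")
  }
  obj
}

set_path <- function(obj, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(o, parts) {
    p <- parts[[1]]
    if (is.null(o) || !p %in% names(o)) {
      stop_val("cannot resolve parameter path '", path, "'")
    }
    if (length(parts) == 1L) {
      if (!is.numeric(o[[p]]) || length(o[[p]]) != 1L) {
        stop_val("parameter path '", path, "' does not address a single numeric value")
      }
      o[[p]] <- value
    } else {
      o[[p]] <- rec(o[[p]], parts[-1])
    }
    o
  }
  rec(obj, parts)
}
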