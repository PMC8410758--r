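# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_cfg("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_cfg("'%s' must be a single positive number", name)
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_cfg("'%s' must be a single non-negative number", name)
  as.numeric(x)
}

check_fraction <- function(x, name, open_left = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x > 1 ||
      (open_left && x <= 0) || (!open_left && x < 0))
    stop_cfg("'%s' must be a fraction in %s", name,
             if (open_left) "(0, 1]" else "[0, 1]")
  as.numeric(x)
}

# Gene identifiers are opaque strings; comparisons are case-folded and
# whitespace-stripped so that e.g. " Pax6" and "PAX6" collide.
normalize_ids <- function(ids) {
  toupper(trimws(as.character(ids)))
}
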