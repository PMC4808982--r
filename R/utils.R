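# Internal helpers shared across modules.

# stop with a classed condition so callers/tests can distinguish error kinds
stop_cumulair <- function(msg, class) {
  abort(msg, class = c(class, "cumulair_error"))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

# contiguous integer year range check
check_years_contiguous <- function(years, what = "years") {
  y <- sort(unique(years))
  if (length(y) > 1L && any(diff(y) != 1L)) {
    stop_cumulair(
      sprintf("%s must form a contiguous range; gaps at %s", what,
              paste(y[which(diff(y) != 1L)] + 1L, collapse = ", ")),
      "cumulair_validation_error"
    )
  }
  invisible(y)
}

# number of calendar days in a year (leap-aware)
days_in_year <- function(year) {
  ifelse((year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0, 366L, 365L)
}

new_cumulair_tbl <- function(x, subclass, ...) {
  out <- tibble::as_tibble(x)
  attrs <- list(...)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c(subclass, class(out))
  out
}
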