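# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# depth grids and wavelength grids must be strictly increasing throughout
check_strictly_increasing <- function(x, what = "grid") {
  stop_if_not(is.numeric(x) && length(x) >= 1 && all(is.finite(x)),
              sprintf("%s must be finite numeric", what))
  if (length(x) > 1 && any(diff(x) <= 0))
    stop(sprintf("%s must be strictly increasing (no duplicates)", what),
         call. = FALSE)
  invisible(x)
}

# trapezoidal integral of y(x); x strictly increasing
trapz_ <- function(x, y) {
  check_strictly_increasing(x, "integration grid")
  if (length(x) == 1) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
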