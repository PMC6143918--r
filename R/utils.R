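# internal helpers shared across modules

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library calls never disturb the
#' caller's random stream. A `NULL` seed evaluates the code with the current
#' stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible child seed
#'
#' Mixes a parent seed with an emission index through a Lehmer-style step so
#' every subnetwork in a recursion gets its own deterministic stream.
#' Result is always in `[1, 2^31 - 2]`.
#'
#' @keywords internal
#' @noRd
child_seed <- function(seed, index) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (abs(as.double(seed)) %% m)
  x <- (x * 48271 + as.double(index) * 16807 + 11) %% m
  as.integer(x %% (m - 1) + 1)
}

stop_modrec <- function(..., class) {
  stop(structure(
    class = c(class, "modrec_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_modrec(name, " must be a number in [", lower, ", ", upper, "]",
                class = "modrec_validation_error")
  }
  invisible(x)
}
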