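#' @keywords internal
"_PACKAGE"

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

utils::globalVariables(c("k", "value", "method"))

## NULL coalescing
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of their
#' seed arguments and never disturb the caller's RNG stream.
#' @noRd
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Combine two integer seeds into one (kept below 2^31)
#' @noRd
seed_combine <- function(a, b) {
  a <- as.double(a) %% 2147483647
  b <- as.double(b) %% 2147483647
  as.integer((a * 69069 + b * 362437 + 1) %% 2147483629)
}

#' Stage-tagged log message (suppressible via options(cryoice.quiet = TRUE))
#' @noRd
ci_log <- function(stage, fmt, ...) {
  if (isTRUE(getOption("cryoice.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[cryoice:%s] %s", stage, sprintf(fmt, ...)))
}
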