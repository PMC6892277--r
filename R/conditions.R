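#' Signal a configuration error
#'
#' Configuration errors (class `placvasc_config_error`) describe invalid or
#' missing run parameters; data errors (class `placvasc_data_error`) describe
#' inputs that cannot be analysed. The command-line wrapper maps them to
#' exit codes 2 and 3 respectively.
#'
#' @param message error message.
#' @keywords internal
#' @noRd
config_error <- function(message) {
  stop(errorCondition(message,
    class = c("placvasc_config_error", "placvasc_error")))
}

#' @noRd
data_error <- function(message) {
  stop(errorCondition(message,
    class = c("placvasc_data_error", "placvasc_error")))
}

# run code with a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}
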