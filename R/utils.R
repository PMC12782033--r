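#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's random state
#' afterwards, so generator functions with explicit `seed` arguments never
#' leak into (or depend on) the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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

#' Derive a child seed from a master seed
#'
#' Counter-based scheme: deterministic, collision-poor for the index ranges
#' used here, and always below 2^31 so the result is a valid R integer seed.
#'
#' @param master Integer master seed.
#' @param ... One or more non-negative integer indices (participant, system,
#'   task, replicate ...).
#' @return An integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  x <- as.double(master) %% 2147483647
  for (i in idx) {
    x <- (x * 69069 + as.double(i) * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(x)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' @keywords internal
ms_to_samples <- function(ms, rate_hz) as.integer(round(ms / 1000 * rate_hz))

# default 32-electrode layout (10-10 names) used by the simulator
DEFAULT_MONTAGE_32 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
  "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz"
)

#' Default channel labels
#'
#' Returns the first `n` labels of the package's 32-site layout, always
#' keeping the measurement sites used by the benchmark (Fz, Cz, Pz, P7, P8,
#' O1, Oz, O2) available for small montages.
#'
#' @param n Number of channels.
#' @return Character vector of length `n`.
#' @export
default_montage <- function(n = 32) {
  core <- c("O1", "Oz", "O2", "Fz", "Cz", "Pz", "P7", "P8")
  if (n <= length(core)) return(core[seq_len(n)])
  extra <- setdiff(c(DEFAULT_MONTAGE_32, "O2"), core)
  c(core, extra)[seq_len(n)]
}
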