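#' Derive a child seed from a parent seed and a string tag
#'
#' All randomness in the package flows from one master seed. Stage-, lesion-
#' and modality-specific seeds are derived deterministically so that any part
#' of a study can be replayed in isolation. The derivation is a multiplicative
#' congruential step on the parent seed combined with a polynomial rolling
#' hash of the tag, reduced modulo 2^31 - 1 (so results always fit a 32-bit
#' R integer).
#'
#' @param seed Integer parent seed.
#' @param ... Character or numeric tag components naming the child stream,
#'   e.g. `derive_seed(s, "lesion", 7, "AIM")`.
#' @return A positive integer seed, strictly less than 2^31.
#' @export
#' @examples
#' derive_seed(42, "lesion", 3, "WL")
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  tag <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- (as.numeric(seed) %% m) * 48271 %% m
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stopifnot_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "chromsep_config_error")
  }
  as.integer(x)
}

match_modality <- function(modality) {
  if (length(modality) != 1 || !modality %in% MODALITIES) {
    abort(sprintf("`modality` must be one of %s.",
                  paste(MODALITIES, collapse = ", ")),
          class = "chromsep_config_error")
  }
  modality
}

is_symmetric_psd <- function(sigma, tol = 1e-8) {
  if (!is.matrix(sigma) || any(dim(sigma) != c(3, 3))) return(FALSE)
  if (max(abs(sigma - t(sigma))) > tol * max(1, max(abs(sigma)))) return(FALSE)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(1, max(abs(ev)))
}
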