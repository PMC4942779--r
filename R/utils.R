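# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a typed ibdquant error
#'
#' All contract violations raise conditions whose class carries a stable
#' machine-readable identifier (e.g. \code{ibdq_channel_missing}), so callers
#' and tests can discriminate failure modes without parsing messages.
#'
#' @param id short identifier, e.g. "channel-missing"
#' @param msg human-readable message
#' @noRd
iq_stop <- function(id, msg) {
  cls <- paste0("ibdq_", gsub("-", "_", id))
  stop(errorCondition(msg, class = c(cls, "ibdq_error")))
}

iq_warn <- function(msg) warning(warningCondition(msg, class = "ibdq_warning"))

#' Names of the five acquisition channels, in canonical storage order.
#' @return character vector of length five
#' @export
channel_names <- function() {
  c("CARS2850", "CARS2930", "TPEF458", "TPEF525", "SHG")
}

# Channels that enter inter-modality contrast pairs (SHG excluded).
contrast_channels <- function() channel_names()[1:4]

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

# Reflected (mirror-including-edge) index vector of length n + 2*pad,
# e.g. n = 4, pad = 2 -> 2 1 1 2 3 4 4 3.
reflect_index <- function(n, pad) {
  if (pad == 0L) return(seq_len(n))
  if (pad > n) iq_stop("kernel-too-large", "padding exceeds image extent")
  c(rev(seq_len(pad)), seq_len(n), n + 1L - seq_len(pad))
}

# Separable Gaussian smoothing with mirror boundary handling.
# Truncated at 3*sigma; kernel renormalised to sum 1.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(x, along_rows) {
    n <- if (along_rows) nrow(x) else ncol(x)
    idx <- reflect_index(n, r)
    out <- 0 * x
    for (j in seq_along(k)) {
      sl <- idx[seq_len(n) + (j - 1L)]
      out <- out + k[j] * (if (along_rows) x[sl, , drop = FALSE]
                           else x[, sl, drop = FALSE])
    }
    out
  }
  conv1(conv1(m, TRUE), FALSE)
}

# Deterministic per-item seeds derived from a master seed, kept below 2^31.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
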