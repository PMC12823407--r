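# internal helpers shared across modules

#' @importFrom withr with_seed
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

#' Derive a reproducible child seed for a named pipeline stage
#'
#' Combines a master seed with a polynomial hash of the stage name so that
#' inserting or reordering stages does not perturb the random stream of any
#' other stage. The result is always a valid 32-bit integer seed.
#'
#' @param master_seed integer master seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(master_seed, stage) {
  stopifnot_scalar(master_seed, "master_seed")
  stopifnot(is.character(stage), length(stage) == 1L, nzchar(stage))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer((abs(master_seed) %% m * 48271 + h) %% m)
}

# log-log linear interpolation with slope-preserving extrapolation at both
# ends; x and y strictly positive, x strictly increasing
loglog_interp <- function(x, y, xout) {
  lx <- log(x); ly <- log(y); lo <- log(xout)
  n <- length(lx)
  idx <- findInterval(lo, lx, all.inside = TRUE)
  slope <- (ly[idx + 1L] - ly[idx]) / (lx[idx + 1L] - lx[idx])
  exp(ly[idx] + slope * (lo - lx[idx]))
}
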