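# internal helpers shared across the package

# Run `code` with a temporarily seeded RNG, restoring the caller's stream.
# seed = NULL runs in the current stream (still deterministic if the caller
# seeded it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single number or NULL", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be a single number", name)
  if (strict && x <= lower) stopf("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict && x < lower) stopf("`%s` must be >= %g (got %g)", name, lower, x)
  invisible(x)
}

# Merge a set of half-open intervals [start, end); touching intervals coalesce.
merge_intervals <- function(start, end, reason = NULL) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      reason = character(0), stringsAsFactors = FALSE))
  if (is.null(reason)) reason <- rep("artifact", length(start))
  o <- order(start, end)
  start <- start[o]; end <- end[o]; reason <- reason[o]
  ms <- start[1]; me <- end[1]; mr <- reason[1]
  out_s <- numeric(0); out_e <- numeric(0); out_r <- character(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
      if (!grepl(reason[i], mr, fixed = TRUE)) mr <- paste(mr, reason[i], sep = "+")
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me); out_r <- c(out_r, mr)
      ms <- start[i]; me <- end[i]; mr <- reason[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me); out_r <- c(out_r, mr)
  data.frame(start_s = out_s, end_s = out_e, reason = out_r,
             stringsAsFactors = FALSE)
}
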