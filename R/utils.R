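# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded components do not perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
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
  })
  set.seed(as.integer(seed))
  expr
}

# Stable small integer hash of a participant id, used to derive per-target
# learner seeds from one experiment seed. Kept below 2^31 when added to any
# sane base seed.
id_hash <- function(id) {
  codes <- utf8ToInt(as.character(id))
  as.integer(sum(codes * seq_along(codes)) %% 100000L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Monday on or before the earliest date; weeks are Monday-Sunday.
week_origin <- function(dates) {
  d0 <- min(dates, na.rm = TRUE)
  # POSIXlt wday: 0 = Sunday ... 6 = Saturday
  wd <- as.POSIXlt(d0)$wday
  d0 - ((wd + 6L) %% 7L)
}

# 1-based Monday-Sunday week index relative to a start date.
week_of <- function(dates, start_date) {
  as.integer(as.numeric(dates - start_date) %/% 7) + 1L
}
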