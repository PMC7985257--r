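# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stage-specific child seed from a global seed. Kept below 2^31 so it
# is always a valid R integer seed.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + offset * 16807) %% 2147483399) + 1L
}

# Explicit not-a-value marker for mathematically undefined results. Operations
# returning it always emit a warning; they never silently coerce to 0.
undefined_value <- function(reason) {
  warning(reason, call. = FALSE)
  NA_real_
}

is_undefined <- function(x) is.na(x)

# Stage logging used by the pipeline; writes to stderr so results streams stay
# clean.
nw_log <- function(stage, ...) {
  if (isTRUE(getOption("nestweb.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = "")))
}

# Validate a numeric matrix of non-negative integer counts; `what` names the
# object in error messages. Returns the matrix with integer storage.
check_count_matrix <- function(x, what = "counts") {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x))
    stop(what, " must be numeric", call. = FALSE)
  bad <- which(is.na(x) | x < 0 | abs(x - round(x)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rn <- rownames(x)[bad[1, 1]]
    cn <- colnames(x)[bad[1, 2]]
    stop(sprintf("%s contains a negative or non-integer value at row '%s', column '%s'",
                 what,
                 if (is.null(rn)) bad[1, 1] else rn,
                 if (is.null(cn)) bad[1, 2] else cn), call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}
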