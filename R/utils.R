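#' @keywords internal
"_PACKAGE"

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

VALID_BASES <- c("A", "C", "G", "T")

# Degree-class labels, ordered from least to most related.
CLASS_LABELS <- c("unrelated", "second_or_third_degree", "second_degree",
                  "first_degree")

`%||%` <- function(a, b) if (is.null(a)) b else a
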