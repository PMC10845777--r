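# Internal argument checks shared across modules.

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "no2burden_invalid_argument")
  }
  as.integer(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  ok <- length(x) == 1L && is.numeric(x) && is.finite(x) &&
    (if (allow_lower) x >= lower else x > lower) &&
    (if (allow_upper) x <= upper else x < upper)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number in the stated range.", name),
          class = "no2burden_invalid_argument")
  }
  as.numeric(x)
}

invalid_argument <- function(msg) {
  abort(msg, class = "no2burden_invalid_argument")
}

# Deterministic per-county substreams: draw one seed per county from the
# master seed so dropping a county never shifts another county's draws.
county_seeds <- function(seed, n) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
    set.seed(seed)
    expr
  }
  withr_seed(sample.int(.Machine$integer.max - 1L, n))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  force(expr)
}
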