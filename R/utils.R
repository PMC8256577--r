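# internal utilities -----------------------------------------------------

`%||%` <- function(x, y) if (is.null(x)) y else x

# All package errors carry a subclass so callers (and tests) can condition
# on the failure mode rather than on message text.
fl_stop <- function(fmt, ..., class = "fl_error", data = NULL) {
  cond <- errorCondition(sprintf(fmt, ...),
                         class = c(class, "fl_error", "error", "condition"))
  if (!is.null(data)) {
    for (nm in names(data)) cond[[nm]] <- data[[nm]]
  }
  stop(cond)
}

# Derive a reproducible sub-seed from a top-level seed and a stage label.
# Every random stage in the package draws its seed this way, so one integer
# pins down the whole study. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h * 9973) %% 2147483647)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

pair_sep <- "\x1f"

pair_keys <- function(id_a, id_b) paste(id_a, id_b, sep = pair_sep)
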