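# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
local_seed <- function(seed, code) {
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
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_posticu <- function(msg, class) {
  rlang::abort(msg, class = paste0("posticu_", class))
}

assert_prob_labels <- function(scores, labels, require_both = TRUE) {
  if (length(scores) != length(labels)) {
    stop_posticu("`scores` and `labels` must have equal length.", "input")
  }
  if (anyNA(scores) || anyNA(labels)) {
    stop_posticu("`scores` and `labels` must not contain missing values.", "input")
  }
  if (!all(labels %in% c(0, 1))) {
    stop_posticu("`labels` must be binary 0/1.", "input")
  }
  if (require_both && (sum(labels) == 0L || sum(labels) == length(labels))) {
    stop_posticu("both outcome classes must be present.", "degenerate")
  }
  invisible(TRUE)
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}
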