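# Internal helpers shared across modules.

# largest-remainder apportionment of `total` into parts proportional to `w`,
# each part capped by `cap`. Guarantees sum(result) == total when total <= sum(cap).
apportion_counts <- function(total, w, cap) {
  stopifnot(total <= sum(cap))
  if (total == 0) return(rep(0L, length(w)))
  if (sum(w) == 0) w <- cap
  raw <- total * w / sum(w)
  out <- pmin(floor(raw), cap)
  rem <- total - sum(out)
  # distribute the remainder by largest fractional part among uncapped parts
  while (rem > 0) {
    frac <- raw - floor(raw)
    frac[out >= cap] <- -Inf
    i <- which.max(frac)
    if (!is.finite(frac[i])) {
      i <- which(out < cap)[1]
    }
    out[i] <- out[i] + 1L
    raw[i] <- floor(raw[i]) # consume its fractional part
    rem <- rem - 1L
  }
  as.integer(out)
}

# column-wise standardization with recorded statistics; zero-sd columns flagged
standardize_columns <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, sd)
  }
  keep <- scale > 0
  z <- sweep(x, 2, center, "-")
  z <- sweep(z, 2, ifelse(keep, scale, 1), "/")
  list(z = z, center = center, scale = scale, nonzero = keep)
}

# deterministic per-stage seed derivation from a single pipeline seed
derive_seed <- function(seed, stage_index) {
  (as.integer(seed) + 1013L * as.integer(stage_index)) %% 2147483647L
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}
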