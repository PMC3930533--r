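#' @keywords internal
"_PACKAGE"

# Fixed base order shared by every association matrix and bootstrap row.
BASES <- c("A", "C", "G", "T")

# Deterministic sub-seed derivation: one user-facing seed fans out into
# independent streams (kept below 2^31 - 1, R's integer ceiling).
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 100003 + stream * 7919 + 1) %% 2147483629)
}

# Nearest-rank empirical percentile: the q-th value of the sorted sample,
# index ceiling(q * n), clamped to [1, n].
pctile_nearest_rank <- function(x, q) {
  n <- length(x)
  sort(x)[pmin(pmax(ceiling(q * n), 1L), n)]
}

# Replace a base with one of the three others, chosen by a uniform draw
# u in [0,1). Vectorised over `base` and `u`.
other_base <- function(base, u) {
  idx <- match(base, BASES)
  shift <- 1L + as.integer(floor(u * 3))      # 1..3
  BASES[((idx - 1L + shift) %% 4L) + 1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
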