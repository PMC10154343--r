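# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

# population standard deviation (divisor n); detector templates and
# cochleagram windows are normalized with this convention throughout
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# deterministic sub-seed derivation; stays within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e7) * 97 + 7919 * (offset %% 1e4) + 1) %% 2147483645L + 1L
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# mutual information (bits) between two binary vectors, from the empirical
# 2x2 joint distribution; 0 log 0 taken as 0
mi_binary <- function(a, b) {
  n <- length(a)
  n11 <- sum(a & b); n10 <- sum(a & !b)
  n01 <- sum(!a & b); n00 <- n - n11 - n10 - n01
  counts <- c(n11, n10, n01, n00)
  p <- counts / n
  pa <- c(sum(p[1:2]), sum(p[3:4]))   # marginal of a
  pb <- c(p[1] + p[3], p[2] + p[4])   # marginal of b
  pe <- c(pa[1] * pb[1], pa[1] * pb[2], pa[2] * pb[1], pa[2] * pb[2])
  keep <- p > 0
  sum(p[keep] * log2(p[keep] / pe[keep]))
}
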