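# Small deterministic fixtures shared across test files.

# 3-gene x 4-sample log2 expression matrix over two stages
tiny_expr <- function() {
  m <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,
                5, 5, 5, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("n1", "n2", "t1", "t2")))
  m
}

tiny_manifest <- function() {
  sample_manifest(c("n1", "n2", "t1", "t2"),
                  c("normal", "normal", "tumor", "tumor"))
}

# random symmetric positive-definite matrix
random_pd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + diag(n) * 0.5
}

# path graph 1-2-3-4 plus pendant 5-2 (mirrors a small basic network with
# a leaf whose local network is just itself and its single neighbor)
toy_graph <- function() {
  clean_graph(data.frame(a = c("1", "2", "3", "2"),
                         b = c("2", "3", "4", "5"),
                         taxon = NA_character_))
}

# exhaustive two-sided rank-sum p-value by enumerating all group labelings
rank_sum_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">"))
  }
  u_obs <- sum(outer(x, y, ">"))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  mid <- n1 * n2 / 2
  mean(abs(us - mid) >= abs(u_obs - mid))
}

# brute-force Benjamini-Hochberg: adj_i = min over j with p_(j) >= p_i of
# min(1, m * p_(j) / rank_j), evaluated straight from the definition
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}
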