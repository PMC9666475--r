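# shared fixtures, built in code at test time

# small rectangular nest (60 x 40 mm, 4 mm body length) with a circular
# brood pile on the left and the entrance mid-right
toy_nest <- function(brood = TRUE) {
  br <- NULL
  if (brood) {
    th <- seq(0, 2 * pi, length.out = 17)[-17]
    br <- cbind(16 + 7 * cos(th), 20 + 7 * sin(th))
  }
  rect_nest(60, 40, 4, brood = br)
}

toy_grid <- function(nest = toy_nest()) build_hex_grid(nest)

# deterministic block-structured bipartite counts: `k` diagonal blocks of
# workers x sites with heavy within-block weight and light noise
block_counts <- function(k = 2, workers_per = 3, sites_per = 4,
                         within = 6L, noise = 0L, seed = 1) {
  set.seed(seed)
  nr <- k * workers_per; nc <- k * sites_per
  W <- matrix(rpois(nr * nc, noise), nr, nc)
  for (b in seq_len(k) - 1)
    W[b * workers_per + seq_len(workers_per),
      b * sites_per + seq_len(sites_per)] <-
      matrix(rpois(workers_per * sites_per, within) + 1L, workers_per)
  dimnames(W) <- list(paste0("w", seq_len(nr)), paste0("s", seq_len(nc)))
  W
}

# enumerate all set partitions of 1..n (list of integer label vectors)
set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in set_partitions(n - 1)) {
    k <- max(p)
    for (m in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, m)
  }
  out
}

# exhaustive maximum Barber modularity: enumerate worker set partitions,
# assign each site optimally (or to its own empty module, contributing 0)
exhaustive_max_q <- function(W) {
  Ftot <- sum(W); k <- rowSums(W); d <- colSums(W)
  best <- -Inf
  for (gw in set_partitions(nrow(W))) {
    K <- as.vector(rowsum(k, gw))
    A <- rowsum(W, gw)
    C <- A - (K %o% d) / Ftot
    q <- sum(pmax(0, apply(C, 2, max))) / Ftot
    if (q > best) best <- q
  }
  best
}

# independent dense evaluation of Barber modularity (double loop)
dense_q <- function(W, gw, gs) {
  Ftot <- sum(W); k <- rowSums(W); d <- colSums(W)
  q <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W)))
    if (gw[i] == gs[j]) q <- q + W[i, j] - k[i] * d[j] / Ftot
  unname(q / Ftot)
}

# tiny planted colony for end-to-end tests (fast: ~2 s)
tiny_colony <- function(seed = 1, duration_s = 3600,
                        mechanisms = c(fpa = FALSE, la = TRUE, be = TRUE),
                        n_workers = c(N = 6, I = 3, P = 3, F = 6)) {
  make_planted_colony(planted_colony_spec(
    n_workers = n_workers, duration_s = duration_s,
    mechanisms = mechanisms, seed = seed))
}
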