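#' Barber modularity of a bipartite partition
#'
#' Weighted bipartite modularity
#' \deqn{Q = \frac{1}{F}\sum_{i,s}\left(A_{is} - \frac{k_i d_s}{F}\right)
#'       \delta(g_i, g_s)}
#' where \eqn{A} is the worker-by-site weight matrix, \eqn{F} its total
#' weight, \eqn{k_i}/\eqn{d_s} the node margins and \eqn{g} the module
#' assignment. All nodes in one module give \eqn{Q = 0}; \eqn{Q \le 1}.
#'
#' @param network a `site_visit_network`.
#' @param partition a `bipartite_partition`, or a list with integer label
#'   vectors `workers` and `sites` (named, or ordered as in the network).
#' @return numeric modularity score.
#' @export
barber_modularity <- function(network, partition) {
  W <- network$weights
  gw <- .part_labels(partition$workers, network$workers)
  gs <- .part_labels(partition$sites, network$sites)
  .barber_q(W, gw, gs, rowSums(W), colSums(W), sum(W))
}

.part_labels <- function(lab, nodes) {
  if (!is.null(names(lab))) {
    if (!all(nodes %in% names(lab)))
      stop("partition does not cover all network nodes")
    lab <- lab[nodes]
  } else if (length(lab) != length(nodes)) {
    stop("partition does not cover all network nodes")
  }
  as.integer(lab)
}

# aggregate matrix rows by integer group onto the full label set `labs`
.agg_rows <- function(W, g, labs) {
  out <- matrix(0, length(labs), ncol(W))
  rs <- rowsum(W, g)
  out[match(as.integer(rownames(rs)), labs), ] <- rs
  out
}

.agg_vec <- function(v, g, labs) {
  out <- numeric(length(labs))
  rs <- rowsum(v, g)
  out[match(as.integer(rownames(rs)), labs)] <- rs
  out
}

.barber_q <- function(W, gw, gs, k, d, Ftot) {
  labs <- sort(unique(c(gw, gs)))
  Mw <- .agg_rows(W, gw, labs)                   # labs x sites
  Ms <- .agg_rows(t(Mw), gs, labs)               # labs(site) x labs(worker)
  within <- sum(diag(Ms))
  K <- .agg_vec(k, gw, labs)
  D <- .agg_vec(d, gs, labs)
  (within - sum(K * D) / Ftot) / Ftot
}

# one stochastic label-propagation run; returns list(gw, gs, Q).
# Q of the returned partition never decreases along the run's trace.
.lpawb_once <- function(W, gw0, max_iter = 200L) {
  r <- nrow(W)
  k <- rowSums(W); d <- colSums(W); Ftot <- sum(W)
  propagate <- function(gw) {
    best <- NULL
    for (iter in seq_len(max_iter)) {
      labs <- sort(unique(gw))
      M <- .agg_rows(W, gw, labs)
      K <- .agg_vec(k, gw, labs)
      S <- M - (K %o% d) / Ftot
      gs <- labs[max.col(t(S), ties.method = "random")]
      labs2 <- sort(unique(gs))
      N <- .agg_rows(t(W), gs, labs2)
      D <- .agg_vec(d, gs, labs2)
      S2 <- N - (D %o% k) / Ftot
      gw_new <- labs2[max.col(t(S2), ties.method = "random")]
      Q <- .barber_q(W, gw_new, gs, k, d, Ftot)
      if (!is.null(best) && Q <= best$Q + 1e-12) return(best)
      best <- list(gw = gw_new, gs = gs, Q = Q)
      gw <- gw_new
    }
    best
  }
  st <- propagate(gw0)
  # agglomerative phase: merge the best module pair while Q improves,
  # re-propagating labels after each accepted merge
  repeat {
    gw <- st$gw; gs <- st$gs
    labs <- sort(unique(c(gw, gs)))
    if (length(labs) < 2) break
    Mw <- .agg_rows(W, gw, labs)
    B <- .agg_rows(t(Mw), gs, labs)              # site-module x worker-module
    K <- .agg_vec(k, gw, labs)
    D <- .agg_vec(d, gs, labs)
    dQ <- (B + t(B) - (K %o% D + D %o% K) / Ftot) / Ftot
    diag(dQ) <- -Inf
    best_pair <- which(dQ == max(dQ), arr.ind = TRUE)[1, ]
    if (dQ[best_pair[1], best_pair[2]] <= 1e-12) break
    a <- labs[best_pair[1]]; b <- labs[best_pair[2]]
    gw[gw == b] <- a; gs[gs == b] <- a
    Qm <- .barber_q(W, gw, gs, k, d, Ftot)
    st2 <- propagate(gw)
    st <- if (st2$Q >= Qm) st2 else list(gw = gw, gs = gs, Q = Qm)
  }
  st
}

#' Partition a site-visit network by stochastic label propagation
#'
#' Weighted bipartite community detection maximising Barber modularity:
#' stochastic label propagation from randomised initialisations followed
#' by agglomerative module merging, repeated over several restarts,
#' keeping the best partition found. The number of modules is not fixed a
#' priori. Ties between equal-gain labels are broken uniformly at random
#' from the seeded stream, so repeated calls with the same seed are
#' identical.
#'
#' @param network a `site_visit_network`.
#' @param seed integer seed (local to this call).
#' @param restarts number of randomised restarts (default 20). The first
#'   restart initialises every worker with a unique label; later restarts
#'   draw random initial label counts.
#' @return Object of class `bipartite_partition`: named integer module
#'   labels for `workers` and `sites` (dense, starting at 1), the
#'   modularity `Q` and `n_modules`.
#' @export
dirt_lpawb_plus <- function(network, seed = 1L, restarts = 20L) {
  W <- network$weights
  if (length(W) == 0) stop("empty network")
  rs <- .local_rng(seed)
  on.exit(.restore_rng(rs))
  r <- nrow(W)
  best <- NULL
  first_mods <- r
  for (it in seq_len(max(1L, restarts))) {
    gw0 <- if (it == 1L) seq_len(r) else {
      cmax <- max(2L, min(r, first_mods + 2L))
      cc <- if (cmax <= 2L) 2L else sample(2:cmax, 1L)
      sample.int(cc, r, replace = TRUE)
    }
    st <- .lpawb_once(W, gw0)
    if (it == 1L) first_mods <- length(unique(c(st$gw, st$gs)))
    if (is.null(best) || st$Q > best$Q + 1e-12) best <- st
  }
  labs <- sort(unique(c(best$gw, best$gs)))
  gw <- match(best$gw, labs); gs <- match(best$gs, labs)
  structure(list(workers = stats::setNames(gw, network$workers),
                 sites = stats::setNames(gs, network$sites),
                 Q = best$Q, n_modules = length(labs)),
            class = "bipartite_partition")
}

#' @export
print.bipartite_partition <- function(x, ...) {
  cat(sprintf(
    "Bipartite partition: %d modules, Q = %.4f (%d workers, %d sites)\n",
    x$n_modules, x$Q, length(x$workers), length(x$sites)))
  invisible(x)
}

#' Modularity significance against the margin-preserving null
#'
#' Compares the maximised modularity of the observed network with the
#' maximised modularity of margin-preserving null networks
#' ([permute_null()]). The empirical p-value is
#' \eqn{p = (1 + \#\{Q_{null} \ge Q_{obs}\}) / (n_{null} + 1)}.
#'
#' @param network a `site_visit_network`.
#' @param n_null number of null networks (default 1000).
#' @param seed integer master seed.
#' @param restarts optimiser restarts per network (applied to the observed
#'   and every null network alike).
#' @return list with `Q_obs`, `Q_null` (numeric vector), `p`.
#' @export
modularity_significance <- function(network, n_null = 1000L, seed = 1L,
                                    restarts = 5L) {
  if (n_null < 1) stop("n_null must be >= 1")
  Q_obs <- dirt_lpawb_plus(network, seed = .derive_seed(seed, 0L),
                           restarts = restarts)$Q
  Q_null <- vapply(seq_len(n_null), function(i) {
    nn <- permute_null(network, seed = .derive_seed(seed, 2L * i))
    dirt_lpawb_plus(nn, seed = .derive_seed(seed, 2L * i + 1L),
                    restarts = restarts)$Q
  }, numeric(1))
  list(Q_obs = Q_obs, Q_null = Q_null,
       p = (1 + sum(Q_null >= Q_obs)) / (n_null + 1))
}

# per-stage/per-iteration seed derivation: multiplicative congruential
# step keeps derived seeds in 1 .. 2^31-1, reproducible from (master, i)
.derive_seed <- function(seed, i) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + as.numeric(i) * 16807 + 1) %% m
  as.integer(s + 1)
}
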