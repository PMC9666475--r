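#' Weighted bipartite site-visit network
#'
#' Wraps a nonnegative integer worker-by-site visit-count matrix as a
#' bipartite network. Isolated nodes (zero row or column margin) are
#' dropped: they carry no information for partitioning.
#'
#' @param counts integer matrix of visit counts with worker row names and
#'   site column names (as from [count_visits()]).
#' @return Object of class `site_visit_network`: list with `weights`
#'   (matrix), `workers`, `sites` (node name vectors).
#' @export
build_network <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0 || sum(counts) == 0)
    stop("empty visit-count matrix")
  if (any(counts < 0)) stop("visit counts must be nonnegative")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("w", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  structure(list(weights = counts,
                 workers = rownames(counts),
                 sites = colnames(counts)),
            class = "site_visit_network")
}

#' @export
print.site_visit_network <- function(x, ...) {
  cat(sprintf(
    "Site-visit network: %d workers x %d sites, %d edges, total weight %d\n",
    length(x$workers), length(x$sites), sum(x$weights > 0),
    sum(x$weights)))
  invisible(x)
}

#' Node margins
#' @param network a `site_visit_network`.
#' @return list with `workers` (row sums) and `sites` (column sums).
#' @export
network_margins <- function(network) {
  list(workers = rowSums(network$weights),
       sites = colSums(network$weights))
}

#' Serialize / read a network as a sorted edge list
#'
#' Tab-separated `worker_id`, `site_id`, `weight`, sorted lexicographically
#' so round trips are bit-identical.
#'
#' @param network a `site_visit_network`.
#' @param path file path.
#' @export
write_network_tsv <- function(network, path) {
  idx <- which(network$weights > 0, arr.ind = TRUE)
  df <- data.frame(worker_id = network$workers[idx[, 1]],
                   site_id = network$sites[idx[, 2]],
                   weight = network$weights[idx])
  df <- df[order(df$worker_id, df$site_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "integer"))
  w <- sort(unique(df$worker_id)); s <- sort(unique(df$site_id))
  m <- matrix(0L, length(w), length(s), dimnames = list(w, s))
  m[cbind(match(df$worker_id, w), match(df$site_id, s))] <- df$weight
  build_network(m)
}

#' Rarefy a site-visit network
#'
#' Subsamples the network to a target number of workers (uniformly,
#' without replacement) and then to a target total weight by subsampling
#' individual visit events without replacement. Used to check that
#' between-colony comparisons are not artefacts of network size.
#'
#' @param network a `site_visit_network`.
#' @param target_workers number of workers to keep.
#' @param target_total_weight total number of visit events to keep.
#' @param seed integer seed (local to this call).
#' @return a rarefied `site_visit_network`.
#' @export
rarefy_network <- function(network, target_workers, target_total_weight,
                           seed = 1L) {
  W <- network$weights
  if (target_workers > nrow(W))
    stop("target_workers exceeds available workers")
  rs <- .local_rng(seed)
  keep <- sort(sample.int(nrow(W), target_workers))
  W <- W[keep, , drop = FALSE]
  total <- sum(W)
  if (target_total_weight > total)
    stop("target_total_weight exceeds available weight after worker subsampling")
  if (target_total_weight < total) {
    # expand to individual events, subsample, recount
    cell <- rep.int(seq_along(W), as.vector(W))
    kept <- sample(cell, target_total_weight, replace = FALSE)
    Wnew <- array(0L, dim = dim(W), dimnames = dimnames(W))
    tab <- table(kept)
    Wnew[as.integer(names(tab))] <- as.integer(tab)
    W <- Wnew
  }
  .restore_rng(rs)
  build_network(W)
}

#' Margin-preserving null network
#'
#' Draws a random worker-by-site table with exactly the same worker and
#' site margins (and hence total weight) as the observed network, by
#' margin-preserving randomisation of individual visit events (Patefield's
#' algorithm, via [stats::r2dtable()]). This is the null ensemble used to
#' test modularity significance.
#'
#' @param network a `site_visit_network`.
#' @param seed integer seed (local to this call).
#' @return a `site_visit_network` with identical margins.
#' @export
permute_null <- function(network, seed = 1L) {
  m <- network_margins(network)
  if (length(m$workers) == 1L || length(m$sites) == 1L)
    return(network)   # a single row or column is fixed by its margins
  rs <- .local_rng(seed)
  W <- stats::r2dtable(1, as.integer(round(m$workers)),
                       as.integer(round(m$sites)))[[1]]
  .restore_rng(rs)
  dimnames(W) <- dimnames(network$weights)
  out <- network
  out$weights <- W
  out
}

# run code under a locally-seeded RNG, restoring global state afterwards
.local_rng <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(has = has, old = old)
}

.restore_rng <- function(state) {
  if (state$has) assign(".Random.seed", state$old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
  invisible(NULL)
}
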