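#' Run a stochastic partition ensemble
#'
#' Applies [dirt_lpawb_plus()] to the network `n_runs` times with
#' independent derived seeds, producing an ensemble of slightly different
#' partitions whose variation defines the fuzzy module scores.
#'
#' @param network a `site_visit_network`.
#' @param n_runs ensemble size (default 1000).
#' @param seed integer master seed; run `i` uses a seed derived from
#'   `(seed, i)`.
#' @param restarts restarts per run passed to [dirt_lpawb_plus()].
#' @return Object of class `partition_ensemble`: list of
#'   `bipartite_partition`s plus the module-count tabulation.
#' @export
run_ensemble <- function(network, n_runs = 1000L, seed = 1L, restarts = 20L) {
  parts <- lapply(seq_len(n_runs), function(i)
    dirt_lpawb_plus(network, seed = .derive_seed(seed, i),
                    restarts = restarts))
  structure(list(partitions = parts, n_runs = n_runs, seed = seed),
            class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  k <- vapply(x$partitions, `[[`, integer(1), "n_modules")
  cat(sprintf("Partition ensemble: %d runs; module counts: %s; %d unique partitions\n",
              x$n_runs,
              paste(sprintf("%d x%d", as.integer(names(table(k))), table(k)),
                    collapse = ", "),
              length(unique(partition_signatures(x)))))
  invisible(x)
}

#' Module-count distribution of an ensemble
#' @param ensemble a `partition_ensemble`.
#' @return table of module counts across runs.
#' @export
module_count_table <- function(ensemble) {
  table(vapply(ensemble$partitions, `[[`, integer(1), "n_modules"))
}

#' Canonical signatures identifying duplicate partitions
#'
#' Two partitions are duplicates when they induce the same grouping of
#' nodes, up to relabelling of module indices. The signature relabels
#' modules by first occurrence over the concatenated worker+site
#' assignment.
#'
#' @param ensemble a `partition_ensemble`.
#' @return character vector of signatures, one per run.
#' @export
partition_signatures <- function(ensemble) {
  vapply(ensemble$partitions, function(p) {
    g <- c(p$workers, p$sites)
    paste(match(g, unique(g)), collapse = ",")
  }, character(1))
}

#' Functionally label the modules of one partition
#'
#' Applies the fixed labelling rules: the module whose sites are on
#' average closest to the nest entrance is the forager module ("F"); the
#' module (or, in two-sided nests, the two modules) with the greatest
#' fractional overlap of member-site area with the brood outline are the
#' nurse module(s) ("N", or "N1"/"N2" by comb face); of the remaining
#' modules, one leftover is peripheral ("P"); with two leftovers the one
#' whose sites lie on average nearer the nest walls is peripheral and the
#' other intermediate ("I"); any further (supernumerary, typically
#' 1-2-worker) modules are left unclassified ("U"), as are modules with no
#' member sites.
#'
#' @param partition a `bipartite_partition`.
#' @param grid the `hex_grid` whose site ids appear in the partition.
#' @param nest the [nest_geometry()]; must carry a brood outline.
#' @param two_nurse allow two nurse modules (default: nests with two comb
#'   faces).
#' @return character vector of functional labels indexed by module.
#' @export
label_partition <- function(partition, grid, nest,
                            two_nurse = nest$sides == 2L) {
  if (is.null(nest$brood))
    stop("nurse labelling requires a brood outline in the nest geometry")
  K <- partition$n_modules
  site_ids <- as.integer(names(partition$sites))
  lab <- rep("U", K)
  msites <- split(site_ids, partition$sites)
  mworkers <- table(factor(partition$workers, levels = seq_len(K)))
  has_sites <- as.character(seq_len(K)) %in% names(msites)

  d_ent <- distance_to_feature(grid, nest, "entrance", sites = site_ids)
  ctr <- site_centers(grid, site_ids)
  in_brood <- .points_in_polygon(ctr[, 1], ctr[, 2], nest$brood)
  d_wall <- distance_to_feature(grid, nest, "wall", sites = site_ids)
  mean_by <- function(v) vapply(seq_len(K), function(m) {
    s <- which(partition$sites == m)
    if (length(s) == 0) NA_real_ else mean(v[s])
  }, numeric(1))
  ment <- mean_by(d_ent)
  mbrood <- mean_by(as.numeric(in_brood))   # fractional overlap with brood
  mwall <- mean_by(d_wall)

  elig <- which(has_sites)
  if (length(elig) == 0) stop("partition has no modules with member sites")
  forager <- elig[which.min(ment[elig])]
  lab[forager] <- "F"
  rest <- setdiff(elig, forager)
  if (length(rest) > 0) {
    ov <- mbrood[rest]
    if (two_nurse && length(rest) >= 2 && sum(ov > 0) >= 2) {
      top2 <- rest[order(ov, decreasing = TRUE)[1:2]]
      side_mean <- vapply(top2, function(m) {
        s <- site_ids[partition$sites == m]
        mean(site_side(grid, s))
      }, numeric(1))
      lab[top2[order(side_mean)]] <- c("N1", "N2")
      rest <- setdiff(rest, top2)
    } else {
      nurse <- rest[which.max(ov)]
      if (max(ov) == 0)   # no member site inside the brood: fall back to distance
        nurse <- rest[which.min(mean_by(
          distance_to_feature(grid, nest, "brood", sites = site_ids))[rest])]
      lab[nurse] <- "N"
      rest <- setdiff(rest, nurse)
    }
  }
  if (length(rest) == 1) {
    lab[rest] <- "P"
  } else if (length(rest) >= 2) {
    # keep the two largest worker groups; supernumerary modules unclassified
    sizes <- as.integer(mworkers[rest])
    big2 <- rest[order(sizes, decreasing = TRUE)[1:2]]
    lab[big2[which.min(mwall[big2])]] <- "P"
    lab[setdiff(big2, big2[which.min(mwall[big2])])] <- "I"
  }
  lab
}

#' Fuzzy module scores from a labelled ensemble
#'
#' For every node, the proportion of ensemble iterations assigning it to
#' each functionally labelled module. Iterations in which a node fell in
#' an unclassified module do not count toward that node's denominator;
#' scores are renormalised so each scored node's vector sums to 1.
#'
#' @param ensemble a `partition_ensemble`.
#' @param grid,nest geometry used for labelling (see [label_partition()]).
#' @param two_nurse allow two nurse modules (see [label_partition()]).
#' @param unique_partitions if `TRUE`, duplicate partitions (up to module
#'   relabelling) are counted once instead of once per iteration.
#' @return Object of class `module_scores`: matrices `workers` and
#'   `sites` (nodes x labels, rows sum to 1), the label set, per-node
#'   primary module, and the proportion of uncounted iterations per node.
#' @export
compute_scores <- function(ensemble, grid, nest,
                           two_nurse = nest$sides == 2L,
                           unique_partitions = FALSE) {
  parts <- ensemble$partitions
  wts <- rep(1, length(parts))
  if (unique_partitions) {
    sig <- partition_signatures(ensemble)
    wts <- as.numeric(!duplicated(sig))
  }
  labels_all <- c("N", "N1", "N2", "I", "P", "F")
  wnames <- names(parts[[1]]$workers)
  snames <- names(parts[[1]]$sites)
  accw <- matrix(0, length(wnames), length(labels_all),
                 dimnames = list(wnames, labels_all))
  accs <- matrix(0, length(snames), length(labels_all),
                 dimnames = list(snames, labels_all))
  unctw <- stats::setNames(numeric(length(wnames)), wnames)
  uncts <- stats::setNames(numeric(length(snames)), snames)
  denom <- 0
  for (j in seq_along(parts)) {
    if (wts[j] == 0) next
    p <- parts[[j]]
    lab <- label_partition(p, grid, nest, two_nurse = two_nurse)
    lw <- lab[p$workers]; ls <- lab[p$sites]
    for (L in labels_all) {
      accw[, L] <- accw[, L] + wts[j] * (lw == L)
      accs[, L] <- accs[, L] + wts[j] * (ls == L)
    }
    unctw <- unctw + wts[j] * (lw == "U")
    uncts <- uncts + wts[j] * (ls == "U")
    denom <- denom + wts[j]
  }
  used <- labels_all[colSums(accw) + colSums(accs) > 0]
  accw <- accw[, used, drop = FALSE]
  accs <- accs[, used, drop = FALSE]
  normalise <- function(m) {
    tot <- rowSums(m)
    m / ifelse(tot > 0, tot, NA)
  }
  sw <- normalise(accw); ss <- normalise(accs)
  structure(list(workers = sw, sites = ss, labels = used,
                 unclassified_workers = unctw / denom,
                 unclassified_sites = uncts / denom),
            class = "module_scores")
}

#' @export
print.module_scores <- function(x, ...) {
  cat(sprintf("Module scores: %d workers, %d sites; labels: %s\n",
              nrow(x$workers), nrow(x$sites),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Primary module of each node
#'
#' @param scores a `module_scores` object.
#' @param what "workers" or "sites".
#' @return character vector of labels (argmax of the score vector; `NA`
#'   for nodes never assigned to a classified module).
#' @export
primary_module <- function(scores, what = c("workers", "sites")) {
  m <- scores[[match.arg(what)]]
  out <- scores$labels[max.col(replace(m, is.na(m), -1),
                               ties.method = "first")]
  out[rowSums(is.na(m)) == ncol(m)] <- NA_character_
  stats::setNames(out, rownames(m))
}

#' Specialist workers and non-overlapping sites
#'
#' A specialist worker (or non-overlapping site) has exactly one nonzero
#' module score.
#'
#' @param scores a `module_scores` object.
#' @param tol scores below `tol` count as zero (default 0: exact).
#' @return list with `specialist_workers` and `nonoverlapping_sites`
#'   proportions.
#' @export
summarize_specialists <- function(scores, tol = 0) {
  spec <- function(m) {
    ok <- rowSums(is.na(m)) < ncol(m)
    mean(rowSums(m[ok, , drop = FALSE] > tol, na.rm = TRUE) == 1)
  }
  list(specialist_workers = spec(scores$workers),
       nonoverlapping_sites = spec(scores$sites))
}

#' Pool the two nurse modules into one
#'
#' Sums the "N1" and "N2" score columns into a single "N" column (used
#' for two-sided honeybee nests, where the two broodnest nurse modules are
#' treated as one group downstream). With fewer than two nurse columns the
#' scores are returned unchanged, with a warning.
#'
#' @param scores a `module_scores` object.
#' @return a `module_scores` object with pooled nurse scores.
#' @export
pool_nurse_modules <- function(scores) {
  nn <- intersect(c("N1", "N2"), scores$labels)
  if (length(nn) < 2) {
    warning("fewer than two nurse modules present; nothing to pool")
    return(scores)
  }
  pool <- function(m) {
    N <- rowSums(m[, nn, drop = FALSE])
    keep <- setdiff(colnames(m), nn)
    out <- cbind(N = N, m[, keep, drop = FALSE])
    out
  }
  scores$workers <- pool(scores$workers)
  scores$sites <- pool(scores$sites)
  scores$labels <- colnames(scores$workers)
  scores
}
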