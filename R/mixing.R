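#' Typical (weighted-average) module-score profile
#'
#' The weighted arithmetic mean of a set of module-score vectors, with
#' weights equal to visit counts (for the typical visitor of a site or the
#' typical site an individual visits) or contact counts (for the typical
#' contacted nestmate). Heavier visitors/sites/partners contribute
#' proportionally more.
#'
#' @param weights nonnegative numeric vector, one weight per contributing
#'   node; must have positive sum.
#' @param scores numeric matrix of score vectors, one row per contributing
#'   node.
#' @return numeric profile vector (named as the score columns).
#' @export
typical_profile <- function(weights, scores) {
  scores <- rbind(scores)
  if (length(weights) != nrow(scores))
    stop("one weight per score row required")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative with positive total")
  v <- as.vector(crossprod(scores, weights) / sum(weights))
  stats::setNames(v, colnames(scores))
}

#' Normalised entropy diversity of a score profile
#'
#' Shannon entropy of the profile divided by `log(n_categories)`, with
#' the convention 0 log 0 = 0. Ranges from 0 (all mass on one module:
#' e.g. a site visited only by specialists of a single module) to 1 (a
#' uniform mix over all modules).
#'
#' @param profile nonnegative profile vector (normalised to sum 1; small
#'   deviations are renormalised).
#' @param n_categories number of module categories defining the maximum
#'   entropy (default: profile length).
#' @return list with `D` (normalised diversity), `H` (entropy, nats) and
#'   `H_max`.
#' @export
score_diversity <- function(profile, n_categories = length(profile)) {
  p <- profile / sum(profile)
  H <- -sum(ifelse(p > 0, p * log(p), 0))
  H_max <- log(n_categories)
  list(D = if (H_max > 0) H / H_max else 0, H = H, H_max = H_max)
}

#' Cosine similarity between two module-score vectors
#'
#' \deqn{\cos_{i,s} = \sum_M M_i M_s / (\|M_i\| \|M_s\|)}. With
#' nonnegative scores the value ranges from 0 (orthogonal, fully
#' mismatched) to 1 (identical direction).
#'
#' @param a,b numeric score vectors of equal length, not all zero.
#' @return similarity in [0, 1].
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}

# row-wise cosine similarity between matched matrices
.cosine_rows <- function(A, B) {
  num <- rowSums(A * B)
  den <- sqrt(rowSums(A^2)) * sqrt(rowSums(B^2))
  ifelse(den > 0, num / den, NA_real_)
}

#' Per-site visitor diversity
#'
#' Module-score diversity of the typical visitor to each site: the
#' visit-weighted mean of the visitors' score vectors, passed through the
#' normalised entropy.
#'
#' @param network a `site_visit_network` (weights = visit counts).
#' @param scores a `module_scores` object (worker scores are used).
#' @param n_categories entropy normalisation (default: number of score
#'   labels).
#' @return named numeric vector of diversities, one per network site.
#' @export
visitor_diversity <- function(network, scores,
                              n_categories = length(scores$labels)) {
  W <- network$weights
  S <- scores$workers[network$workers, , drop = FALSE]
  ok <- rowSums(is.na(S)) == 0
  vapply(seq_along(network$sites), function(j) {
    w <- W[ok, j]
    if (sum(w) <= 0) return(NA_real_)
    score_diversity(typical_profile(w, S[ok, , drop = FALSE]),
                    n_categories)$D
  }, numeric(1)) -> d
  stats::setNames(d, network$sites)
}

#' Per-worker visited-site diversity
#'
#' @inheritParams visitor_diversity
#' @return named numeric vector of diversities, one per worker.
#' @export
visited_diversity <- function(network, scores,
                              n_categories = length(scores$labels)) {
  W <- network$weights
  S <- scores$sites[network$sites, , drop = FALSE]
  ok <- rowSums(is.na(S)) == 0
  vapply(seq_along(network$workers), function(i) {
    w <- W[i, ok]
    if (sum(w) <= 0) return(NA_real_)
    score_diversity(typical_profile(w, S[ok, , drop = FALSE]),
                    n_categories)$D
  }, numeric(1)) -> d
  stats::setNames(d, network$workers)
}

#' Per-worker contacted-nestmate diversity
#'
#' @param contacts symmetric matrix of pairwise contact counts with worker
#'   dimnames; self-contacts (the diagonal) are ignored.
#' @inheritParams visitor_diversity
#' @return named numeric vector of diversities, one per worker in
#'   `contacts`.
#' @export
contact_diversity <- function(contacts, scores,
                              n_categories = length(scores$labels)) {
  ids <- rownames(contacts)
  S <- scores$workers[ids, , drop = FALSE]
  vapply(seq_along(ids), function(i) {
    w <- contacts[i, ]; w[i] <- 0
    ok <- rowSums(is.na(S)) == 0
    w <- w * ok
    if (sum(w) <= 0) return(NA_real_)
    score_diversity(typical_profile(w[ok], S[ok, , drop = FALSE]),
                    n_categories)$D
  }, numeric(1)) -> d
  stats::setNames(d, ids)
}

#' Site covariate table
#'
#' One row per visited site: visitor diversity plus distances (in body
#' lengths) to the brood outline and nest entrance, for downstream group
#' contrasts.
#'
#' @param grid a `hex_grid`.
#' @param nest the matching [nest_geometry()].
#' @param network a `site_visit_network`.
#' @param scores a `module_scores` object.
#' @return data.frame with columns `site_id`, `visitor_diversity`,
#'   `d_brood_bl`, `d_entrance_bl`.
#' @export
site_covariates <- function(grid, nest, network, scores) {
  ids <- as.integer(network$sites)
  data.frame(
    site_id = ids,
    visitor_diversity = as.numeric(visitor_diversity(network, scores)),
    d_brood_bl = if (is.null(nest$brood)) NA_real_ else
      distance_to_feature(grid, nest, "brood", sites = ids),
    d_entrance_bl = distance_to_feature(grid, nest, "entrance", sites = ids))
}
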