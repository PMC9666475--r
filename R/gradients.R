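#' Fit module-score gradient fields by local spatial regression
#'
#' For every site and module, the site's module score is regressed on the
#' x and y coordinates of all site centres within `radius_bl` body
#' lengths of the focal centre (inclusive), giving the local plane
#' \eqn{M_s = a x + b y + c}. The vector \eqn{g = (a, b)} points up the
#' steepest local increase of the module score; its magnitude is the
#' transition steepness. Neighbourhoods with uniform scores give
#' magnitude 0 and an undefined direction; degenerate neighbourhoods
#' (fewer than 3 sites or collinear centres) are flagged the same way.
#'
#' @param site_scores numeric matrix, sites x modules (rows ordered by
#'   site id over the full grid, or use `sites`).
#' @param grid a `hex_grid`.
#' @param sites site ids corresponding to rows of `site_scores` (default:
#'   all grid sites).
#' @param radius_bl neighbourhood radius in body lengths (default 1).
#' @return Object of class `gradient_field`: matrices `gx`, `gy`, `mag`
#'   (sites x modules; zero where undefined), logical matrix `defined`,
#'   plus `sites` and module `labels`.
#' @export
fit_gradient_field <- function(site_scores, grid,
                               sites = seq_len(nrow(site_scores)),
                               radius_bl = 1) {
  site_scores <- as.matrix(site_scores)
  if (nrow(site_scores) != length(sites))
    stop("one score row per site required")
  ctr <- site_centers(grid, sites)
  sidev <- site_side(grid, sites)
  r <- radius_bl * grid$body_length
  nbr <- .radius_neighbours(ctr, sidev, r)
  nM <- ncol(site_scores)
  gx <- gy <- matrix(0, length(sites), nM,
                     dimnames = list(sites, colnames(site_scores)))
  defined <- matrix(FALSE, length(sites), nM)
  for (i in seq_along(sites)) {
    nb <- nbr[[i]]
    if (length(nb) < 3) next
    x <- ctr[nb, 1] - ctr[i, 1]; y <- ctr[nb, 2] - ctr[i, 2]
    X <- cbind(1, x, y)
    XtX <- crossprod(X)
    if (abs(det(XtX)) < 1e-10) next
    beta <- solve(XtX, crossprod(X, site_scores[nb, , drop = FALSE]))
    gx[i, ] <- beta[2, ]; gy[i, ] <- beta[3, ]
    defined[i, ] <- TRUE
  }
  mag <- sqrt(gx^2 + gy^2)
  # exactly-uniform neighbourhoods: magnitude 0, direction undefined
  defined <- defined & (mag > 1e-12)
  gx[!defined] <- 0; gy[!defined] <- 0; mag[!defined] <- 0
  structure(list(gx = gx, gy = gy, mag = mag, defined = defined,
                 sites = sites, labels = colnames(site_scores)),
            class = "gradient_field")
}

# neighbours within radius r on the same side, inclusive of self
.radius_neighbours <- function(ctr, sidev, r) {
  ord <- order(ctr[, 2])
  n <- nrow(ctr)
  out <- vector("list", n)
  ys <- ctr[ord, 2]
  for (ii in seq_len(n)) {
    i <- ord[ii]
    lo <- findInterval(ctr[i, 2] - r - 1e-9, ys)
    hi <- findInterval(ctr[i, 2] + r + 1e-9, ys)
    cand <- ord[(lo + 1):hi]
    cand <- cand[sidev[cand] == sidev[i]]
    d2 <- (ctr[cand, 1] - ctr[i, 1])^2 + (ctr[cand, 2] - ctr[i, 2])^2
    out[[i]] <- cand[d2 <= r^2 + 1e-9]
  }
  out
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("Gradient field: %d sites x %d modules; mean |g| = %.4g (defined sites)\n",
              nrow(x$gx), ncol(x$gx), mean(x$mag[x$defined])))
  invisible(x)
}

#' Classify headings as up- or down-gradient
#'
#' A segment heads up-gradient when the absolute angular difference
#' between its heading and the local gradient direction is smaller than
#' pi/2 (equivalently, positive dot product with g); otherwise (including
#' exactly pi/2) it heads down-gradient. Zero gradients give `NA`.
#'
#' @param heading numeric vector of segment headings (radians).
#' @param gx,gy gradient vector components at the segment locations.
#' @return character vector "up"/"down" (`NA` where the gradient is zero).
#' @export
classify_heading <- function(heading, gx, gy) {
  dot <- cos(heading) * gx + sin(heading) * gy
  # the pi/2 tie resolves to down; tolerance absorbs cos(pi/2) != 0
  out <- ifelse(dot > 1e-9 * sqrt(gx^2 + gy^2), "up", "down")
  out[gx == 0 & gy == 0] <- NA_character_
  out
}

#' Relative turn angles in the primary-module gradient field
#'
#' For each worker and site with a defined gradient in the worker's
#' primary-module field, the worker's mean unsigned active turn angle
#' minus the all-worker mean at the same site for the same
#' gradient-relative heading class:
#' \deqn{\Delta\theta^{down}_{i,s} = \bar\theta^{down}_{i,s,M_i} -
#'       \bar\theta^{down}_{s,M_i}}
#' and likewise up-gradient. Positive down-gradient values mean the
#' resident turns more than average when heading out of its module.
#'
#' @param activity an `activity_bouts` object (its active turns are used).
#' @param grid a `hex_grid`.
#' @param field a `gradient_field` over all grid sites.
#' @param primary named vector mapping worker id to primary module label
#'   (a column name of the field); with `NULL`, deviations are returned
#'   for every worker in every module's field (callers then select
#'   residents themselves).
#' @param min_turns minimum turns per (worker, site, direction) mean
#'   (default 1).
#' @return data.frame: `worker_id`, `site_id`, `module`, `direction`
#'   ("down"/"up"), `dtheta` (radians), `mag` (field steepness at the
#'   site), `n_turns`.
#' @export
relative_turn_angles <- function(activity, grid, field, primary = NULL,
                                 min_turns = 1L) {
  tr <- activity$turns
  tr <- tr[tr$active, , drop = FALSE]
  if (nrow(tr) == 0) return(data.frame())
  tr$site <- locate_site(grid, tr$x, tr$y, tr$side)
  tr <- tr[!is.na(tr$site), , drop = FALSE]
  tr$worker_id <- as.character(tr$worker_id)
  out <- NULL
  fsites <- field$sites
  for (M in colnames(field$gx)) {
    res_workers <- if (is.null(primary)) unique(tr$worker_id) else
      names(primary)[!is.na(primary) & primary == M]
    si <- match(tr$site, fsites)
    gx <- field$gx[si, M]; gy <- field$gy[si, M]
    def <- field$defined[si, M]
    dir <- classify_heading(tr$heading, gx, gy)
    ok <- def & !is.na(dir)
    d <- tr[ok, , drop = FALSE]
    d$dir <- dir[ok]
    if (nrow(d) == 0) next
    gsite <- paste(d$site, d$dir, sep = "\r")
    site_mean <- tapply(d$turn, gsite, mean)
    dres <- d[d$worker_id %in% res_workers, , drop = FALSE]
    if (nrow(dres) == 0) next
    gws <- paste(dres$worker_id, dres$site, dres$dir, sep = "\r")
    own <- tapply(dres$turn, gws, mean)
    nn <- tapply(dres$turn, gws, length)
    keep <- nn >= min_turns
    ids <- do.call(rbind, strsplit(names(own)[keep], "\r", fixed = TRUE))
    sid <- as.integer(ids[, 2])
    out <- rbind(out, data.frame(
      worker_id = ids[, 1], site_id = sid, module = M,
      direction = ids[, 3],
      dtheta = as.numeric(own[keep]) -
        as.numeric(site_mean[paste(sid, ids[, 3], sep = "\r")]),
      mag = field$mag[match(sid, fsites), M],
      n_turns = as.integer(nn[keep])))
  }
  if (is.null(out))
    out <- data.frame(worker_id = character(), site_id = integer(),
                      module = character(), direction = character(),
                      dtheta = numeric(), mag = numeric(),
                      n_turns = integer())
  rownames(out) <- NULL
  out
}

#' Steepness-binned means of relative turn angles
#'
#' Bins the relative-turn table into equal-count quantile bins of field
#' steepness (over records with positive steepness) and reports per-bin,
#' per-direction grand means with sign-flip permutation confidence
#' intervals; p-values are Benjamini-Hochberg corrected across bins and
#' directions.
#'
#' @param rel output of [relative_turn_angles()].
#' @param n_bins number of quantile bins (default 5).
#' @param n_perm sign-flip permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame per (bin, direction): `bin`, `mag_mid`,
#'   `direction`, `mean_dtheta`, `ci_lo`, `ci_hi` (null band), `p`,
#'   `p_bh`, `n`.
#' @export
steepness_binned_contrast <- function(rel, n_bins = 5L, n_perm = 1000L,
                                      seed = 1L) {
  rel <- rel[rel$mag > 0 & !is.na(rel$dtheta), , drop = FALSE]
  if (nrow(rel) == 0) return(data.frame())
  br <- unique(stats::quantile(rel$mag, probs = seq(0, 1, length.out =
                                                      n_bins + 1)))
  rel$bin <- cut(rel$mag, breaks = br, include.lowest = TRUE,
                 labels = FALSE)
  rs <- .local_rng(seed)
  on.exit(.restore_rng(rs))
  rows <- NULL
  for (b in sort(unique(rel$bin))) for (dir in c("down", "up")) {
    d <- rel[rel$bin == b & rel$direction == dir, , drop = FALSE]
    if (nrow(d) == 0) next
    obs <- mean(d$dtheta)
    perm <- vapply(seq_len(n_perm), function(i)
      mean(d$dtheta * sample(c(-1, 1), nrow(d), replace = TRUE)),
      numeric(1))
    rows <- rbind(rows, data.frame(
      bin = b, mag_mid = stats::median(d$mag), direction = dir,
      mean_dtheta = obs,
      ci_lo = stats::quantile(perm, 0.025, names = FALSE),
      ci_hi = stats::quantile(perm, 0.975, names = FALSE),
      p = (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1),
      n = nrow(d)))
  }
  if (!is.null(rows)) rows$p_bh <- stats::p.adjust(rows$p, method = "BH")
  rows
}
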