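# Scaled distance of a feature to its nearest domain boundary. The raw bp
# distance is divided by the size of the closest domain so that domains of
# very different sizes become comparable: 0.5 is the farthest possible point
# inside a domain (its center), 0 is the boundary, and -1 is the farthest
# retained point outside (one full domain length away); features farther out
# than one domain length are discarded from the analysis.

#' Scaled distance of features to domain boundaries
#'
#' For each feature midpoint the closest domain (on the same chromosome) is
#' found. Inside a domain the distance to the nearer boundary is divided by
#' that domain's size, giving a value in \[0, 0.5\]; outside, the distance to
#' the nearest boundary is divided by that domain's size and negated, and
#' features lying more than one domain length away are discarded (flagged,
#' not dropped). A feature exactly one domain length outside is retained
#' (scaled = -1). Features straddling a boundary are classified by their
#' midpoint. When an outside midpoint is equidistant from two domains the
#' upstream domain is used.
#'
#' @param features GRanges; the reference point is the feature midpoint.
#' @param domains domain_set (merged internally).
#' @return data.frame with one row per feature: `feature_id`, `chrom`,
#'   `domain_label`, `closest_start`, `closest_end` (0-based half-open),
#'   `raw_distance` (bp, positive inside / negative outside), `scaled`,
#'   `inside`, `retained`, `reason` (NA when retained).
#' @export
scaled_distance <- function(features, domains) {
  ds <- if (inherits(domains, "domain_set")) domains else
    domain_set(domains, label = "domains")
  gr <- sort(ds$ranges)
  dch <- as.character(seqnames(gr))
  ids <- if (is.null(names(features)))
    paste0("feature_", seq_along(features)) else names(features)
  fch <- as.character(seqnames(features))
  mid <- (start(features) - 1 + end(features)) / 2  # 0-based, may be x.5

  n <- length(features)
  out <- data.frame(feature_id = ids, chrom = fch,
                    domain_label = ds$label,
                    closest_start = NA_real_, closest_end = NA_real_,
                    raw_distance = NA_real_, scaled = NA_real_,
                    inside = NA, retained = FALSE,
                    reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (ch in unique(fch)) {
    fi <- which(fch == ch)
    di <- which(dch == ch)
    if (length(di) == 0) {
      out$reason[fi] <- "no_domain_on_chromosome"
      next
    }
    s0 <- start(gr)[di] - 1
    e0 <- end(gr)[di]
    b <- as.numeric(rbind(s0, e0))
    m <- mid[fi]
    j <- findInterval(m, b)
    k_in <- (j + 1) %/% 2            # domain index when inside
    inside <- j %% 2 == 1
    # outside points sitting exactly on an end boundary belong to that domain
    on_end <- !inside & j > 0 & m == b[pmax(j, 1)]
    inside <- inside | on_end
    k_in[on_end] <- j[on_end] %/% 2

    # inside features
    ii <- which(inside)
    if (length(ii)) {
      k <- k_in[ii]
      w <- e0[k] - s0[k]
      d <- pmin(m[ii] - s0[k], e0[k] - m[ii])
      rows <- fi[ii]
      out$closest_start[rows] <- s0[k]; out$closest_end[rows] <- e0[k]
      out$raw_distance[rows] <- d
      out$scaled[rows] <- d / w
      out$inside[rows] <- TRUE
      out$retained[rows] <- TRUE
    }
    # outside features: nearest of flanking domains
    oo <- which(!inside)
    if (length(oo)) {
      kl <- j[oo] %/% 2              # left domain index, 0 if none
      kr <- kl + 1                   # right domain index, may exceed n
      dl <- ifelse(kl >= 1, m[oo] - e0[pmax(kl, 1)], Inf)
      dr <- ifelse(kr <= length(s0), s0[pmin(kr, length(s0))] - m[oo], Inf)
      use_left <- dl <= dr           # tie -> upstream domain
      k <- ifelse(use_left, kl, kr)
      d <- ifelse(use_left, dl, dr)
      w <- e0[k] - s0[k]
      rows <- fi[oo]
      out$closest_start[rows] <- s0[k]; out$closest_end[rows] <- e0[k]
      out$raw_distance[rows] <- -d
      out$scaled[rows] <- -d / w
      out$inside[rows] <- FALSE
      keep <- d / w <= 1
      out$retained[rows] <- keep
      out$reason[rows[!keep]] <- "beyond_one_domain_size"
      out$scaled[rows[!keep]] <- NA_real_
    }
  }
  out
}

#' Analytic scaled-distance distribution under uniform placement
#'
#' Closed-form reference distribution of the scaled boundary distance when
#' feature midpoints are placed uniformly over the genome. Inside each
#' domain the scaled value is uniform with CDF `2t` on \[0, 0.5\]; each gap
#' splits at its midpoint between the flanking domains, contributing the
#' retained outside mass piecewise linearly on \[-1, 0\]. Used as an
#' independent check of [scaled_distance()].
#'
#' @param domains domain_set.
#' @return list with `cdf` (vectorized function of the scaled value,
#'   conditional on retention) and `retained_fraction` (probability that a
#'   uniformly placed midpoint is retained).
#' @export
scaled_distance_null_cdf <- function(domains) {
  ds <- if (inherits(domains, "domain_set")) domains else
    domain_set(domains, label = "domains")
  gr <- sort(ds$ranges)
  dch <- as.character(seqnames(gr))
  sl <- GenomeInfoDb::seqlengths(ds$assembly)
  # outside pieces: (m = retained measure, w = domain size); inside: widths
  piece_m <- numeric(0); piece_w <- numeric(0)
  in_w <- numeric(0)
  for (ch in GenomeInfoDb::seqnames(ds$assembly)) {
    di <- which(dch == ch)
    if (length(di) == 0) next
    s0 <- start(gr)[di] - 1; e0 <- end(gr)[di]
    w <- e0 - s0
    in_w <- c(in_w, w)
    L <- as.numeric(sl[ch])
    # start gap -> first domain only
    if (s0[1] > 0) {
      piece_m <- c(piece_m, min(s0[1], w[1])); piece_w <- c(piece_w, w[1])
    }
    # interior gaps -> split at midpoint between flanking domains
    if (length(di) > 1) {
      g <- s0[-1] - e0[-length(e0)]
      piece_m <- c(piece_m, pmin(g / 2, w[-length(w)]), pmin(g / 2, w[-1]))
      piece_w <- c(piece_w, w[-length(w)], w[-1])
    }
    # end gap -> last domain only
    if (e0[length(e0)] < L) {
      piece_m <- c(piece_m, min(L - e0[length(e0)], w[length(w)]))
      piece_w <- c(piece_w, w[length(w)])
    }
  }
  W <- sum(in_w)
  M <- W + sum(piece_m)
  G <- genome_size(ds$assembly)
  # mass(scaled <= t): for t <= 0 each outside piece contributes
  # max(0, m - |t| w) (the retained d-range beyond |t| w); for t > 0 each
  # domain adds min(2t, 1) of its width on top of the full outside mass.
  cdf <- function(t) {
    vapply(t, function(tt) {
      if (tt < -1) return(0)
      out_mass <- sum(pmax(0, piece_m - abs(min(tt, 0)) * piece_w))
      in_mass <- if (tt <= 0) 0 else sum(pmin(2 * tt, 1) * in_w)
      (out_mass + in_mass) / M
    }, numeric(1))
  }
  list(cdf = cdf, retained_fraction = M / G)
}

#' Rank-sum comparison of two scaled-distance samples
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test. Uses exact enumeration
#' for combined sample size <= 12 without ties and the tie-corrected normal
#' approximation otherwise.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @return list with `statistic` (the Mann-Whitney U of `group_a` over
#'   `group_b`), `p.value`, `method`, `n_a`, `n_b`.
#' @export
compare_distance_distributions <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  n <- length(group_a) + length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- n <= 12 && !ties
  ht <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = "two.sided",
                exact = exact, correct = !exact))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = if (exact) "exact" else "normal approximation (tie-corrected)",
       n_a = length(group_a), n_b = length(group_b))
}
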