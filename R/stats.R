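#' Empirical PDF of an observable
#'
#' Normalized histogram (probability masses, not densities) on uniform bin
#' edges. Two PDFs are comparable by [hellinger()] only if they share the
#' same edges; samples outside the range are dropped with a warning.
#'
#' @param x samples.
#' @param range length-2 numeric range of the support.
#' @param bins number of uniform bins.
#' @param label optional observable label (carried in the object).
#' @return an object of class `school_pdf` with fields `edges` (length
#'   `bins + 1`), `mass` (sums to 1), `n` (samples used), `label`.
#' @export
empirical_pdf <- function(x, range, bins = 100, label = NULL) {
  stopifnot(length(range) == 2, range[2] > range[1], bins >= 1)
  x <- x[is.finite(x)]
  keep <- x >= range[1] & x <= range[2]
  if (any(!keep)) {
    warning(sum(!keep), " sample(s) outside the PDF range were dropped")
  }
  x <- x[keep]
  if (length(x) == 0) stop("no samples inside the PDF range")
  edges <- seq(range[1], range[2], length.out = bins + 1)
  counts <- graphics::hist(x, breaks = edges, plot = FALSE)$counts
  structure(
    list(
      edges = edges, mass = counts / sum(counts), n = length(x),
      label = label %||% "observable"
    ),
    class = "school_pdf"
  )
}

#' @export
print.school_pdf <- function(x, ...) {
  cat(sprintf(
    "<school_pdf> %s: %d bins on [%.3g, %.3g], n = %d\n",
    x$label, length(x$mass), x$edges[1], x$edges[length(x$edges)], x$n
  ))
  invisible(x)
}

#' Hellinger distance between two empirical PDFs
#'
#' Discrete Bhattacharyya form \eqn{D(F|G) = \sqrt{1 - \sum_i \sqrt{F_i
#' G_i}}}, equivalently \eqn{\sqrt{\frac12 \sum_i (\sqrt{F_i} -
#' \sqrt{G_i})^2}}. It is 0 iff the PDFs coincide and 1 iff their supports
#' are disjoint; in practice a distance above about 0.1 marks two clearly
#' dissimilar distributions.
#'
#' @param f,g `school_pdf` objects on identical bin edges.
#' @return a number in `[0, 1]`.
#' @examples
#' a <- empirical_pdf(runif(1000), c(0, 1), 20)
#' hellinger(a, a) # 0
#' @export
hellinger <- function(f, g) {
  stopifnot(inherits(f, "school_pdf"), inherits(g, "school_pdf"))
  if (length(f$edges) != length(g$edges) ||
    max(abs(f$edges - g$edges)) > 1e-12) {
    stop("the two PDFs must share identical bin edges")
  }
  d2 <- 1 - sum(sqrt(f$mass * g$mass))
  sqrt(max(d2, 0))
}

#' Fit the distance rescaling factor between two cohesion distributions
#'
#' Grid search for the multiplier \eqn{\lambda} applied to the candidate
#' distance samples that minimizes the \eqn{l_1} norm of the difference
#' between the reference PDF and the histogram of the rescaled samples on
#' the reference edges. This is the procedure behind the published scale
#' factors \eqn{\lambda_M = 0.87} (model vs fish) and \eqn{\lambda_R =
#' 0.35} (robots vs fish); the rescaling applies to distance-valued
#' observables (cohesion, wall distance) only.
#'
#' @param reference a `school_pdf` of the reference cohesion distribution.
#' @param candidate_samples raw candidate distance samples (m).
#' @param lambda_grid grid of multipliers to search.
#' @return an object of class `scale_factor`: list with `lambda` (the
#'   minimizer), `objective` (its l1 value) and `profile` (tibble `lambda`,
#'   `l1`).
#' @export
fit_scale_factor <- function(reference, candidate_samples,
                             lambda_grid = seq(0.2, 3, by = 0.005)) {
  stopifnot(inherits(reference, "school_pdf"))
  candidate_samples <- candidate_samples[is.finite(candidate_samples)]
  if (length(unique(candidate_samples)) < 2) {
    stop("candidate samples are degenerate (fewer than 2 distinct values)")
  }
  edges <- reference$edges
  l1 <- vapply(lambda_grid, function(lam) {
    s <- lam * candidate_samples
    s <- s[s >= edges[1] & s <= edges[length(edges)]]
    if (length(s) == 0) {
      return(sum(reference$mass) + 1)
    }
    m <- graphics::hist(s, breaks = edges, plot = FALSE)$counts
    sum(abs(reference$mass - m / sum(m)))
  }, numeric(1))
  best <- which.min(l1)
  structure(
    list(
      lambda = lambda_grid[best], objective = l1[best],
      profile = tibble::tibble(lambda = lambda_grid, l1 = l1)
    ),
    class = "scale_factor"
  )
}

#' @export
print.scale_factor <- function(x, ...) {
  cat(sprintf("<scale_factor> lambda = %.4g (l1 = %.4g)\n", x$lambda, x$objective))
  invisible(x)
}

#' Mirror-symmetrize a trajectory set
#'
#' Appends the mirror image (y -> -y, headings negated) of every
#' trajectory, doubling the sample count. Burst-and-coast swimmers show no
#' left/right asymmetry, so in finite recordings this removes the
#' artificial rotation-direction bias without affecting the distributions
#' of cohesion, polarization, wall distance, or counter-milling index; the
#' wall-angle distribution becomes even by construction.
#'
#' @param traj a trajectory tibble (`time_s`, `agent_id`, `x_m`, `y_m`,
#'   optionally `heading_rad`).
#' @return a tibble with twice the rows and an added logical `mirrored`
#'   column.
#' @export
symmetrize <- function(traj) {
  stopifnot(all(c("time_s", "agent_id", "x_m", "y_m") %in% names(traj)))
  mirror <- traj
  mirror$y_m <- -mirror$y_m
  if ("heading_rad" %in% names(mirror)) {
    mirror$heading_rad <- wrap_angle(-mirror$heading_rad)
  }
  dplyr::bind_rows(
    dplyr::mutate(traj, mirrored = FALSE),
    dplyr::mutate(mirror, mirrored = TRUE)
  )
}

#' Cohesion-polarization density map
#'
#' 2D histogram of paired (C, P) samples on a 40 x 50 grid (40 cohesion
#' columns, 50 polarization rows). Normalization `"total"` divides by the
#' grand total; `"per_polarization_row"` turns each polarization row into a
#' PDF of the cohesion (empty rows stay zero and are flagged).
#'
#' @param c_samples,p_samples paired cohesion (m) and polarization samples.
#' @param c_range,p_range ranges of the grid.
#' @param bins length-2 integer: bins along C and along P.
#' @param normalization `"total"` or `"per_polarization_row"`.
#' @return a tibble with columns `c_mid`, `p_mid`, `count`, `density`, and
#'   attribute `empty_rows` (indices of empty polarization rows under row
#'   normalization).
#' @export
density_map <- function(c_samples, p_samples, c_range = c(0, 0.25),
                        p_range = c(0, 1), bins = c(40L, 50L),
                        normalization = c("total", "per_polarization_row")) {
  normalization <- match.arg(normalization)
  stopifnot(length(c_samples) == length(p_samples))
  ok <- is.finite(c_samples) & is.finite(p_samples) &
    c_samples >= c_range[1] & c_samples <= c_range[2] &
    p_samples >= p_range[1] & p_samples <= p_range[2]
  cs <- c_samples[ok]
  ps <- p_samples[ok]
  c_edges <- seq(c_range[1], c_range[2], length.out = bins[1] + 1)
  p_edges <- seq(p_range[1], p_range[2], length.out = bins[2] + 1)
  ci <- pmin(pmax(findInterval(cs, c_edges, rightmost.closed = TRUE), 1), bins[1])
  pi_ <- pmin(pmax(findInterval(ps, p_edges, rightmost.closed = TRUE), 1), bins[2])
  counts <- matrix(0, bins[2], bins[1])
  for (s in seq_along(ci)) counts[pi_[s], ci[s]] <- counts[pi_[s], ci[s]] + 1
  empty_rows <- integer(0)
  dens <- if (normalization == "total") {
    counts / max(sum(counts), 1)
  } else {
    rs <- rowSums(counts)
    empty_rows <- which(rs == 0)
    if (length(empty_rows) > 0) {
      warning(length(empty_rows), " empty polarization row(s) left as zeros")
    }
    sweep(counts, 1, pmax(rs, 1), "/")
  }
  c_mid <- (c_edges[-1] + c_edges[-length(c_edges)]) / 2
  p_mid <- (p_edges[-1] + p_edges[-length(p_edges)]) / 2
  out <- tibble::tibble(
    c_mid = rep(c_mid, each = bins[2]),
    p_mid = rep(p_mid, times = bins[1]),
    count = as.vector(counts),
    density = as.vector(dens)
  )
  attr(out, "empty_rows") <- empty_rows
  attr(out, "normalization") <- normalization
  out
}

#' Default PDF bin specifications for the five observables
#'
#' Hellinger distances depend on the binning, so comparisons should state
#' the bin spec used. These defaults cover the bounded-arena ranges:
#' cohesion on `[0, 0.25]` m (100 bins), polarization on `[0, 1]` (100),
#' wall distance on `[0, R]` (100), wall angle on `(-pi, pi]` (72), and
#' counter-milling index on `[-1, 1]` (80).
#'
#' @param arena_radius tank radius (m).
#' @return a named list of `list(range =, bins =)` specs, one per
#'   observable column name produced by [compute_observables()].
#' @export
default_pdf_bins <- function(arena_radius = 0.25) {
  list(
    cohesion_m = list(range = c(0, 0.25), bins = 100L),
    polarization = list(range = c(0, 1), bins = 100L),
    r_wb_m = list(range = c(0, arena_radius), bins = 100L),
    theta_wb_rad = list(range = c(-pi, pi), bins = 72L),
    q = list(range = c(-1, 1), bins = 80L)
  )
}

#' Hellinger distances between two sets of observable distributions
#'
#' Builds the empirical PDF of each observable column present in both
#' summary tables and returns the per-observable Hellinger distance plus
#' their mean (the `<All>` global quantifier). Distance-valued observables
#' (`cohesion_m`, `r_wb_m`) of the candidate can be rescaled by `lambda`
#' first.
#'
#' @param reference,candidate observable tibbles from
#'   [compute_observables()].
#' @param bins bin specs as from [default_pdf_bins()].
#' @param lambda distance rescaling applied to the candidate's
#'   `cohesion_m` and `r_wb_m` columns.
#' @return a tibble with columns `observable`, `distance`, plus one row
#'   `"<All>"` holding the mean distance.
#' @export
observable_distances <- function(reference, candidate,
                                 bins = default_pdf_bins(), lambda = 1) {
  obs <- intersect(names(bins), intersect(names(reference), names(candidate)))
  if (length(obs) == 0) stop("no common observable columns")
  scale_cols <- c("cohesion_m", "r_wb_m")
  d <- vapply(obs, function(o) {
    rv <- reference[[o]]
    cv <- candidate[[o]]
    if (o %in% scale_cols) cv <- lambda * cv
    suppressWarnings({
      f <- empirical_pdf(rv, bins[[o]]$range, bins[[o]]$bins, label = o)
      g <- empirical_pdf(cv, bins[[o]]$range, bins[[o]]$bins, label = o)
    })
    hellinger(f, g)
  }, numeric(1))
  tibble::tibble(
    observable = c(obs, "<All>"),
    distance = unname(c(d, mean(d)))
  )
}
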