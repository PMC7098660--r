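#' Neighbor-selection strategy
#'
#' A strategy fixes, for a whole simulation, how the neighbors entering the
#' social sum are chosen at every kick of the focal swimmer: the `k`
#' nearest, `k` drawn uniformly at random without replacement, or the `k`
#' with the largest influence on the focal swimmer (see
#' [pair_influence()]). `"none"` (equivalently `k = 0`) disables social
#' interactions; `"all"` selects every neighbor. The selected identities
#' are re-evaluated at every kick, but the rule itself never changes.
#'
#' @param kind one of `"nearest"`, `"random"`, `"influential"`, `"all"`,
#'   `"none"`.
#' @param k number of neighbors (ignored for `"all"`/`"none"`).
#' @return an object of class `school_strategy`.
#' @examples
#' strategy("influential", k = 1)
#' strategy("nearest", k = 2)
#' @export
strategy <- function(kind = c("nearest", "random", "influential", "all", "none"),
                     k = 1L) {
  kind <- match.arg(kind)
  k <- as.integer(k)
  if (kind == "none") k <- 0L
  if (kind != "none" && kind != "all" && k < 1L) {
    stop("k must be >= 1 for kind '", kind, "' (use kind = \"none\" for k = 0)")
  }
  structure(list(kind = kind, k = k), class = "school_strategy")
}

#' @export
print.school_strategy <- function(x, ...) {
  cat("<school_strategy>", x$kind,
    if (x$kind %in% c("nearest", "random", "influential")) paste0("k = ", x$k),
    "\n"
  )
  invisible(x)
}

# resolve strategy to (code, k) given N; shared by R selection and the engine
resolve_strategy <- function(strat, n_agents) {
  stopifnot(inherits(strat, "school_strategy"))
  k <- switch(strat$kind,
    none = 0L,
    all = n_agents - 1L,
    strat$k
  )
  if (k > n_agents - 1L) {
    stop("k = ", k, " exceeds N - 1 = ", n_agents - 1L, " available neighbors")
  }
  code <- match(strat$kind, c("none", "nearest", "random", "influential", "all")) - 1L
  list(code = code, k = k)
}

#' Select the interacting neighbors of a focal swimmer
#'
#' Applies a neighbor-selection strategy to the instantaneous state of the
#' school at one kick of the focal swimmer. Distance and influence ties are
#' broken by lowest agent index, so the selection is deterministic given
#' the RNG state (only the `"random"` kind consumes random numbers).
#'
#' @param focal index (1-based) of the kicking swimmer.
#' @param states a data frame with one row per swimmer and columns `x`,
#'   `y`, `heading` giving the instantaneous (glide-interpolated) state.
#' @param strat a [strategy()] object.
#' @param params a [school_params()] object (needed for the influence
#'   ranking).
#' @param influence_truncated apply the attraction cut-off inside the
#'   influence ranking (default `FALSE`).
#' @return integer vector of selected neighbor indices (possibly empty),
#'   in increasing index order.
#' @export
select_neighbors <- function(focal, states, strat, params,
                             influence_truncated = FALSE) {
  n <- nrow(states)
  if (n < 2) stop("need at least 2 swimmers")
  res <- resolve_strategy(strat, n)
  others <- setdiff(seq_len(n), focal)
  if (res$k == 0L) {
    return(integer(0))
  }
  if (res$k == n - 1L) {
    return(others)
  }
  sel <- switch(strat$kind,
    nearest = {
      d <- sqrt((states$x[others] - states$x[focal])^2 +
        (states$y[others] - states$y[focal])^2)
      others[order(d, others)[seq_len(res$k)]]
    },
    random = sample(others, res$k),
    influential = {
      rs <- purrr::map_dfr(others, function(j) {
        relative_state(
          c(states$x[focal], states$y[focal]), states$heading[focal],
          c(states$x[j], states$y[j]), states$heading[j]
        )
      })
      infl <- pair_influence(
        rs$d_ij, rs$psi_ij, rs$phi_ij, params,
        truncated = influence_truncated
      )
      others[order(-infl, others)[seq_len(res$k)]]
    }
  )
  sort(sel)
}

#' Overlap distribution of independently drawn k-subsets
#'
#' Exact distribution, by full enumeration, of the size of the common
#' intersection of `n_draws` independent uniform k-subsets of a pool. With
#' a pool of 4 neighbors and `k = 3`, two independent strategies select
#' exactly the same neighbors with probability 0.25 and three strategies
#' with probability 0.0625 -- the combinatorial reason why all selection
#' strategies converge once k is close to the pool size.
#'
#' @param pool_size number of candidate neighbors (at most 12; enumeration
#'   is exact).
#' @param k subset size drawn by each strategy.
#' @param n_draws number of independent draws (strategies).
#' @return a tibble with columns `overlap` (0..k), `probability`, and
#'   `p_at_least` (probability that the common overlap is >= `overlap`).
#' @examples
#' subset_overlap_probability(4, 3, 2)
#' @export
subset_overlap_probability <- function(pool_size, k, n_draws) {
  stopifnot(pool_size >= 1, k >= 1, k <= pool_size, n_draws >= 1)
  if (pool_size > 12) stop("pool_size too large for exact enumeration")
  subs <- utils::combn(pool_size, k)
  masks <- apply(subs, 2, function(s) sum(bitwShiftL(1L, s - 1L)))
  n_sub <- length(masks)
  # intersection mask over n_draws independent choices, enumerated by
  # expanding one draw at a time: state = distribution over masks
  dist <- table(masks) / n_sub
  state <- stats::setNames(as.numeric(dist), names(dist))
  for (i in seq_len(n_draws - 1L)) {
    nxt <- new.env(parent = emptyenv())
    for (m in names(state)) {
      pm <- state[[m]]
      inter <- bitwAnd(as.integer(m), masks)
      for (j in seq_len(n_sub)) {
        key <- as.character(inter[j])
        prev <- if (is.null(nxt[[key]])) 0 else nxt[[key]]
        nxt[[key]] <- prev + pm / n_sub
      }
    }
    state <- stats::setNames(
      vapply(ls(nxt), function(kk) nxt[[kk]], numeric(1)), ls(nxt)
    )
  }
  popcount <- function(m) sum(bitwAnd(bitwShiftR(m, 0:(pool_size - 1L)), 1L))
  sizes <- vapply(as.integer(names(state)), popcount, numeric(1))
  prob <- vapply(0:k, function(s) sum(state[sizes == s]), numeric(1))
  tibble::tibble(
    overlap = 0:k,
    probability = prob,
    p_at_least = rev(cumsum(rev(prob)))
  )
}
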