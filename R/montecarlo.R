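#' Monte Carlo sampling-adequacy simulation
#'
#' How many randomly drawn virtual cores per case are needed to reproduce
#' the whole-slide statistics? For every requested sample size n, `reps`
#' random subsets of n tiles are drawn without replacement (default 10 per
#' case and size, sizes 2..200 in steps of 1), and for each draw the median
#' bud count, the median budding grade and the normalized Shannon entropy of
#' the grades are computed. Each (size, rep) combination runs on its own
#' deterministic RNG substream derived from the master seed, so results are
#' reproducible and order-independent.
#'
#' @param counts numeric vector of per-tile bud counts for one case (>= 2
#'   tiles).
#' @param sizes sample sizes (default `2:200`); sizes above the tile count
#'   are truncated to it, with a warning.
#' @param reps repetitions per size (default 10).
#' @param scheme [gradingScheme()] for the per-tile grades.
#' @param seed master seed.
#' @return list with `draws` (tidy data.frame: `n`, `rel_n`, `rep`,
#'   `median_buds`, `median_grade`, `norm_entropy`), `envelope` (per-size
#'   min/median/max of each statistic across reps) and `wholeSlide` (the
#'   same three statistics on all tiles). The median grade is rounded
#'   half-down to an integer grade.
#' @export
runSubsampling <- function(counts, sizes = 2:200, reps = 10,
                           scheme = gradingScheme("satoh"), seed = 1) {
  nTiles <- length(counts)
  if (nTiles < 2L) stop("need at least two tiles per case")
  if (any(sizes > nTiles)) {
    warning("sample sizes above the tile count truncated")
    sizes <- pmin(sizes, nTiles)
  }
  sizes <- sort(unique(sizes))
  grades <- budGrade(counts, scheme)
  K <- length(scheme$grades)
  statsOf <- function(idx) {
    g <- grades[idx]
    c(median_buds = stats::median(counts[idx]),
      ## half-down rounding of a possibly half-integer median grade
      median_grade = as.integer(ceiling(stats::median(g) - 0.5)),
      norm_entropy = normalizedEntropy(g, K)$normalized)
  }
  combos <- expand.grid(rep = seq_len(reps), n = sizes)
  subseeds <- substreamSeeds(seed, nrow(combos))
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    n <- combos$n[k]
    idx <- withSeed(subseeds[k], sample.int(nTiles, n))
    st <- statsOf(idx)
    data.frame(n = n, rel_n = n / nTiles, rep = combos$rep[k],
               median_buds = st[["median_buds"]],
               median_grade = st[["median_grade"]],
               norm_entropy = st[["norm_entropy"]])
  })
  draws <- do.call(rbind, rows)
  env <- do.call(rbind, lapply(split(draws, draws$n), function(d) {
    data.frame(n = d$n[1], rel_n = d$rel_n[1],
               buds_min = min(d$median_buds), buds_med = stats::median(d$median_buds),
               buds_max = max(d$median_buds),
               grade_min = min(d$median_grade), grade_max = max(d$median_grade),
               entropy_min = min(d$norm_entropy),
               entropy_med = stats::median(d$norm_entropy),
               entropy_max = max(d$norm_entropy))
  }))
  rownames(env) <- NULL
  whole <- statsOf(seq_len(nTiles))
  list(draws = draws, envelope = env,
       wholeSlide = list(median_buds = whole[["median_buds"]],
                         median_grade = whole[["median_grade"]],
                         norm_entropy = whole[["norm_entropy"]]))
}
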